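test_that("initialization is seeded, bounded and pass-through", {
  g <- planted_partition(2, 25, 0.3, 0.05, seed = 3)$graph
  cfg <- entopt_config(seed = 11)
  s1 <- init_layout(g, cfg)
  s2 <- init_layout(g, cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$positions >= 0 & s1$positions <= 1))
  expect_true(all(s1$widths == 0.1))

  tab <- data.frame(node_id = c("A", "B"), x = c(0, 1), y = c(0, 0))
  st <- init_layout(dyad(), entopt_config(), tab)
  expect_identical(st$positions, cbind(c(0, 1), c(0, 0)))

  bad <- data.frame(node_id = "A", x = 0, y = 0)
  expect_error(init_layout(dyad(), entopt_config(), bad), "missing node.*B")
})

test_that("coincident nodes are jittered apart deterministically", {
  tab <- data.frame(node_id = c("A", "B", "C"), x = c(1, 1, 2),
                    y = c(1, 1, 0))
  cfg <- entopt_config(seed = 5)
  s1 <- init_layout(path3(), cfg, tab)
  s2 <- init_layout(path3(), cfg, tab)
  expect_identical(s1, s2)
  expect_false(any(duplicated(s1$positions, MARGIN = 1)))
  expect_lt(max(abs(s1$positions[2, ] - c(1, 1))), 1e-5)
})

test_that("width phase never increases the loss from any start", {
  for (seed in 1:5) {
    case <- random_case(8, seed = 20 + seed)
    tg <- build_target(case$graph)
    res <- run_phase(case$state, tg, "W", entopt_config(max_iter = 50))
    expect_true(all(diff(res$trace$loss) <= 1e-12))
    d0 <- relative_entropy(tg, representation(case$state, tg))
    expect_lte(res$kl, d0 + 1e-12)
  }
})

test_that("graphs with exact representations reach zero loss", {
  fit <- entopt(k3(), seed = 2)
  expect_lt(fit$loss, 1e-6)

  # two disconnected equal-weight dyads also admit an exact representation
  g <- weighted_graph(c("A", "B", "C", "D"), rbind(c(1, 2), c(3, 4)))
  hits <- sum(vapply(1:10, function(s) entopt(g, seed = s)$loss < 1e-6,
                     logical(1)))
  expect_gte(hits, 8)

  # 2-node graph: single pair, q = p = 1 regardless of geometry
  expect_equal(entopt(dyad(), seed = 1, schedule = "WP")$loss, 0)
})

test_that("optimization is deterministic and monotone across the schedule", {
  pp <- planted_partition(3, 8, 0.6, 0.05, seed = 9)
  f1 <- entopt(pp$graph, seed = 4)
  f2 <- entopt(pp$graph, seed = 4)
  expect_equal(f1$kl, f2$kl, tolerance = 1e-12)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)

  tr <- f1$trace
  expect_true(all(diff(tr$loss) <= 1e-12))   # non-increasing accepted steps
  expect_lte(tr$loss[nrow(tr)], tr$loss[1])
})

test_that("optimizer matches a 1-D grid-search oracle on the frozen-width path", {
  tg <- build_target(path3())
  st <- layout_state(rbind(c(0, 0), c(0.6, 0), c(1, 0)), 1)
  res <- run_phase(st, tg, "P", entopt_config(max_iter = 500))
  expect_true(all(abs(res$state$positions[, 2]) < 1e-12))  # stays collinear

  # oracle: symmetric configurations (0, g, 2g), widths 1, grid step 1e-3
  gs <- seq(1e-3, 10, by = 1e-3)
  kl <- vapply(gs, function(gap) {
    o <- exp(c(-gap^2 / 4, -gap^2, -gap^2 / 4))
    q <- o / sum(o)
    sum(0.5 * log(0.5 / q[c(1, 3)]))
  }, numeric(1))
  expect_lt(abs(res$kl - min(kl)), 1e-3)
})

test_that("schedule strings and config values are validated", {
  expect_error(entopt_config(schedule = ""), "schedule")
  expect_error(entopt_config(schedule = "PXW"), "schedule")
  expect_error(entopt_config(max_iter = 0))
  expect_error(entopt_config(rel_tol = 0))
  expect_identical(entopt_config(schedule = "pw")$schedule, c("P", "W"))
})

test_that("restarts keep the best of the derived-seed runs", {
  g <- weighted_graph(c("A", "B", "C", "D"), rbind(c(1, 2), c(3, 4)))
  single <- entopt(g, seed = 6)
  multi <- entopt(g, seed = 6, restarts = 3)
  expect_lte(multi$kl, single$kl + 1e-12)
})

test_that("per-iteration work is quadratic in the node count", {
  pp <- planted_partition(2, 10, 0.5, 0.1, seed = 2)
  tg <- build_target(pp$graph)
  st <- init_layout(pp$graph, entopt_config(seed = 1))
  entopt:::overlap_evals_reset()
  res <- run_phase(st, tg, "P", entopt_config(max_iter = 5))
  evals <- entopt:::overlap_evals_get()
  n_pairs <- 20 * 19 / 2
  # every loss/gradient evaluation touches each pair exactly once
  expect_equal(evals %% n_pairs, 0)
  expect_lte(evals / n_pairs, 5 * 62 + 2)  # iterations x (line search + grad)
})
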