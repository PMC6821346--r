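test_that("target distribution normalizes edge weights over all pairs", {
  tri <- build_target(k3())
  expect_equal(sum(tri$p), 1, tolerance = 1e-12)
  expect_equal(tri$p, rep(1 / 3, 3))

  pa <- build_target(path3())
  expect_equal(nrow(pa$pairs), 3)  # pair index spans all pairs
  expect_equal(sort(pa$p), c(0, 0.5, 0.5))
  expect_equal(sum(pa$p > 0), 2)  # AC absent from the support

  w <- build_target(weighted_graph(c("A", "B", "C"),
                                   rbind(c(1, 2), c(2, 3)), c(1, 3)))
  expect_equal(sort(w$p), c(0, 0.25, 0.75))
})

test_that("squared-adjacency target matches the matrix-product oracle", {
  g <- path3()
  M <- adjacency_matrix(g) %*% adjacency_matrix(g)  # independent oracle
  expect_equal(unname(M), rbind(c(1, 0, 1), c(0, 2, 0), c(1, 0, 1)))

  tg <- build_target(g, use_square = TRUE, ignore_square_diagonal = TRUE)
  expect_equal(nrow(tg$pairs), 3)           # off-diagonal pairs only
  expect_equal(tg$p[tg$p > 0], 1)           # all mass on (A, C)
  ac <- which(tg$p > 0)
  expect_equal(tg$pairs[ac, ], c(1, 3))

  kept <- build_target(g, use_square = TRUE, ignore_square_diagonal = FALSE)
  expect_equal(nrow(kept$pairs), 6)         # 3 pairs + 3 self-pairs
  diag_rows <- kept$pairs[, 1] == kept$pairs[, 2]
  total <- sum(M[upper.tri(M)]) + sum(diag(M))
  expect_equal(sum(kept$p[diag_rows]), sum(diag(M)) / total,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(kept$p[diag_rows]), c(1, 2, 1) / 5)
  expect_equal(sum(kept$p), 1, tolerance = 1e-12)
})

test_that("degenerate targets are rejected", {
  expect_error(build_target(dyad(), use_square = TRUE,
                            ignore_square_diagonal = TRUE), "zero total mass")
  g <- weighted_graph(c("A", "B"), matrix(integer(0), 0, 2))
  expect_error(build_target(g), "no edges")
})

test_that("gaussian overlap matches its closed form and limits", {
  expect_equal(gaussian_overlap(c(0, 0), c(0, 0), 1, 1), 1 / (4 * pi),
               tolerance = 1e-12)
  # numerically integrated oracle, frozen: two unit Gaussians 1 apart
  expect_equal(gaussian_overlap(c(0, 0), c(1, 0), 1, 1),
               exp(-0.25) / (4 * pi), tolerance = 1e-12)
  far <- gaussian_overlap(c(0, 0), c(100, 0), 1, 1)
  expect_true(far >= 0 && far < 1e-300 && !is.nan(far))

  set.seed(1)
  for (k in 1:100) {
    ri <- runif(2); rj <- runif(2); si <- runif(1, 0.1, 2)
    sj <- runif(1, 0.1, 2)
    expect_identical(gaussian_overlap(ri, rj, si, sj),
                     gaussian_overlap(rj, ri, sj, si))
  }
})

test_that("representation normalizes overlaps over the target pair index", {
  d <- build_target(dyad())
  st <- layout_state(rbind(c(0, 0), c(5, 3)), c(0.2, 2))
  expect_equal(representation(st, d)$q, 1)

  tri <- build_target(k3())
  expect_equal(representation(equilateral_state(), tri)$q, rep(1 / 3, 3),
               tolerance = 1e-12)

  # collinear nodes, unit widths: overlaps prop to e^-1/4, e^-1/4, e^-1
  pa <- build_target(path3())
  st <- layout_state(rbind(c(0, 0), c(1, 0), c(2, 0)), 1)
  q <- representation(st, pa)$q
  oracle <- exp(c(-1 / 4, -1, -1 / 4)) / sum(exp(c(-1 / 4, -1, -1 / 4)))
  expect_equal(q, oracle, tolerance = 1e-12)
  expect_equal(q[c(1, 3)], rep(0.4044708, 2), tolerance = 1e-6)
  expect_equal(q[2], 0.1910585, tolerance = 1e-6)
  expect_equal(sum(q), 1, tolerance = 1e-12)
})

test_that("representation is invariant under similarity transforms", {
  for (seed in 1:5) {
    case <- random_case(8, seed = seed)
    tg <- build_target(case$graph)
    q0 <- representation(case$state, tg)$q
    th <- runif(1, 0, 2 * pi); c0 <- runif(1, 0.1, 10)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    st2 <- layout_state(sweep(case$state$positions %*% t(R) * c0, 2,
                              c(-3, 7), "+"),
                        case$state$widths * c0)
    expect_equal(representation(st2, tg)$q, q0, tolerance = 1e-10)
  }
})

test_that("representation cost is one overlap per pair (quadratic in n)", {
  case <- random_case(13, seed = 3)
  tg <- build_target(case$graph)
  entopt:::overlap_evals_reset()
  representation(case$state, tg)
  expect_identical(entopt:::overlap_evals_get(), 13 * 12 / 2)
})

test_that("an over-spread layout fails loudly, not with NaNs", {
  pa <- build_target(path3())
  st <- layout_state(rbind(c(0, 0), c(1e6, 0), c(2e6, 0)), 0.01)
  expect_error(representation(st, pa), "underflow")
})
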