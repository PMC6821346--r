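#' Optimization settings for [entopt()]
#'
#' @param schedule character string over `P` (position phase) and `W` (width
#'   phase), e.g. the default `"PWPWP"`: optimize positions, then widths,
#'   alternating. Loss typically plateaus within this default 5-phase
#'   schedule; append phases while the loss still decreases.
#' @param max_iter maximum accepted gradient steps per phase.
#' @param rel_tol relative loss-change convergence threshold per phase.
#' @param seed integer seed for random initialization (and coincident-node
#'   jitter); `NULL` uses the session RNG state.
#' @param sigma0 initial Gaussian width (standard deviation, layout units).
#' @param use_square build the target from the squared adjacency matrix?
#' @param ignore_square_diagonal drop the diagonal of the squared matrix?
#' @param report_every iteration interval at which trace rows are recorded
#'   and the progress callback is invoked.
#' @param max_seconds advisory wall-clock limit per phase, checked between
#'   iterations.
#' @return A list of class `entopt_config`.
#' @export
entopt_config <- function(schedule = "PWPWP", max_iter = 500L,
                          rel_tol = 1e-9, seed = NULL, sigma0 = 0.1,
                          use_square = FALSE, ignore_square_diagonal = TRUE,
                          report_every = 10L, max_seconds = Inf) {
  phases <- parse_schedule(schedule)
  stopifnot(max_iter >= 1, rel_tol > 0, sigma0 > 0, report_every >= 1)
  structure(list(schedule = phases, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, seed = seed, sigma0 = sigma0,
                 use_square = use_square,
                 ignore_square_diagonal = ignore_square_diagonal,
                 report_every = as.integer(report_every),
                 max_seconds = max_seconds),
            class = "entopt_config")
}

parse_schedule <- function(schedule) {
  if (length(schedule) == 1 && is.character(schedule))
    schedule <- strsplit(toupper(schedule), "")[[1]]
  if (length(schedule) == 0 || !all(schedule %in% c("P", "W")))
    stop("schedule must be a non-empty string over the characters P and W")
  schedule
}

#' Initial layout for an optimization run
#'
#' Random mode draws node positions uniformly in the unit square under the
#' configured seed and sets all widths to `sigma0`. Provided mode copies
#' coordinates (and widths, if present) from a layout table. Exactly
#' coincident nodes are separated by a seeded jitter of 1e-6 so symmetric
#' configurations cannot lock the gradient at zero distance.
#'
#' @param graph an [weighted_graph()] object.
#' @param config an [entopt_config()].
#' @param provided optional layout table (data frame `node_id,x,y[,width]`,
#'   as from [read_layout()]) covering all graph nodes.
#' @return An [layout_state()] whose rows follow the graph's node order.
#' @export
init_layout <- function(graph, config = entopt_config(), provided = NULL) {
  n <- length(graph$nodes)
  if (is.null(provided)) {
    pos <- with_seed(config$seed,
                     matrix(runif(2 * n), n, 2))
    widths <- rep(config$sigma0, n)
  } else {
    if (is.matrix(provided))
      provided <- as_layout_table(provided, graph)
    idx <- match(graph$nodes, provided$node_id)
    if (anyNA(idx))
      stop("provided layout is missing node(s): ",
           paste(graph$nodes[is.na(idx)], collapse = ", "))
    pos <- cbind(provided$x[idx], provided$y[idx])
    widths <- if (is.null(provided$width)) rep(config$sigma0, n)
              else provided$width[idx]
    if (anyNA(widths)) widths[is.na(widths)] <- config$sigma0
  }
  if (any(pos_dup <- duplicated(pos, MARGIN = 1))) {
    jitter <- with_seed(if (is.null(config$seed)) NULL else config$seed + 1L,
                        matrix(runif(2 * sum(pos_dup), -1, 1), ncol = 2))
    pos[pos_dup, ] <- pos[pos_dup, , drop = FALSE] + 1e-6 * jitter
  }
  layout_state(pos, widths)
}

#' Run one optimization phase (positions or widths)
#'
#' Full-batch gradient descent with backtracking (Armijo) line search on only
#' the phase's variables: node positions in a `P` phase, node widths in a `W`
#' phase. Every accepted step strictly decreases the KL loss; the phase stops
#' at `max_iter` accepted steps, when the relative loss change drops below
#' `rel_tol`, or when no decreasing step exists. Widths are clamped at the
#' admissible floor (1e-6 of the layout diameter).
#'
#' @param state starting [layout_state()].
#' @param target an [build_target()] object.
#' @param phase `"P"` (positions) or `"W"` (widths).
#' @param config an [entopt_config()].
#' @param label phase label recorded in the trace (default the phase letter).
#' @param callback optional `function(phase, iteration, loss)` invoked every
#'   `report_every` accepted steps with the normalized loss.
#' @return List with the updated `state`, final `kl`, and `trace` (data frame
#'   `phase`, `iteration`, `loss` of normalized losses at recorded steps).
#' @export
run_phase <- function(state, target, phase = c("P", "W"),
                      config = entopt_config(), label = NULL,
                      callback = NULL) {
  phase <- match.arg(phase)
  if (is.null(label)) label <- phase
  h <- target_entropy(target)
  norm <- function(kl) if (h > 0) kl / h else kl
  t0 <- proc.time()[["elapsed"]]

  g <- loss_gradients(state, target)
  f <- g$kl
  if (!is.finite(f))
    stop("non-finite loss at phase start: degenerate layout geometry")
  trace <- data.frame(phase = label, iteration = 0L, loss = norm(f))

  # phase variables: positions as-is; widths through their logarithm, which
  # makes the steps multiplicative, keeps widths positive by construction and
  # removes the scale sensitivity of raw-sigma steps (chain rule:
  # dD/dlog(sigma) = sigma * dD/dsigma)
  get_x <- function(st) if (phase == "P") st$positions else log(st$widths)
  get_g <- function(gr, st) if (phase == "P") gr$position
                            else st$widths * gr$width
  set_x <- function(st, x) {
    if (phase == "P") st$positions <- x
    else st$widths <- pmax(exp(x), sigma_min(st))
    st
  }

  alpha <- 1
  iter <- 0L
  small <- 0L    # consecutive below-tolerance improvements
  prev <- NULL   # previous accepted point/gradient, for the BB step size
  while (iter < config$max_iter) {
    grad <- get_g(g, state)
    if (sqrt(sum(grad^2)) < 1e-15) break
    x <- get_x(state)
    # initial trial step: spectral (Barzilai-Borwein) estimate from the last
    # accepted step, safeguarded by the Armijo backtracking below so every
    # accepted step still strictly decreases the loss
    if (!is.null(prev)) {
      sv <- x - prev$x
      yv <- grad - prev$g
      sy <- sum(sv * yv)
      alpha <- if (sy > 0) min(sum(sv * sv) / sy, 1e6) else alpha * 2
    } else {
      alpha <- min(1, 1 / max(abs(grad)))
    }
    accepted <- FALSE
    for (bt in 1:60) {
      cand <- set_x(state, x - alpha * grad)
      # projected-step Armijo decrement (projection: the width floor)
      decr <- sum(grad * (x - get_x(cand)))
      f_new <- tryCatch(
        relative_entropy(target, representation(cand, target)),
        error = function(e) Inf)
      if (is.finite(f_new) && decr > 0 && f_new <= f - 1e-4 * decr) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    iter <- iter + 1L
    improvement <- f - f_new
    prev <- list(x = x, g = grad)
    state <- cand
    f <- f_new
    g <- loss_gradients(state, target)
    if (iter %% config$report_every == 0L) {
      trace <- rbind(trace,
                     data.frame(phase = label, iteration = iter,
                                loss = norm(f)))
      if (!is.null(callback)) callback(label, iter, norm(f))
    }
    # spectral steps make uneven progress, so declare convergence only after
    # several consecutive below-tolerance improvements
    small <- if (improvement <= config$rel_tol * max(abs(f), 1e-300))
      small + 1L else 0L
    if (small >= 5L) break
    if (proc.time()[["elapsed"]] - t0 > config$max_seconds) break
  }
  if (nrow(trace) == 0 || trace$iteration[nrow(trace)] != iter)
    trace <- rbind(trace,
                   data.frame(phase = label, iteration = iter, loss = norm(f)))
  list(state = state, kl = f, trace = trace)
}

#' Fit an entropy-optimized network layout
#'
#' Represents every node as an isotropic 2-D Gaussian and minimizes the
#' Kullback-Leibler divergence between the network's target distribution over
#' node pairs and the layout's normalized pairwise-overlap distribution, by
#' alternating gradient-descent phases over node positions (`P`) and node
#' widths (`W`). The default `"PWPWP"` schedule alternates position, width,
#' position, width, position; the normalized information loss D of the result
#' is the layout quality score.
#'
#' @param graph an [weighted_graph()] object (or the result of
#'   [read_network()]).
#' @param init optional starting coordinates: a layout table
#'   (`node_id,x,y[,width]` data frame, as from [read_layout()] or
#'   [layout_force_directed()]). When omitted, positions are drawn uniformly
#'   at random in the unit square under `seed`.
#' @param restarts number of additional random restarts with derived seeds;
#'   the layout with the lowest loss is kept.
#' @param callback optional progress function, see [run_phase()].
#' @inheritParams entopt_config
#' @param ... passed on to [entopt_config()].
#' @return An object of class `entopt`: list with `state` (final positions
#'   and widths), `kl`, `entropy`, `loss` (normalized information loss D),
#'   `trace` (per-phase loss trace), `target`, `graph`, `config`. Methods:
#'   [print.entopt()], [summary.entopt()], [coef.entopt()], [plot.entopt()],
#'   [fitted.entopt()], [residuals.entopt()].
#' @examples
#' g <- weighted_graph(c("A", "B", "C"),
#'                     rbind(c(1, 2), c(2, 3), c(1, 3)))
#' fit <- entopt(g, seed = 1)
#' fit$loss  # ~0: the equilateral triangle represents K3 exactly
#' @export
entopt <- function(graph, init = NULL, seed = NULL, restarts = 0, ...,
                   callback = NULL) {
  config <- entopt_config(seed = seed, ...)
  fit <- entopt_once(graph, config, init, callback)
  if (restarts > 0 && is.null(init)) {
    for (k in seq_len(restarts)) {
      cfg_k <- config
      cfg_k$seed <- if (is.null(seed)) NULL else seed + k * 1009L
      alt <- entopt_once(graph, cfg_k, NULL, callback)
      if (alt$kl < fit$kl) fit <- alt
    }
  }
  fit$call <- match.call()
  fit
}

entopt_once <- function(graph, config, init, callback = NULL) {
  target <- build_target(graph, config$use_square,
                         config$ignore_square_diagonal)
  state <- init_layout(graph, config, init)
  traces <- list()
  kl <- relative_entropy(target, representation(state, target))
  for (k in seq_along(config$schedule)) {
    ph <- config$schedule[k]
    res <- run_phase(state, target, ph, config,
                     label = paste0(ph, k), callback = callback)
    state <- res$state
    kl <- res$kl
    traces[[k]] <- res$trace
  }
  trace <- do.call(rbind, traces)
  h <- target_entropy(target)
  structure(list(graph = graph, target = target, state = state,
                 kl = kl, entropy = h,
                 loss = as.numeric(normalized_loss(kl, target)),
                 normalized = h > 0,
                 trace = trace, config = config,
                 positions_fixed = all(config$schedule == "W")),
            class = "entopt")
}
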