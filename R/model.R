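#' Build the target distribution P over node pairs
#'
#' The network is recast as a probability distribution over unordered node
#' pairs. With `use_square = FALSE`, `p_ij = w_ij / sum(w)`. With
#' `use_square = TRUE` the symmetric weight matrix (zero diagonal) is squared,
#' `M = W %*% W`, whose entries count (weighted) shared neighbors and hence
#' interaction-profile similarity; `p` is then proportional to the entries of
#' `M`, each unordered off-diagonal pair counted once. The diagonal of the
#' square, `M_ii = sum_j w_ij^2`, is dropped when `ignore_square_diagonal` is
#' `TRUE`; when kept, the diagonal entries become self-pairs `(i, i)`.
#'
#' The pair index of the result spans *all* `n(n-1)/2` unordered pairs (plus
#' all `n` self-pairs in the kept-diagonal squared mode); pairs not carrying
#' mass have `p = 0` and are excluded from the support but remain in the
#' sample space over which the representation distribution is normalized.
#'
#' @param graph an [weighted_graph()] object with at least one edge.
#' @param use_square square the adjacency matrix before normalizing?
#' @param ignore_square_diagonal drop the diagonal of the squared matrix?
#'   Ignored when `use_square = FALSE` (the raw adjacency has no diagonal).
#' @return An object of class `entopt_target`: list with `pairs` (integer
#'   matrix, `i <= j`), `p` (probabilities summing to 1), `n`, `nodes`, and
#'   the two flags.
#' @examples
#' g <- weighted_graph(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
#' tg <- build_target(g, use_square = TRUE, ignore_square_diagonal = TRUE)
#' tg$p[tg$p > 0]  # all W^2 off-diagonal mass sits on the pair (A, C)
#' @export
build_target <- function(graph, use_square = FALSE,
                         ignore_square_diagonal = TRUE) {
  stopifnot(inherits(graph, "entopt_graph"))
  if (nrow(graph$edges) < 1) stop("graph has no edges; target is undefined")
  n <- length(graph$nodes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- unname(ut[order(ut[, 1], ut[, 2]), , drop = FALSE])
  if (!use_square) {
    mass <- numeric(nrow(pairs))
    key <- (pairs[, 1] - 1) * n + pairs[, 2]
    ekey <- (graph$edges[, 1] - 1) * n + graph$edges[, 2]
    mass[match(ekey, key)] <- graph$weights
    diag_kept <- FALSE
  } else {
    W <- adjacency_matrix(graph)
    M <- W %*% W
    diag_kept <- !ignore_square_diagonal
    mass <- M[pairs]
    if (diag_kept) {
      pairs <- rbind(pairs, cbind(seq_len(n), seq_len(n)))
      mass <- c(mass, diag(M))
    }
  }
  total <- sum(mass)
  if (total <= 0)
    stop("target has zero total mass (squared adjacency carries no ",
         "off-diagonal weight and its diagonal is ignored)")
  structure(list(pairs = pairs, p = mass / total, n = n, nodes = graph$nodes,
                 use_square = use_square,
                 ignore_square_diagonal = !diag_kept && use_square),
            class = "entopt_target")
}

#' @export
print.entopt_target <- function(x, ...) {
  cat(sprintf(
    "entopt_target: %d nodes, %d pairs (%d with mass)%s\n",
    x$n, nrow(x$pairs), sum(x$p > 0),
    if (x$use_square)
      paste0(", squared adjacency (diagonal ",
             if (x$ignore_square_diagonal) "ignored" else "kept", ")")
    else ""))
  invisible(x)
}

#' Layout state: node positions and Gaussian widths
#'
#' @param positions numeric `n x 2` matrix of node coordinates.
#' @param widths positive numeric vector of per-node Gaussian standard
#'   deviations, recycled to `n`.
#' @return An object of class `entopt_state`.
#' @export
layout_state <- function(positions, widths = 0.1) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, all(is.finite(positions)))
  widths <- rep_len(as.numeric(widths), nrow(positions))
  stopifnot(all(is.finite(widths)), all(widths > 0))
  structure(list(positions = unname(positions), widths = widths),
            class = "entopt_state")
}

# smallest admissible width: 1e-6 of the current layout diameter, with an
# absolute floor so a collapsed layout still has a positive bound
sigma_min <- function(state) {
  d <- layout_diameter(state$positions)
  max(1e-6 * d, 1e-12)
}

layout_diameter <- function(pos) {
  rx <- range(pos[, 1]); ry <- range(pos[, 2])
  # diameter of the bounding box bounds the true diameter within sqrt(2);
  # adequate for a floor and O(n) to compute
  sqrt(diff(rx)^2 + diff(ry)^2)
}

#' Overlap integral of two isotropic 2-D Gaussians
#'
#' Closed form of `integral g_i(x) g_j(x) dx` for unit-mass isotropic
#' Gaussians with centers `r_i`, `r_j` and standard deviations
#' `sigma_i`, `sigma_j`:
#' `(2 * pi * (sigma_i^2 + sigma_j^2))^-1 * exp(-|r_i - r_j|^2 / (2 * (sigma_i^2 + sigma_j^2)))`.
#'
#' @param r_i,r_j length-2 numeric centers.
#' @param sigma_i,sigma_j positive standard deviations.
#' @return The (strictly positive) overlap value.
#' @examples
#' gaussian_overlap(c(0, 0), c(0, 0), 1, 1)  # 1 / (4 * pi)
#' @export
gaussian_overlap <- function(r_i, r_j, sigma_i, sigma_j) {
  stopifnot(all(is.finite(c(r_i, r_j, sigma_i, sigma_j))),
            sigma_i > 0, sigma_j > 0)
  s <- sigma_i^2 + sigma_j^2
  d2 <- sum((r_i - r_j)^2)
  exp(-d2 / (2 * s)) / (2 * pi * s)
}

# vectorized log-overlaps for a pair index against a layout state; self-pairs
# (i == j) use the node's self-overlap 1 / (4 * pi * sigma_i^2). Returned in
# log space so that distant pairs never underflow before normalization.
pair_log_overlaps <- function(state, pairs) {
  i <- pairs[, 1]; j <- pairs[, 2]
  s <- state$widths[i]^2 + state$widths[j]^2
  d2 <- (state$positions[i, 1] - state$positions[j, 1])^2 +
        (state$positions[i, 2] - state$positions[j, 2])^2
  .entopt_state$overlap_evals <- .entopt_state$overlap_evals + nrow(pairs)
  -log(2 * pi * s) - d2 / (2 * s)
}

#' Representation distribution Q of a layout
#'
#' Normalizes the pairwise Gaussian overlaps of the layout over the target's
#' pair index into a probability distribution; this is the distribution the
#' picture "offers" as a stand-in for the network's target distribution P.
#' Overlaps are computed in log space and floored at 1e-300 before
#' normalization, so very distant pairs degrade gracefully instead of
#' producing NaNs.
#'
#' @param state an [layout_state()] covering the target's nodes.
#' @param target an [build_target()] object supplying the pair index.
#' @return An object of class `entopt_rep`: list with `q` (probabilities
#'   summing to 1) and `log_q` (exact log-probabilities, no underflow).
#' @export
representation <- function(state, target) {
  stopifnot(inherits(state, "entopt_state"), inherits(target, "entopt_target"))
  if (nrow(state$positions) != target$n)
    stop("layout covers ", nrow(state$positions), " nodes, target needs ",
         target$n)
  lo <- pair_log_overlaps(state, target$pairs)
  if (max(lo) < log(1e-300))
    stop("all pairwise overlaps underflowed: degenerate, over-spread layout")
  lo <- pmax(lo, log(1e-300))
  m <- max(lo)
  lz <- m + log(sum(exp(lo - m)))
  structure(list(q = exp(lo - lz), log_q = lo - lz), class = "entopt_rep")
}
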