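#' Score a fixed (foreign) layout by width-only optimization
#'
#' The comparison protocol for layouts produced by any tool: node positions
#' are frozen and only the node probability distributions (the Gaussian
#' widths) are optimized; the resulting normalized information loss D is the
#' layout's score. Widths start from `sigma0` unless the layout table carries
#' a `width` column.
#'
#' @param graph an [weighted_graph()] object.
#' @param positions layout table (`node_id,x,y[,width]` data frame) covering
#'   all graph nodes.
#' @param ... options forwarded to [entopt_config()] (notably `use_square`,
#'   `ignore_square_diagonal`, `max_iter`).
#' @return An `entopt` object with `positions_fixed = TRUE`; its `loss` is
#'   the layout's D.
#' @export
score_layout <- function(graph, positions, ...) {
  opts <- list(...)
  opts$schedule <- "W"
  config <- do.call(entopt_config, opts)
  fit <- entopt_once(graph, config, positions)
  fit$call <- match.call()
  fit
}

#' Fold improvement between two layout losses
#'
#' Ratio of a baseline layout's loss to the entropy-optimized layout's loss,
#' both computed on the same graph and target flags. A zero optimized loss
#' with a positive baseline loss yields `Inf` with attribute
#' `exact_representation = TRUE`, not an error. The ratio is identical
#' whether raw or normalized losses are supplied (the normalizer cancels).
#'
#' @param d_baseline loss of the conventional/baseline layout.
#' @param d_entopt loss of the entropy-optimized layout.
#' @return The fold improvement `d_baseline / d_entopt`.
#' @export
fold_improvement <- function(d_baseline, d_entopt) {
  stopifnot(d_baseline >= 0, d_entopt >= 0)
  if (d_entopt == 0)
    return(structure(if (d_baseline > 0) Inf else 1,
                     exact_representation = TRUE))
  d_baseline / d_entopt
}

#' Module separation of a layout (mean silhouette)
#'
#' Mean silhouette coefficient of the node positions under Euclidean
#' distance with the given module labels: close to 1 when modules form
#' tight, well-separated clusters, near 0 for arbitrary placement, negative
#' when modules overlap badly. Labels with a single member contribute 0, as
#' do nodes whose silhouette denominator is 0 (e.g. all positions
#' coincident). Invariant under translation, rotation and uniform scaling of
#' the layout.
#'
#' @param positions `n x 2` numeric matrix, an [layout_state()], or an
#'   [entopt()] fit.
#' @param labels per-node module identifiers (length `n`, >= 2 distinct).
#' @return A number in `[-1, 1]`.
#' @export
module_separation <- function(positions, labels) {
  if (inherits(positions, "entopt")) positions <- positions$state
  if (inherits(positions, "entopt_state")) positions <- positions$positions
  positions <- as.matrix(positions)
  labels <- as.integer(factor(labels))
  stopifnot(nrow(positions) == length(labels))
  if (length(unique(labels)) < 2)
    stop("module_separation needs at least 2 distinct labels")
  sil <- cluster::silhouette(labels, dist(positions))
  widths <- sil[, "sil_width"]
  widths[!is.finite(widths)] <- 0   # coincident-position convention
  mean(widths)
}

#' Force-directed baseline layout
#'
#' Fruchterman-Reingold coordinates (via igraph) used as the conventional
#' baseline layout and as a recommended pre-ordering for [entopt()]; a good
#' starting point shortens optimization and helps avoid mis-positioned nodes.
#'
#' @param graph an [weighted_graph()] object.
#' @param seed integer seed for the (randomized) algorithm.
#' @param niter number of force-directed iterations.
#' @return Layout table data frame `node_id,x,y,width` (widths 0.1).
#' @export
layout_force_directed <- function(graph, seed = NULL, niter = 500) {
  ig <- igraph::graph_from_edgelist(
    matrix(graph$nodes[graph$edges], ncol = 2), directed = FALSE)
  miss <- setdiff(graph$nodes, igraph::V(ig)$name)
  if (length(miss)) ig <- igraph::add_vertices(ig, length(miss), name = miss)
  igraph::E(ig)$weight <- graph$weights
  xy <- with_seed(seed, igraph::layout_with_fr(ig, niter = niter))
  ord <- match(graph$nodes, igraph::V(ig)$name)
  data.frame(node_id = graph$nodes, x = xy[ord, 1], y = xy[ord, 2],
             width = 0.1)
}

#' Random baseline layout
#'
#' Uniform positions in the unit square; the weakest baseline a layout score
#' should beat.
#'
#' @inheritParams layout_force_directed
#' @param sigma0 width assigned to every node.
#' @return Layout table data frame `node_id,x,y,width`.
#' @export
layout_random <- function(graph, seed = NULL, sigma0 = 0.1) {
  n <- length(graph$nodes)
  pos <- with_seed(seed, matrix(runif(2 * n), n, 2))
  data.frame(node_id = graph$nodes, x = pos[, 1], y = pos[, 2],
             width = sigma0)
}

#' Compare several layouts of one network
#'
#' Scores each layout with the width-only protocol of [score_layout()] (an
#' entry named `entopt`, or any `entopt` fit, is re-scored the same way for
#' fairness) and reports losses plus fold improvements relative to the best
#' layout.
#'
#' @param graph an [weighted_graph()] object.
#' @param layouts named list of >= 2 layout tables (data frames) and/or
#'   [entopt()] fits.
#' @param ... forwarded to [score_layout()] (target flags, iteration caps).
#' @return Data frame with columns `layout_name`, `kl`, `target_entropy`,
#'   `normalized_loss`, `fold_vs_best`, ordered as supplied.
#' @export
compare_layouts <- function(graph, layouts, ...) {
  if (length(layouts) < 2)
    stop("need at least 2 layouts to compare")
  if (is.null(names(layouts)) || any(names(layouts) == ""))
    stop("layouts must be a fully named list")
  rows <- lapply(names(layouts), function(nm) {
    lay <- layouts[[nm]]
    if (inherits(lay, "entopt")) lay <- as_layout_table(lay, graph)
    fit <- score_layout(graph, lay, ...)
    data.frame(layout_name = nm, kl = fit$kl,
               target_entropy = fit$entropy,
               normalized_loss = fit$loss)
  })
  out <- do.call(rbind, rows)
  best <- min(out$normalized_loss)
  out$fold_vs_best <- vapply(out$normalized_loss, fold_improvement,
                             numeric(1), d_entopt = best)
  out
}
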