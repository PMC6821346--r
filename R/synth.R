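#' Planted-partition benchmark graph
#'
#' Equal-size stochastic block model: nodes are split into `n_modules`
#' blocks of `nodes_per_module`; each within-block pair is an edge
#' independently with probability `p_in`, each between-block pair with
#' `p_out < p_in`. Ground-truth module labels come with the graph, standing
#' in for the modular structure (protein complexes) of real interactomes.
#' For benchmark use the graph must be connected; disconnected draws are
#' retried with incremented seeds up to 10 times.
#'
#' @param n_modules number of modules.
#' @param nodes_per_module nodes per module.
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability, `0 <= p_out < p_in <= 1`.
#' @param weight_mode `"unit"` (all weights 1) or `"uniform"` (weights drawn
#'   uniformly from `w_range`).
#' @param w_range length-2 positive range for `"uniform"` weights.
#' @param seed integer seed; the draw is deterministic per seed.
#' @param require_connected retry until connected (default TRUE)?
#' @return List with `graph` (an `entopt_graph`) and `labels` (integer module
#'   assignment per node, names = node ids).
#' @examples
#' pp <- planted_partition(2, 5, 0.9, 0.1, seed = 1)
#' table(pp$labels)
#' @export
planted_partition <- function(n_modules, nodes_per_module, p_in, p_out,
                              weight_mode = c("unit", "uniform"),
                              w_range = c(0.5, 1.5), seed = NULL,
                              require_connected = TRUE) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(n_modules >= 1, nodes_per_module >= 1,
            p_out >= 0, p_out < p_in, p_in <= 1)
  n <- n_modules * nodes_per_module
  if (n < 2) stop("need at least 2 nodes")
  labels <- rep(seq_len(n_modules), each = nodes_per_module)
  nodes <- sprintf("m%d_n%d", labels, sequence(rep(nodes_per_module,
                                                   n_modules)))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- labels[ut[, 1]] == labels[ut[, 2]]
  prob <- ifelse(same, p_in, p_out)
  for (attempt in 0:10) {
    s <- if (is.null(seed)) NULL else seed + attempt
    draw <- with_seed(s, {
      keep <- runif(nrow(ut)) < prob
      w <- if (weight_mode == "unit") rep(1, sum(keep))
           else runif(sum(keep), w_range[1], w_range[2])
      list(keep = keep, w = w)
    })
    edges <- ut[draw$keep, , drop = FALSE]
    if (nrow(edges) == 0) next
    if (!require_connected || is_connected_edges(n, edges)) {
      g <- build_graph(nodes, unname(edges), draw$w,
                       where = "planted partition")
      names(labels) <- nodes
      return(list(graph = g, labels = labels))
    }
    if (is.null(seed)) next
  }
  stop("planted partition stayed disconnected after 10 seed retries; ",
       "increase p_in/p_out or module sizes")
}

is_connected_edges <- function(n, edges) {
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, t(edges))
  igraph::is_connected(ig)
}

#' Ring of cliques benchmark graph
#'
#' `n_cliques` fully connected cliques of `clique_size` nodes, joined into a
#' ring by one bridge edge between consecutive cliques. A deterministic
#' modular graph (no randomness): `n_cliques * choose(clique_size, 2) +
#' n_cliques` edges, always connected, labels = clique membership.
#'
#' @param n_cliques number of cliques (>= 3).
#' @param clique_size nodes per clique (>= 3).
#' @return List with `graph` and `labels` as in [planted_partition()].
#' @export
ring_of_cliques <- function(n_cliques, clique_size) {
  stopifnot(n_cliques >= 3, clique_size >= 3)
  labels <- rep(seq_len(n_cliques), each = clique_size)
  nodes <- sprintf("c%d_n%d", labels,
                   sequence(rep(clique_size, n_cliques)))
  edges <- NULL
  for (c in seq_len(n_cliques)) {
    base <- (c - 1) * clique_size
    idx <- which(upper.tri(matrix(0, clique_size, clique_size)),
                 arr.ind = TRUE)
    edges <- rbind(edges, idx + base)
    nxt <- if (c == n_cliques) 1 else c + 1
    # bridge: last node of this clique to first node of the next
    edges <- rbind(edges, c(base + clique_size,
                            (nxt - 1) * clique_size + 1))
  }
  g <- build_graph(nodes, unname(edges), rep(1, nrow(edges)),
                   where = "ring of cliques")
  names(labels) <- nodes
  list(graph = g, labels = labels)
}

#' Write a benchmark graph and its labels to disk
#'
#' Writes the edge list as TSV (`source target weight`) and the module
#' labels as CSV (`node_id,module`), the formats the rest of the toolchain
#' reads.
#'
#' @param bench list with `graph` and `labels`, as returned by the
#'   generators.
#' @param edges_path output TSV path.
#' @param labels_path optional output CSV path for labels.
#' @return Invisibly, `edges_path`.
#' @export
write_benchmark <- function(bench, edges_path, labels_path = NULL) {
  g <- bench$graph
  tab <- data.frame(source = g$nodes[g$edges[, 1]],
                    target = g$nodes[g$edges[, 2]],
                    weight = g$weights)
  write.table(tab, edges_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(labels_path))
    write.csv(data.frame(node_id = g$nodes,
                         module = unname(bench$labels)),
              labels_path, row.names = FALSE, quote = FALSE)
  invisible(edges_path)
}
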