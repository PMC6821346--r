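#' Construct a weighted undirected graph
#'
#' The basic network container: an ordered node set plus undirected,
#' positively weighted edges stored once each as index pairs `i < j`.
#' Self-loops are not representable; node order is whatever order the ids
#' are supplied in (for files, first-appearance order), which fixes a stable
#' node indexing.
#'
#' @param nodes character vector of unique node identifiers (length >= 2).
#' @param edges two-column matrix of node indices or a two-column character
#'   matrix of node ids; one row per undirected edge.
#' @param weights numeric vector of positive edge weights, recycled from 1.
#' @return An object of class `entopt_graph` with elements `nodes`, `edges`
#'   (integer matrix, `i < j` per row) and `weights`.
#' @examples
#' g <- weighted_graph(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
#' g
#' @export
weighted_graph <- function(nodes, edges, weights = 1) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (length(nodes) < 2) stop("a graph needs at least 2 nodes")
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  if (is.character(edges)) {
    idx <- match(edges, nodes)
    if (anyNA(idx)) stop("edge endpoint not in node set: ",
                         paste(unique(edges[is.na(idx)]), collapse = ", "))
    edges <- matrix(idx, ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  weights <- rep_len(as.numeric(weights), nrow(edges))
  build_graph(nodes, edges, weights)
}

# shared finalization: validates weights, drops self-loops, merges duplicate
# undirected edges by summing weights (both with warnings), sorts each pair
build_graph <- function(nodes, edges, weights, where = "input") {
  if (length(nodes) < 2)
    stop("fewer than 2 nodes in ", where)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("negative or non-finite edge weight in ", where)
  if (nrow(edges) > 0) {
    loop <- edges[, 1] == edges[, 2]
    if (any(loop)) {
      warning(sum(loop), " self-loop(s) dropped from ", where)
      edges <- edges[!loop, , drop = FALSE]
      weights <- weights[!loop]
    }
    zero <- weights == 0
    if (any(zero)) {
      warning(sum(zero), " zero-weight edge(s) dropped from ", where)
      edges <- edges[!zero, , drop = FALSE]
      weights <- weights[!zero]
    }
  }
  if (nrow(edges) > 0) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    key <- paste(edges[, 1], edges[, 2])
    if (anyDuplicated(key)) {
      warning("duplicate undirected edge(s) merged by summing weights in ",
              where)
      weights <- as.numeric(rowsum(weights, key, reorder = FALSE))
      edges <- edges[!duplicated(key), , drop = FALSE]
    }
  }
  structure(list(nodes = nodes, edges = edges, weights = weights),
            class = "entopt_graph")
}

#' @export
print.entopt_graph <- function(x, ...) {
  cat(sprintf("entopt_graph: %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  w <- x$weights
  if (length(w) && !all(w == 1))
    cat(sprintf("  weights in [%g, %g]\n", min(w), max(w)))
  invisible(x)
}

#' Number of nodes / edges of a graph
#' @param graph an [weighted_graph()] object.
#' @return integer count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Dense symmetric adjacency (weight) matrix
#' @param graph an [weighted_graph()] object.
#' @return `n x n` numeric matrix with zero diagonal, dimnames = node ids.
#' @export
adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    W[graph$edges] <- graph$weights
    W[graph$edges[, 2:1, drop = FALSE]] <- graph$weights
  }
  W
}

#' Read a network from an edge-list, SIF or GraphML file
#'
#' Edge lists are whitespace- or tab-separated with an optional third weight
#' column; lines starting with `#` are ignored. SIF rows are
#' `source type target [target ...]`; the interaction type is ignored and all
#' edges get weight 1. GraphML is parsed with igraph and honors a `weight`
#' edge attribute. Unweighted edges get weight 1; duplicate undirected edges
#' are merged by summing weights and self-loops are dropped, each with a
#' warning. Node indexing is deterministic: first appearance in the file.
#'
#' @param path path to the network file.
#' @param format one of `"auto"`, `"edgelist"`, `"sif"`, `"graphml"`. `"auto"`
#'   sniffs GraphML content and otherwise uses the file extension
#'   (`.sif` for SIF, anything else edge list).
#' @return An `entopt_graph` object.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
         edgelist = read_edgelist(path),
         sif = read_sif(path),
         graphml = read_graphml(path))
}

sniff_format <- function(path) {
  head <- tryCatch(readLines(path, n = 5, warn = FALSE), error = function(e) "")
  if (any(grepl("<graphml", head, fixed = TRUE))) return("graphml")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("graphml", "xml")) return("graphml")
  if (ext == "sif") return("sif")
  "edgelist"
}

parse_weight <- function(tok, path, lineno) {
  w <- suppressWarnings(as.numeric(tok))
  if (is.na(w)) stop(sprintf("%s line %d: malformed weight '%s'",
                             path, lineno, tok))
  w
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  from <- character(0); to <- character(0); w <- numeric(0)
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (line == "" || startsWith(line, "#")) next
    tok <- strsplit(line, "[ \t]+")[[1]]
    if (length(tok) < 2 || length(tok) > 3)
      stop(sprintf("%s line %d: expected 2 or 3 fields, got %d",
                   path, k, length(tok)))
    from <- c(from, tok[1]); to <- c(to, tok[2])
    w <- c(w, if (length(tok) == 3) parse_weight(tok[3], path, k) else 1)
  }
  edges_to_graph(from, to, w, path)
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  from <- character(0); to <- character(0); singles <- character(0)
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (line == "" || startsWith(line, "#")) next
    tok <- strsplit(line, if (grepl("\t", line)) "\t" else "[ ]+")[[1]]
    tok <- tok[tok != ""]
    if (length(tok) == 1) { singles <- c(singles, tok); next }
    if (length(tok) == 2)
      stop(sprintf("%s line %d: SIF row needs source, type and target(s)",
                   path, k))
    from <- c(from, rep(tok[1], length(tok) - 2))
    to <- c(to, tok[-(1:2)])
  }
  edges_to_graph(from, to, rep(1, length(from)), path, extra_nodes = singles)
}

edges_to_graph <- function(from, to, w, where, extra_nodes = character(0)) {
  nodes <- unique(c(rbind(from, to), extra_nodes))
  if (any(w < 0)) stop("negative edge weight in ", where)
  edges <- cbind(match(from, nodes), match(to, nodes))
  build_graph(nodes, edges, w, where = where)
}

read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  build_graph(nodes, el, w, where = path)
}

#' Read a layout table (node positions and widths)
#'
#' Accepts a CSV with header columns `node_id,x,y` and optionally `width`,
#' or a GraphML file carrying `x`, `y` (and optionally `width`) node
#' attributes. A missing width column is filled with `default_width`.
#'
#' @param path path to the layout file.
#' @param default_width width assigned when the file carries none
#'   (default 0.1, the optimizer's initial Gaussian standard deviation).
#' @return A data frame with columns `node_id`, `x`, `y`, `width`.
#' @export
read_layout <- function(path, default_width = 0.1) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  if (sniff_format(path) == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    tab <- data.frame(node_id = igraph::vertex_attr(g, "name"),
                      x = igraph::vertex_attr(g, "x"),
                      y = igraph::vertex_attr(g, "y"))
    wv <- igraph::vertex_attr(g, "width")
    tab$width <- if (is.null(wv)) default_width else wv
    if (is.null(tab$x) || is.null(tab$y))
      stop("GraphML layout lacks x/y node attributes: ", path)
    return(tab)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("layout CSV must have header columns node_id,x,y[,width]: ", path)
  for (col in intersect(c("x", "y", "width"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("%s: malformed numeric '%s' in column %s (row %d, node %s)",
                   path, tab[[col]][bad[1]], col, bad[1],
                   tab$node_id[bad[1]]))
    if (anyNA(v))
      stop(sprintf("%s: missing value in column %s (row %d)", path, col,
                   which(is.na(v))[1]))
    tab[[col]] <- v
  }
  if (is.null(tab$width)) tab$width <- default_width
  tab$node_id <- as.character(tab$node_id)
  if (anyDuplicated(tab$node_id))
    stop("duplicate node_id in layout file: ", path)
  tab[c("node_id", "x", "y", "width")]
}

#' Write a layout to CSV or GraphML
#'
#' CSV output has columns `node_id,x,y,width`, one row per node in graph node
#' order. GraphML output stores the graph together with `x`, `y`, `width`
#' node attributes and `weight` edge attributes, so that [read_network()] and
#' [read_layout()] on the written file reproduce both.
#'
#' @param layout a layout state (from [entopt()]/[init_layout()]) or a data
#'   frame with `node_id`, `x`, `y`, `width`.
#' @param graph the `entopt_graph` the layout belongs to.
#' @param path output path.
#' @param format `"csv"` or `"graphml"`.
#' @return Invisibly, the normalized layout data frame that was written.
#' @export
write_layout <- function(layout, graph, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  tab <- as_layout_table(layout, graph)
  tab <- tab[match(graph$nodes, tab$node_id), ]
  if (anyNA(tab$node_id))
    stop("layout does not cover all graph nodes")
  if (format == "csv") {
    write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, quote = FALSE)
  } else {
    ig <- igraph::graph_from_edgelist(
      matrix(graph$nodes[graph$edges], ncol = 2), directed = FALSE)
    miss <- setdiff(graph$nodes, igraph::V(ig)$name)
    if (length(miss)) ig <- igraph::add_vertices(ig, length(miss), name = miss)
    ord <- match(igraph::V(ig)$name, tab$node_id)
    igraph::V(ig)$x <- tab$x[ord]
    igraph::V(ig)$y <- tab$y[ord]
    igraph::V(ig)$width <- tab$width[ord]
    igraph::E(ig)$weight <- graph$weights
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(tab)
}

# coerce a layout state (positions matrix + widths) or data frame to the
# canonical node table
as_layout_table <- function(layout, graph) {
  if (is.data.frame(layout)) {
    if (is.null(layout$width)) layout$width <- 0.1
    return(layout[c("node_id", "x", "y", "width")])
  }
  if (inherits(layout, "entopt"))
    layout <- layout$state
  if (is.list(layout) && !is.null(layout$positions))
    return(data.frame(node_id = graph$nodes,
                      x = layout$positions[, 1],
                      y = layout$positions[, 2],
                      width = layout$widths))
  if (is.matrix(layout) && ncol(layout) >= 2)
    return(data.frame(node_id = graph$nodes, x = layout[, 1], y = layout[, 2],
                      width = if (ncol(layout) >= 3) layout[, 3] else 0.1))
  stop("cannot interpret layout object")
}
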