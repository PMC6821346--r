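#' @export
print.entopt <- function(x, ...) {
  cat("Entropy-optimized network layout\n")
  cat(sprintf("  nodes: %d, edges: %d, target: %s\n",
              length(x$graph$nodes), nrow(x$graph$edges),
              if (x$target$use_square) "squared adjacency" else "adjacency"))
  cat(sprintf("  schedule: %s%s\n", paste(x$config$schedule, collapse = ""),
              if (isTRUE(x$positions_fixed)) " (positions held fixed)" else ""))
  cat(sprintf("  KL divergence: %.6g nats,  H(P): %.6g nats\n",
              x$kl, x$entropy))
  cat(sprintf("  normalized information loss D: %.6g%s\n", x$loss,
              if (!x$normalized) " (H(P) = 0; raw KL reported)" else ""))
  invisible(x)
}

#' Summarize an entropy-optimized layout
#'
#' @param object an [entopt()] fit.
#' @param ... unused.
#' @return The fit, invisibly, after printing the loss, the per-phase loss
#'   trace endpoints, and the width range.
#' @export
summary.entopt <- function(object, ...) {
  print(object)
  tr <- object$trace
  last <- tr[!duplicated(tr$phase, fromLast = TRUE), ]
  cat("  loss at phase ends:\n")
  for (k in seq_len(nrow(last)))
    cat(sprintf("    %-4s iter %4d   D = %.6g\n",
                last$phase[k], last$iteration[k], last$loss[k]))
  cat(sprintf("  widths: [%.4g, %.4g]\n",
              min(object$state$widths), max(object$state$widths)))
  invisible(object)
}

#' Extract the fitted layout coordinates
#'
#' @param object an [entopt()] fit.
#' @param ... unused.
#' @return Matrix with one row per node (rownames = node ids) and columns
#'   `x`, `y`, `width`.
#' @export
coef.entopt <- function(object, ...) {
  out <- cbind(object$state$positions, object$state$widths)
  dimnames(out) <- list(object$graph$nodes, c("x", "y", "width"))
  out
}

#' Fitted representation distribution Q
#'
#' @param object an [entopt()] fit.
#' @param ... unused.
#' @return Numeric vector of pair probabilities over the target's pair index.
#' @export
fitted.entopt <- function(object, ...) {
  representation(object$state, object$target)$q
}

#' Pairwise residuals p - q
#'
#' The signed discrepancy between the target and representation
#' probabilities on each node pair; large positive values mark edges the
#' layout under-represents (nodes drawn too far apart or too narrow).
#'
#' @param object an [entopt()] fit.
#' @param ... unused.
#' @return Numeric vector `p - q` over the target's pair index, with pair
#'   labels `"i--j"` as names.
#' @export
residuals.entopt <- function(object, ...) {
  r <- object$target$p - fitted(object)
  names(r) <- paste(object$target$nodes[object$target$pairs[, 1]],
                    object$target$nodes[object$target$pairs[, 2]],
                    sep = "--")
  r
}

#' Plot an entropy-optimized layout
#'
#' Draws edges as segments and nodes as circles whose radii are the fitted
#' Gaussian widths, optionally colored by module labels.
#'
#' @param x an [entopt()] fit.
#' @param labels optional per-node module labels (factor or vector, graph
#'   node order) used for colors.
#' @param edge_col edge segment color.
#' @param ... passed to [graphics::plot()].
#' @return The fit, invisibly.
#' @export
plot.entopt <- function(x, labels = NULL, edge_col = "grey70", ...) {
  pos <- x$state$positions
  w <- x$state$widths
  col <- if (is.null(labels)) "steelblue"
         else grDevices::hcl.colors(length(unique(labels)),
                                    "Dark 3")[as.integer(factor(labels))]
  graphics::plot(pos, type = "n", asp = 1, xlab = "x", ylab = "y",
                 main = sprintf("D = %.4g", x$loss), ...)
  if (nrow(x$graph$edges))
    graphics::segments(pos[x$graph$edges[, 1], 1], pos[x$graph$edges[, 1], 2],
                       pos[x$graph$edges[, 2], 1], pos[x$graph$edges[, 2], 2],
                       col = edge_col)
  graphics::symbols(pos[, 1], pos[, 2], circles = w, inches = FALSE,
                    add = TRUE, fg = col, bg = grDevices::adjustcolor(col, 0.4))
  invisible(x)
}
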