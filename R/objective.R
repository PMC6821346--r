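#' Relative entropy (Kullback-Leibler divergence) D(P || Q)
#'
#' `sum over pairs with p > 0 of p * log(p / q)` in nats; pairs with `p = 0`
#' contribute exactly zero. This is the information lost when the layout's
#' representation distribution Q stands in for the network's target
#' distribution P. Non-negative, and zero iff P = Q on the support of P.
#'
#' @param target an [build_target()] object.
#' @param rep an [representation()] object over the same pair index.
#' @return Non-negative divergence in nats.
#' @export
relative_entropy <- function(target, rep) {
  stopifnot(inherits(target, "entopt_target"), inherits(rep, "entopt_rep"))
  if (length(rep$q) != nrow(target$pairs))
    stop("target and representation are over different pair indexes")
  on <- target$p > 0
  if (any(rep$log_q[on] == -Inf))
    stop("q = 0 on a pair with p > 0: corrupted representation")
  # non-negative by Gibbs' inequality; clamp the ~1e-16 roundoff at P = Q
  max(0, sum(target$p[on] * (log(target$p[on]) - rep$log_q[on])))
}

#' Shannon entropy H(P) of the target distribution
#'
#' `-sum over p > 0 of p * log(p)` in nats; the normalizer of the layout
#' quality score D.
#'
#' @param target an [build_target()] object.
#' @return Non-negative entropy in nats.
#' @export
target_entropy <- function(target) {
  stopifnot(inherits(target, "entopt_target"))
  p <- target$p[target$p > 0]
  -sum(p * log(p))
}

#' Normalized information loss D
#'
#' The layout quality score: KL divergence divided by the target entropy,
#' a dimensionless loss comparable across networks of different sizes.
#' When `H(P) = 0` (a single-pair target) the raw divergence is returned
#' unchanged and flagged via the `"normalized"` attribute.
#'
#' @param kl non-negative KL divergence in nats.
#' @param target the [build_target()] object that produced it.
#' @return The normalized loss, with attribute `normalized` (logical).
#' @export
normalized_loss <- function(kl, target) {
  stopifnot(kl >= 0)
  h <- target_entropy(target)
  if (h > 0) structure(kl / h, normalized = TRUE)
  else structure(kl, normalized = FALSE)
}

#' Analytic gradients of the KL loss
#'
#' Exact gradient of `relative_entropy(target, representation(state, target))`
#' with respect to every node position and width, including the coupling term
#' from the normalization of Q. With overlaps `o_k` and `Z = sum o_k`,
#' `dD/dtheta = sum_k (q_k - p_k) * dlog(o_k)/dtheta`, and for a pair
#' `(i, j)` with `s = sigma_i^2 + sigma_j^2`:
#' `dlog(o)/dr_i = -(r_i - r_j) / s` and
#' `dlog(o)/dsigma_i = 2 * sigma_i * (d^2 / (2 s^2) - 1 / s)`;
#' a self-pair `(i, i)` contributes `-2 / sigma_i` to the width gradient
#' and nothing to the position gradient.
#'
#' @param state an [layout_state()].
#' @param target an [build_target()] object.
#' @return List with `position` (`n x 2` matrix) and `width` (length-`n`
#'   vector) gradients, plus the current `kl` and `rep` so callers can reuse
#'   them.
#' @export
loss_gradients <- function(state, target) {
  rep <- representation(state, target)
  pairs <- target$pairs
  i <- pairs[, 1]; j <- pairs[, 2]
  off <- i != j
  coef <- rep$q - target$p            # (q - p) per pair
  n <- target$n
  gpos <- matrix(0, n, 2)
  gwid <- numeric(n)

  if (any(off)) {
    io <- i[off]; jo <- j[off]
    s <- state$widths[io]^2 + state$widths[jo]^2
    dx <- state$positions[io, 1] - state$positions[jo, 1]
    dy <- state$positions[io, 2] - state$positions[jo, 2]
    d2 <- dx^2 + dy^2
    cf <- coef[off]
    # position gradient: dD/dr_i = sum_j (q - p) * (-(r_i - r_j) / s)
    gx <- -cf * dx / s
    gy <- -cf * dy / s
    gpos[, 1] <- accumulate_by_node(c(gx, -gx), c(io, jo), n)
    gpos[, 2] <- accumulate_by_node(c(gy, -gy), c(io, jo), n)
    # width gradient through s for both endpoints
    dlds <- cf * (d2 / (2 * s^2) - 1 / s)
    gwid <- accumulate_by_node(
      c(2 * state$widths[io] * dlds, 2 * state$widths[jo] * dlds),
      c(io, jo), n)
  }
  if (any(!off)) {
    id <- i[!off]
    gwid[id] <- gwid[id] + coef[!off] * (-2 / state$widths[id])
  }
  list(position = gpos, width = gwid,
       kl = relative_entropy(target, rep), rep = rep)
}

accumulate_by_node <- function(values, nodes, n) {
  out <- numeric(n)
  acc <- rowsum(values, nodes)
  out[as.integer(rownames(acc))] <- acc
  out
}
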