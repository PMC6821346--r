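# shared fixtures and independent oracles, built in code at test time

k3 <- function() weighted_graph(c("A", "B", "C"),
                                rbind(c(1, 2), c(2, 3), c(1, 3)))

path3 <- function() weighted_graph(c("A", "B", "C"),
                                   rbind(c(1, 2), c(2, 3)))

dyad <- function() weighted_graph(c("A", "B"), rbind(c(1, 2)))

# equilateral triangle layout with equal widths: exact representation of K3
equilateral_state <- function(width = 0.3) {
  layout_state(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)), width)
}

# independent finite-difference oracle for the loss gradients
fd_gradients <- function(state, target, h_rel = 1e-6) {
  f <- function(st) relative_entropy(target, representation(st, target))
  n <- nrow(state$positions)
  gp <- matrix(0, n, 2)
  gw <- numeric(n)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      h <- h_rel * max(1, abs(state$positions[i, d]))
      sp <- state; sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- state; sm$positions[i, d] <- sm$positions[i, d] - h
      gp[i, d] <- (f(sp) - f(sm)) / (2 * h)
    }
    h <- h_rel * max(1, state$widths[i])
    sp <- state; sp$widths[i] <- sp$widths[i] + h
    sm <- state; sm$widths[i] <- sm$widths[i] - h
    gw[i] <- (f(sp) - f(sm)) / (2 * h)
  }
  list(position = gp, width = gw)
}

rel_vec_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-12)

# random connected-ish test graph with a random layout state
random_case <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < p
  if (sum(keep) < 1) keep[1] <- TRUE
  g <- weighted_graph(sprintf("n%d", 1:n), ut[keep, , drop = FALSE],
                      runif(sum(keep), 0.5, 2))
  st <- layout_state(matrix(runif(2 * n), n, 2), runif(n, 0.05, 0.5))
  list(graph = g, state = st)
}
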