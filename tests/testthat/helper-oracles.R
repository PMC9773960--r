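# Independent brute-force oracle for the mean-constrained fit: exhaustive
# grid search over the mean-constrained slice of the probability simplex
# (the constraints pin down the last two coordinates, so K = 3 is a 1-D
# grid and K = 4 a 2-D grid), followed by a local refinement pass around
# the grid minimiser. Returns the minimal objective found.
oracle_min_objective <- function(p, v, m, step = 1e-3) {
  K <- length(v)
  stopifnot(K %in% c(3L, 4L))
  objective <- function(qm) {
    # qm: matrix with K columns of candidate distributions
    ok <- rowSums(qm < -1e-9) == 0
    obj <- rep(Inf, nrow(qm))
    idx <- which(p > 0)
    if (any(ok)) {
      qs <- pmax(qm[ok, idx, drop = FALSE], 1e-300)
      obj[ok] <- as.vector(log(qs) %*% (-p[idx])) + sum(p[idx] * log(p[idx]))
    }
    obj
  }
  candidates <- function(g1, g2 = NULL) {
    if (K == 3L) {
      q1 <- g1
      q3 <- (m - v[1] * q1 - v[2] * (1 - q1)) / (v[3] - v[2])
      cbind(q1, 1 - q1 - q3, q3)
    } else {
      g <- expand.grid(q1 = g1, q2 = g2)
      s <- 1 - g$q1 - g$q2
      t <- m - v[1] * g$q1 - v[2] * g$q2
      q4 <- (t - v[3] * s) / (v[4] - v[3])
      cbind(g$q1, g$q2, s - q4, q4)
    }
  }
  g <- seq(0, 1, by = step)
  qm <- candidates(g, g)
  obj <- objective(qm)
  best <- which.min(obj)
  # refinement: ±1 coarse cell around the argmin at 1/50 of the step
  refine <- function(center) {
    seq(max(0, center - step), min(1, center + step), by = step / 50)
  }
  qm2 <- if (K == 3L) candidates(refine(qm[best, 1])) else
    candidates(refine(qm[best, 1]), refine(qm[best, 2]))
  min(min(obj), min(objective(qm2)))
}

# Independent base-2 KL / Jensen-Shannon oracle, written directly from the
# definition (0 * log 0 = 0).
oracle_jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl2 <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl2(p, m) + kl2(q, m)) / 2
}

# Kolmogorov distance of a sample from the uniform(0,1) distribution.
ks_uniform <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(abs(x - seq_len(n) / n), abs(x - (seq_len(n) - 1) / n))
}
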