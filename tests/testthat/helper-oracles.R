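# Independent oracles used by the tests. These deliberately share no code
# with the implementation paths they check.

# Joint-likelihood maximization by cyclic coordinate-wise grid ascent,
# staged resolution 0.1 -> 0.01 -> 0.001 over [-6, 6]. Identification by
# post-hoc centering (the likelihood is invariant to a common shift).
grid_jmle <- function(X, lo = -6, hi = 6, steps = c(0.1, 0.01, 0.001)) {
  N <- nrow(X); L <- ncol(X)
  rs <- rowSums(X); cs <- colSums(X)
  stopifnot(all(rs > 0 & rs < L), all(cs > 0 & cs < N)) # no extremes
  th <- rep(0, N); de <- rep(0, L)
  for (st in steps) {
    for (sweep in 1:500) {
      moved <- FALSE
      for (i in seq_len(N)) {
        g <- if (st == steps[1]) seq(lo, hi, by = st) else
          seq(max(lo, th[i] - 25 * st), min(hi, th[i] + 25 * st), by = st)
        ll <- g * rs[i] - rowSums(log1p(exp(outer(g, de, "-"))))
        tnew <- g[which.max(ll)]
        if (abs(tnew - th[i]) > st / 2) moved <- TRUE
        th[i] <- tnew
      }
      for (j in seq_len(L)) {
        g <- if (st == steps[1]) seq(lo, hi, by = st) else
          seq(max(lo, de[j] - 25 * st), min(hi, de[j] + 25 * st), by = st)
        ll <- -g * cs[j] - colSums(log1p(exp(outer(th, g, "-"))))
        dnew <- g[which.max(ll)]
        if (abs(dnew - de[j]) > st / 2) moved <- TRUE
        de[j] <- dnew
      }
      if (!moved) break
    }
  }
  ctr <- mean(de)
  list(theta = th - ctr, delta = de - ctr)
}

# Fixed-grid trapezoid quadrature of the cohort-averaged sensitivity.
trap_sensitivity <- function(delta, mean = -0.6, sd = 1, n = 1e4) {
  th <- seq(mean - 8 * sd, mean + 8 * sd, length.out = n)
  p <- plogis(th - delta)
  f <- dnorm(th, mean, sd) * (-p * (1 - p))
  sum((f[-1] + f[-n]) / 2) * (th[2] - th[1])
}

# Minimal hand-built rasch_fit for unit tests that need exact parameters.
forge_fit <- function(theta, delta, theta_se = NULL, delta_se = NULL) {
  structure(list(
    theta = theta, theta_se = theta_se %||% rep(0.3, length(theta)),
    delta = delta, delta_se = delta_se %||% rep(0.2, length(delta)),
    person_extreme = rep(FALSE, length(theta)),
    item_extreme = rep(FALSE, length(delta)),
    convergence = list(iterations = 0L, last_change = 0, converged = TRUE),
    theta_mean = mean(theta), theta_sd = sd(theta),
    groups = NULL, control = rasch_control()
  ), class = "rasch_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small non-extreme binary matrices for oracle comparisons.
oracle_matrices <- function() {
  list(
    m3x3 = matrix(c(1, 0, 1,
                    0, 1, 0,
                    1, 1, 0), 3, 3, byrow = TRUE),
    m4x3 = matrix(c(1, 0, 0,
                    1, 1, 0,
                    0, 1, 1,
                    1, 0, 1), 4, 3, byrow = TRUE),
    m5x4 = matrix(c(1, 1, 0, 0,
                    0, 1, 1, 0,
                    1, 0, 1, 1,
                    0, 1, 0, 1,
                    1, 0, 1, 0), 5, 4, byrow = TRUE),
    m5x4b = matrix(c(1, 1, 1, 0,
                     1, 0, 0, 1,
                     0, 1, 1, 0,
                     0, 0, 1, 1,
                     1, 1, 0, 0), 5, 4, byrow = TRUE)
  )
}
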