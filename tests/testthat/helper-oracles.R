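# Independent oracles, deliberately written against the model definitions
# rather than the package internals they check.

# Brute-force latent-class pattern probability: explicit sum over the two
# latent classes with scalar loops over callers.
oracle_ci_prob <- function(eta, fp, fn, y) {
  p0 <- 1 - eta
  p1 <- eta
  for (k in seq_along(y)) {
    p0 <- p0 * if (y[k] == 1) fp[k] else 1 - fp[k]
    p1 <- p1 * if (y[k] == 1) 1 - fn[k] else fn[k]
  }
  p0 + p1
}

# Adaptive numerical integration of the random-effects pattern probability
# over the standard-normal random effect.
oracle_re_prob <- function(eta, a0, a1, sigma, y) {
  class_int <- function(a) {
    f <- function(b) {
      out <- dnorm(b)
      for (k in seq_along(y)) {
        pk <- pnorm(a[k] + sigma * b)
        out <- out * if (y[k] == 1) pk else 1 - pk
      }
      out
    }
    integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  (1 - eta) * class_int(a0) + eta * class_int(a1)
}

# Marginal detection probability under the random-effects probit, by
# numerical integration (checks the closed form Phi(a / sqrt(1+sigma^2))).
oracle_re_marginal <- function(a, sigma) {
  integrate(function(b) pnorm(a + sigma * b) * dnorm(b),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# Best log-likelihood over a dense grid of CI parameterizations with a
# common fp and fn across the K callers (a subset of the full parameter
# space, so its maximum is a valid lower bound for the MLE).
oracle_grid_loglik <- function(counts, step = 0.02) {
  K <- attr(counts, "K")
  bits <- do.call(rbind, lapply(strsplit(names(counts), ""), as.integer))
  n <- as.numeric(counts)
  s <- rowSums(bits)
  grid <- seq(step, 1 - step, by = step)
  best <- -Inf
  for (eta in grid) {
    for (fp in grid) {
      p0 <- fp^s * (1 - fp)^(K - s)
      for (fn in grid) {
        p1 <- (1 - fn)^s * fn^(K - s)
        ll <- sum(n * log(pmax((1 - eta) * p0 + eta * p1, 1e-12)))
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# Multinomial draw of a pattern-count table from CI parameters.
draw_ci_counts <- function(eta, fp, fn, N, callers = NULL) {
  params <- lcm_ci_params(eta, fp, fn)
  p <- ci_pattern_prob(params)
  x <- rmultinom(1, N, p)[, 1]
  pattern_counts(setNames(as.integer(x), names(p)), callers = callers)
}
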