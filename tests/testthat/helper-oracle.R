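# Independent oracles, deliberately written against different
# parameterizations than the package's fitters.

# Reduced (no-interaction) log-binomial MLE on four exposure cells, by direct
# optimization over the three cell survival probabilities (log scale), with
# the combination cell tied to the Bliss product p_A * p_B / p_0.
oracle_reduced_loglik <- function(k, n) {
  negll <- function(th) {
    eta <- c(th[1], th[1] + th[2], th[1] + th[3], th[1] + th[2] + th[3])
    if (any(eta > -1e-12)) return(1e10)
    -sum(k * eta + (n - k) * log1p(-exp(eta)))
  }
  start <- log(pmin((k + 0.5) / (n + 1), 0.99))
  o <- stats::optim(c(start[1], start[2] - start[1], start[3] - start[1]),
                    negll, method = "Nelder-Mead",
                    control = list(maxit = 50000, reltol = 1e-14))
  o <- stats::optim(o$par, negll, method = "Nelder-Mead",
                    control = list(maxit = 50000, reltol = 1e-15))
  -o$value
}

# saturated log-binomial log-likelihood: fitted probabilities are the
# observed proportions
oracle_saturated_loglik <- function(k, n) {
  p <- k / n
  sum(k * log(p) + (n - k) * ifelse(n > k, log(1 - p), 0))
}

# plain Newton-Raphson for the logistic model (no stats::glm machinery)
oracle_logit_fit <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    step <- solve(crossprod(X, X * W), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  unname(beta)
}
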