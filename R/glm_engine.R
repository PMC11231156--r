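#' Fit a binomial GLM for binary survival with a log or logit link
#'
#' With `link = "log"` coefficients are log survival-probability ratios
#' (relative risks), and the Bernoulli likelihood is maximized subject to the
#' linear constraint that every distinct covariate pattern has linear
#' predictor `eta <= 0` (fitted survival probability at most 1). This is a
#' linearly constrained concave program solved by a log-barrier method with
#' decreasing barrier weight and BFGS inner steps, started at the log of
#' group-level empirical survival shrunk toward (k + 0.5)/(n + 1) so the start
#' is strictly feasible; the procedure is deterministic. With
#' `link = "logit"` the fit is ordinary unconstrained IRLS via
#' [stats::glm.fit()].
#'
#' @param design Numeric design matrix, full column rank, with named columns;
#'   the first column is the intercept.
#' @param outcomes Binary outcome vector (1 = survived), one per design row.
#' @param link `"log"` or `"logit"`.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum inner iterations per barrier stage.
#' @return An object of class `binom_fit`: `link`, named `coefficients`,
#'   `loglik` (nats), `fitted` (per-row survival probabilities), `converged`,
#'   `boundary` (some constraint active at the optimum, log link only),
#'   `eta_max`, `vcov` (inverse observed information; `NULL` at a boundary
#'   solution), `n`, and the aggregated covariate patterns.
#' @examples
#' X <- cbind(`(Intercept)` = 1, x_A = c(0, 1, 0, 1), x_B = c(0, 0, 1, 1),
#'            `x_A:x_B` = c(0, 0, 0, 1))
#' X <- X[rep(1:4, each = 10), ]
#' y <- rep(c(1, 1, 1, 0), 10)
#' fit_binomial_glm(X, y, link = "log")
#' @export
fit_binomial_glm <- function(design, outcomes, link = c("log", "logit"),
                             tol = 1e-10, max_iter = 500L) {
  link <- match.arg(link)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("V", seq_len(ncol(design)))
  stopifnot(nrow(design) == length(outcomes), all(outcomes %in% c(0, 1)))
  if (all(outcomes == 1) || all(outcomes == 0))
    stop("outcomes must contain at least one death and one survivor",
         call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient", call. = FALSE)

  # aggregate to distinct covariate patterns: likelihood only depends on
  # per-pattern success counts
  key <- apply(design, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  U <- design[first, , drop = FALSE]
  idx <- match(key, key[first])
  n_j <- as.vector(tabulate(idx, nbins = nrow(U)))
  k_j <- as.vector(rowsum(as.numeric(outcomes), idx)[, 1])

  if (link == "logit") {
    fit <- stats::glm.fit(design, outcomes,
                          family = stats::binomial("logit"),
                          control = stats::glm.control(epsilon = tol,
                                                       maxit = max_iter))
    beta <- fit$coefficients
    eta <- drop(design %*% beta)
    p <- stats::plogis(eta)
    ll <- bernoulli_loglik(p, outcomes)
    info <- crossprod(design * sqrt(p * (1 - p)))
    res <- new_binom_fit(link, beta, ll, p, fit$converged, FALSE,
                         max(eta), solve(info), length(outcomes), U, k_j, n_j)
    return(res)
  }

  degenerate <- which(k_j == 0)
  if (length(degenerate) > 0) {
    pat <- apply(U[degenerate, , drop = FALSE], 1, paste, collapse = ",")
    stop("degenerate group under log link (zero survivors) for covariate pattern(s): ",
         paste(pat, collapse = "; "), call. = FALSE)
  }

  # strictly feasible start: shrunken empirical log-survival per pattern,
  # least-squares projected onto the column space
  eta0 <- log((k_j + 0.5) / (n_j + 1))
  beta <- qr.solve(U, eta0)
  eta <- drop(U %*% beta)
  if (max(eta) > -1e-8) beta[1] <- beta[1] - (max(eta) + 1e-4)

  negll <- function(b) {
    e <- drop(U %*% b)
    if (any(e >= 0)) return(.Machine$double.xmax / 4)
    -sum(k_j * e + (n_j - k_j) * log1p(-exp(e)))
  }
  obj <- function(b, mu) {
    e <- drop(U %*% b)
    if (any(e >= 0)) return(.Machine$double.xmax / 4)
    -sum(k_j * e + (n_j - k_j) * log1p(-exp(e))) - mu * sum(log(-e))
  }
  grad <- function(b, mu) {
    e <- drop(U %*% b)
    ex <- exp(e)
    de <- -(k_j - (n_j - k_j) * ex / (1 - ex)) - mu / e
    drop(crossprod(U, de))
  }

  prev <- negll(beta)
  converged <- TRUE
  for (mu in 10^seq(-2, -9, by = -1)) {
    o <- stats::optim(beta, obj, grad, mu = mu, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-15))
    beta <- o$par
    cur <- negll(beta)
    converged <- o$convergence %in% c(0L, 1L)
    if (o$convergence == 1L && abs(cur - prev) > tol * (abs(cur) + 1))
      converged <- FALSE
    prev <- cur
  }
  if (!converged)
    warning("log-binomial fit did not converge within max_iter", call. = FALSE)

  # Newton polish: at a strictly interior optimum the barrier bias is
  # removable; damped Newton steps on the unpenalized likelihood converge
  # quadratically and feasibility is enforced by step halving
  for (it in seq_len(50L)) {
    e <- drop(U %*% beta)
    if (max(e) > -1e-5) break
    ex <- exp(e)
    gvec <- k_j - (n_j - k_j) * ex / (1 - ex)
    h <- (n_j - k_j) * ex / (1 - ex)^2
    score <- drop(crossprod(U, gvec))
    H <- crossprod(U * sqrt(pmax(h, 1e-12)))
    step <- tryCatch(solve(H, score), error = function(err) NULL)
    if (is.null(step)) break
    f0 <- negll(beta)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (negll(cand) <= f0 + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- beta; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    if (moved < 1e-12) break
  }

  eta <- drop(U %*% beta)
  boundary <- max(eta) > -1e-6
  fitted <- exp(pmin(drop(design %*% beta), 0))
  ll <- -negll(beta)
  vcov <- NULL
  if (!boundary) {
    ex <- exp(eta)
    # observed information: -d2 ll / d eta_j^2 = (n_j - k_j) e^eta/(1-e^eta)^2
    h <- (n_j - k_j) * ex / (1 - ex)^2
    info <- crossprod(U * sqrt(h))
    vcov <- tryCatch(solve(info), error = function(e) NULL)
  }
  names(beta) <- colnames(design)
  new_binom_fit("log", beta, ll, fitted, converged, boundary, max(eta), vcov,
                length(outcomes), U, k_j, n_j)
}

new_binom_fit <- function(link, beta, ll, fitted, converged, boundary,
                          eta_max, vcov, n, patterns, k_j, n_j) {
  structure(
    list(link = link, coefficients = beta, loglik = ll, fitted = fitted,
         converged = converged, boundary = boundary, eta_max = eta_max,
         vcov = vcov, n = n, patterns = patterns, k = k_j, n_pattern = n_j),
    class = "binom_fit"
  )
}

bernoulli_loglik <- function(p, y) {
  ll <- numeric(length(y))
  ll[y == 1] <- log(p[y == 1])
  q <- 1 - p[y == 0]
  ll[y == 0] <- ifelse(q > 0, log(q), -Inf)
  sum(ll)
}

#' Bernoulli log-likelihood of a fit on given data
#'
#' Evaluates the Bernoulli log-likelihood at a fit's coefficients on a
#' conformable design and outcome vector (in nats; always `<= 0`).
#'
#' @param fit A `binom_fit`.
#' @param design Design matrix conformable with the fit's coefficients.
#' @param outcomes Binary outcomes.
#' @return The log-likelihood in nats.
#' @export
log_likelihood <- function(fit, design, outcomes) {
  eta <- drop(as.matrix(design) %*% fit$coefficients)
  p <- if (fit$link == "log") exp(pmin(eta, 0)) else stats::plogis(eta)
  bernoulli_loglik(p, outcomes)
}

#' Likelihood-ratio statistic for nested binomial fits
#'
#' `2 * (loglik_full - loglik_reduced)`. The reduced model's columns must be a
#' strict subset of the full model's, on the same data. Tiny negative values
#' (numerical noise at an interior optimum near the null) are clamped to zero
#' with a warning.
#'
#' @param full,reduced `binom_fit` objects on the same data.
#' @return Nonnegative LR statistic.
#' @export
lr_statistic <- function(full, reduced) {
  full_cols <- colnames(full$patterns)
  red_cols <- colnames(reduced$patterns)
  if (!all(red_cols %in% full_cols) || full$n != reduced$n)
    stop("models are not nested on the same data", call. = FALSE)
  lr <- 2 * (full$loglik - reduced$loglik)
  if (lr < 0) {
    if (lr > -1e-6) {
      warning("clamping tiny negative LR statistic to 0", call. = FALSE)
      lr <- 0
    } else {
      stop("negative LR statistic: models are not nested or fits failed",
           call. = FALSE)
    }
  }
  lr
}

#' Upper-tail chi-squared probability
#'
#' `P(chi^2_df > stat)`, the reference p-value of the likelihood-ratio test.
#'
#' @param stat Nonnegative test statistic.
#' @param df Degrees of freedom (>= 1).
#' @return p-value in (0, 1].
#' @examples
#' chi2_upper_tail(3.841, 1)
#' @export
chi2_upper_tail <- function(stat, df = 1L) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stopifnot(is.finite(stat), stat >= 0)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' @export
print.binom_fit <- function(x, ...) {
  cat(sprintf("<binom_fit> link = %s, n = %d, logLik = %.4f\n",
              x$link, x$n, x$loglik))
  print(round(x$coefficients, 5))
  if (x$boundary) cat("note: boundary solution (some fitted p at 1)\n")
  if (!x$converged) cat("warning: did not converge\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binomial survival GLM fit
#'
#' @param x A `binom_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`, and
#'   `std.error` when the observed information is available).
#' @export
tidy.binom_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients))
  if (!is.null(x$vcov)) out$std.error <- sqrt(diag(x$vcov))
  out
}

#' One-row summary of a binomial survival GLM fit
#'
#' @param x A `binom_fit`.
#' @param ... Unused.
#' @return A one-row tibble: link, log-likelihood, number of coefficients,
#'   observations, convergence and boundary flags.
#' @export
glance.binom_fit <- function(x, ...) {
  tibble::tibble(link = x$link, logLik = x$loglik,
                 df = length(x$coefficients), nobs = x$n,
                 converged = x$converged, boundary = x$boundary)
}

#' Serialize a fit to JSON
#'
#' @param fit A `binom_fit`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(link = fit$link, terms = names(fit$coefficients),
              coefficients = unname(fit$coefficients), loglik = fit$loglik,
              converged = fit$converged, boundary = fit$boundary)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
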