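nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-8) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

nb_deviance <- function(y, mu, phi) {
  # unit deviances of the NB with fixed phi (Poisson limit for tiny phi)
  yp <- pmax(y, 1e-10)
  if (phi < 1e-8) {
    2 * sum(y * log(yp / mu) - (y - mu))
  } else {
    2 * sum(y * log(yp / mu) -
              (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

#' Fit a univariate negative-binomial GLM
#'
#' Maximum-likelihood fit of the model
#' \deqn{\log \mu_i = \log(N_i f_i) + b_0 + b_1 x_i}
#' at fixed dispersion `phi` (variance \eqn{\mu + \phi \mu^2}), by
#' iteratively reweighted least squares with a log link. With `x = NULL`
#' the intercept-only null model is fit, for use with [lr_test()].
#'
#' @param y Non-negative integer counts, one per sample.
#' @param x Numeric covariate with at least two distinct values, or `NULL`
#'   for the null model.
#' @param norm Normalization list from [tmm_norm_factors()] (or a numeric
#'   vector of offsets on the natural-log scale).
#' @param phi Negative-binomial dispersion, >= 0.
#' @param tol Relative deviance change declaring convergence.
#' @param max_iter Iteration cap.
#' @return A list of class `"nb_glm_fit"`: `coef` (b0 and, when `x` given,
#'   b1 on the natural-log scale per covariate unit), `loglik`,
#'   `deviance`, `fitted`, `phi`, `converged`, `iter`.
#' @export
fit_nb_glm <- function(y, x = NULL, norm, phi, tol = 1e-8, max_iter = 100L) {
  offset <- if (is.list(norm)) log(norm$lib_sizes * norm$factors) else norm
  n <- length(y)
  if (length(offset) != n) {
    stop("offset/normalization length must match counts", call. = FALSE)
  }
  has_x <- !is.null(x)
  if (has_x) {
    if (length(x) != n) stop("covariate length mismatch", call. = FALSE)
    if (anyNA(x)) stop("covariate contains missing values", call. = FALSE)
    if (length(unique(x)) < 2L) {
      stop("E_DEGENERATE: covariate is constant", call. = FALSE)
    }
  }
  if (sum(y) == 0) stop("all-zero count vector; filter taxa first",
                        call. = FALSE)

  b0 <- log(sum(y) / sum(exp(offset)))
  b1 <- 0
  eta0 <- b0 + if (has_x) b1 * x else 0
  dev <- nb_deviance(y, exp(clamp(eta0, -30, 30) + offset), phi)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- b0 + if (has_x) b1 * x else 0
    eta <- clamp(eta, -30, 30)
    mu <- exp(eta + offset)
    w <- mu / (1 + phi * mu)
    if (any(!is.finite(w)) || all(w == 0)) {
      stop(sprintf(
        "non-finite working weights at iteration %d (b0=%.3g, b1=%.3g)",
        iter, b0, b1), call. = FALSE)
    }
    z <- eta + (y - mu) / mu
    if (has_x) {
      sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
      swz <- sum(w * z); swxz <- sum(w * x * z)
      det <- sw * swxx - swx^2
      if (!is.finite(det) || abs(det) < 1e-12 * sw * max(swxx, 1)) {
        stop("E_DEGENERATE: singular design in IRLS", call. = FALSE)
      }
      b0 <- (swxx * swz - swx * swxz) / det
      b1 <- (sw * swxz - swx * swz) / det
    } else {
      b0 <- sum(w * z) / sum(w)
    }
    eta <- clamp(b0 + if (has_x) b1 * x else 0, -30, 30)
    dev_new <- nb_deviance(y, exp(eta + offset), phi)
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  mu <- exp(clamp(b0 + if (has_x) b1 * x else 0, -30, 30) + offset)
  structure(list(
    coef = if (has_x) c(b0 = b0, b1 = b1) else c(b0 = b0),
    loglik = nb_loglik(y, mu, phi),
    deviance = dev, fitted = mu, phi = phi,
    converged = converged, iter = iter, n = n
  ), class = "nb_glm_fit")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Likelihood-ratio test of two nested NB GLM fits
#'
#' Compares a full fit (with covariate) to the intercept-only null fit on
#' the same counts, offsets and dispersion. The statistic
#' \eqn{2(\ell_{full} - \ell_{null})} is clipped at zero and referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param full,null `"nb_glm_fit"` objects from [fit_nb_glm()].
#' @return A list with `lr` (statistic) and `p` (upper-tail p-value).
#' @export
lr_test <- function(full, null) {
  if (full$n != null$n) {
    stop("full and null fits use different numbers of samples",
         call. = FALSE)
  }
  lr <- max(0, 2 * (full$loglik - null$loglik))
  list(lr = lr, p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}
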