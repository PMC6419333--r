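offsets <- function(n, lib = 1000) rep(log(lib), n)

test_that("near-Poisson two-group fit matches the closed-form log ratio", {
  # group means 2 and 8 with equal offsets: b1 = ln(8/2), log2FC = 2
  y <- c(rep(2, 30), rep(8, 30))
  x <- rep(0:1, each = 30)
  fit <- fit_nb_glm(y, x, offsets(60), phi = 1e-6)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["b1"]), log(4), tolerance = 1e-6)
  expect_equal(unname(fit$coef["b1"]) / log(2), 2, tolerance = 1e-6)
})

test_that("fit maximizes the same likelihood as a reference NB GLM", {
  withr::with_seed(2, {
    x <- rep(0:1, each = 20)
    o <- offsets(40)
    mu <- exp(o - 5 + 1.2 * x)
    y <- rnbinom(40, mu = mu, size = 1 / 0.4)
  })
  fit <- fit_nb_glm(y, x, o, phi = 0.4)
  ref <- stats::glm(y ~ x, family = MASS::negative.binomial(theta = 1 / 0.4),
                    offset = o)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("rescaling the covariate rescales the slope exactly", {
  withr::with_seed(4, {
    x <- runif(50)
    y <- rnbinom(50, mu = exp(offsets(50, 500) - 3 + x), size = 2)
  })
  f1 <- fit_nb_glm(y, x, offsets(50, 500), phi = 0.5)
  f10 <- fit_nb_glm(y, 10 * x, offsets(50, 500), phi = 0.5)
  expect_equal(unname(f1$coef["b1"]), 10 * unname(f10$coef["b1"]),
               tolerance = 1e-6)
  expect_equal(f1$loglik, f10$loglik, tolerance = 1e-8)
})

test_that("degenerate designs and bad inputs are rejected", {
  y <- rpois(10, 5)
  expect_error(fit_nb_glm(y, rep(1, 10), offsets(10), 0.1), "E_DEGENERATE")
  expect_error(fit_nb_glm(rep(0, 10), rep(0:1, 5), offsets(10), 0.1),
               "all-zero")
  expect_error(fit_nb_glm(y, c(NA, runif(9)), offsets(10), 0.1), "missing")
  # a single nonzero count still converges to finite coefficients
  y1 <- c(rep(0, 19), 3)
  fit <- fit_nb_glm(y1, rep(0:1, each = 10), offsets(20), 0.5)
  expect_true(all(is.finite(fit$coef)))
})

test_that("likelihood-ratio test follows the chi-square(1) reference", {
  f <- list(loglik = -10, n = 20)
  n0 <- list(loglik = -10, n = 20)
  expect_equal(lr_test(f, n0), list(lr = 0, p = 1))
  n1 <- list(loglik = -10 - 3.841459 / 2, n = 20)
  expect_equal(lr_test(f, n1)$p, 0.05, tolerance = 1e-4)
  expect_error(lr_test(f, list(loglik = -10, n = 19)), "different numbers")
})

test_that("full-model likelihood never falls below the null's", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- 30
      x <- rnorm(n)
      y <- rnbinom(n, mu = exp(offsets(n, 200) - 3), size = 2)
      if (sum(y) == 0) next
      o <- offsets(n, 200)
      full <- fit_nb_glm(y, x, o, phi = 0.5)
      null <- fit_nb_glm(y, NULL, o, phi = 0.5)
      expect_gte(full$loglik, null$loglik - 1e-8)
    }
  })
})

test_that("dispersion estimates recover the generating value", {
  # 50 taxa, n = 200: Poisson data should give near-zero phi, phi = 0.5
  # data should give estimates in a band around 0.5
  gen <- function(phi, seed) {
    withr::with_seed(seed, {
      x <- rnorm(200)
      mu <- exp(log(50) + 0 * x)
      y <- t(vapply(1:50, function(j) {
        if (phi == 0) rpois(200, mu) else rnbinom(200, mu = mu, size = 1 / phi)
      }, numeric(200)))
      list(cm = otu_counts(y, lineages = paste0("k__T", 1:50),
                           sample_ids = paste0("s", 1:200)), x = x)
    })
  }
  d0 <- gen(0, 21)
  phi0 <- estimate_dispersions(d0$cm, d0$x,
                               norm = libsize_norm_factors(d0$cm))
  expect_lte(median(phi0), 0.05)

  d5 <- gen(0.5, 22)
  phi5 <- estimate_dispersions(d5$cm, d5$x,
                               norm = libsize_norm_factors(d5$cm))
  expect_gte(median(phi5), 0.3)
  expect_lte(median(phi5), 0.8)
})

test_that("shrinkage pulls per-taxon dispersions toward the common value", {
  withr::with_seed(23, {
    x <- rnorm(100)
    y <- rbind(rnbinom(100, mu = 50, size = 1 / 0.1),
               rnbinom(100, mu = 50, size = 1 / 2))
  })
  cm <- otu_counts(y, lineages = c("k__A", "k__B"),
                   sample_ids = paste0("s", 1:100))
  phi <- estimate_dispersions(cm, x, norm = libsize_norm_factors(cm))
  raw <- attr(phi, "raw")
  common <- attr(phi, "common")
  for (j in 1:2) {
    lo <- min(raw[j], common); hi <- max(raw[j], common)
    expect_gte(phi[[j]], lo - 1e-12)
    expect_lte(phi[[j]], hi + 1e-12)
  }
  expect_error(estimate_dispersions(cm, x[1:10]), "length")
  zero <- otu_counts(rbind(y[1, ], 0), lineages = c("k__A", "k__B"),
                     sample_ids = paste0("s", 1:100))
  expect_error(estimate_dispersions(zero, x), "all-zero")
})
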