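#' Estimate per-taxon NB dispersions with shrinkage
#'
#' For each taxon, the profile log-likelihood of the dispersion
#' \eqn{\phi} is evaluated on a log-spaced grid in \[1e-6, 10\],
#' re-fitting the GLM coefficients (intercept plus covariate slope) at
#' every candidate value. Per-taxon estimates are then shrunk toward the
#' common (all-taxa) profile maximizer by maximizing a weighted profile
#' likelihood in which the common curve receives a prior weight
#' equivalent to `prior_obs` observations relative to the taxon's own
#' `n` samples. This stabilizes dispersion estimates for individual taxa
#' while letting well-measured taxa keep their own value.
#'
#' @param cm An [otu_counts] object (all-zero taxa must already have been
#'   removed with [filter_taxa()]).
#' @param covariate Numeric covariate, one value per sample, no missing
#'   values.
#' @param norm Normalization from [tmm_norm_factors()]; computed here if
#'   `NULL`.
#' @param grid_size Number of grid points.
#' @param prior_obs Prior weight of the common dispersion, in
#'   observation-equivalents.
#' @return Named numeric vector of shrunk dispersions, one per taxon, with
#'   attributes `common` (the common maximizer) and `raw` (per-taxon
#'   unshrunk maximizers).
#' @export
estimate_dispersions <- function(cm, covariate, norm = NULL,
                                 grid_size = 21L, prior_obs = 10) {
  y <- cm$counts
  n <- ncol(y)
  if (length(covariate) != n) {
    stop("covariate length must equal the number of samples", call. = FALSE)
  }
  if (anyNA(covariate)) {
    stop("covariate contains missing values; drop them first", call. = FALSE)
  }
  if (any(rowSums(y) == 0)) {
    stop("all-zero taxon rows present; apply filter_taxa() first",
         call. = FALSE)
  }
  if (is.null(norm)) norm <- tmm_norm_factors(cm)
  grid <- exp(seq(log(1e-6), log(10), length.out = grid_size))
  # profile log-likelihood: taxa x grid
  prof <- vapply(grid, function(phi) {
    vapply(seq_len(nrow(y)), function(j)
      fit_nb_glm(y[j, ], covariate, norm, phi)$loglik, numeric(1))
  }, numeric(nrow(y)))
  if (nrow(y) == 1L) prof <- matrix(prof, nrow = 1L)
  common_curve <- colSums(prof) / nrow(y)
  # weighted profile: own curve (n observations) + prior_obs-weighted common
  pen <- prof + (prior_obs / n) *
    matrix(common_curve, nrow = nrow(y), ncol = grid_size, byrow = TRUE)
  # refine every grid maximizer inside its bracketing interval; the
  # common curve is smooth, so it is spline-interpolated off-grid
  common_fun <- stats::splinefun(log(grid), common_curve)
  refine <- function(i, obj) {
    lo <- log(grid[max(i - 1L, 1L)])
    hi <- log(grid[min(i + 1L, grid_size)])
    if (hi - lo < 1e-8) return(grid[i])
    exp(stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum)
  }
  common <- refine(which.max(common_curve), common_fun)
  raw <- vapply(seq_len(nrow(y)), function(j) {
    refine(which.max(prof[j, ]), function(lphi)
      fit_nb_glm(y[j, ], covariate, norm, exp(lphi))$loglik)
  }, numeric(1))
  phi <- vapply(seq_len(nrow(y)), function(j) {
    refine(which.max(pen[j, ]), function(lphi) {
      fit_nb_glm(y[j, ], covariate, norm, exp(lphi))$loglik +
        (prior_obs / n) * common_fun(lphi)
    })
  }, numeric(1))
  structure(stats::setNames(pmax(phi, 1e-6), cm$lineages),
            common = common, raw = stats::setNames(raw, cm$lineages))
}
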