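#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scale factors to correct for
#' compositional differences between libraries. For each sample, log2
#' abundance ratios (M-values) against a reference sample are trimmed —
#' 30% from each tail of the M-values and 5% from each tail of the average
#' log abundances (A-values) — and averaged with inverse-variance
#' (delta-method binomial) weights. The reference is the sample whose
#' upper quartile of nonzero count proportions is closest to the mean
#' upper quartile across samples. Factors are rescaled so their geometric
#' mean is 1.
#'
#' @param cm An [otu_counts] object with at least two samples, each with
#'   at least one nonzero count.
#' @param logratio_trim Fraction trimmed from each tail of the M-values.
#' @param sum_trim Fraction trimmed from each tail of the A-values.
#' @return A list with `factors` (per-sample scale factor, geometric mean
#'   1) and `lib_sizes`, both named by sample. The product
#'   `lib_sizes * factors` is the effective library size used as a GLM
#'   offset.
#' @export
tmm_norm_factors <- function(cm, logratio_trim = 0.30, sum_trim = 0.05) {
  y <- cm$counts
  N <- cm$library_sizes
  if (ncol(y) < 2L) stop("TMM needs at least two samples", call. = FALSE)
  if (any(N == 0)) {
    stop(sprintf("sample '%s' has zero total counts",
                 cm$sample_ids[which(N == 0)[1]]), call. = FALSE)
  }
  props <- sweep(y, 2L, N, "/")
  uq <- apply(props, 2L, function(p) stats::quantile(p[p > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  yr <- y[, ref]
  Nr <- N[ref]

  f <- vapply(seq_len(ncol(y)), function(i) {
    if (i == ref) return(1)
    yi <- y[, i]
    ok <- yi > 0 & yr > 0
    if (!any(ok)) {
      stop(sprintf(
        "sample '%s' shares no nonzero taxa with the reference '%s'",
        cm$sample_ids[i], cm$sample_ids[ref]), call. = FALSE)
    }
    M <- log2((yi[ok] / N[i]) / (yr[ok] / Nr))
    A <- 0.5 * log2((yi[ok] / N[i]) * (yr[ok] / Nr))
    w <- (N[i] - yi[ok]) / (N[i] * yi[ok]) + (Nr - yr[ok]) / (Nr * yr[ok])
    if (max(abs(M)) < 1e-6) return(1)  # identical composition
    keep <- M > stats::quantile(M, logratio_trim) - 1e-12 &
      M < stats::quantile(M, 1 - logratio_trim) + 1e-12 &
      A > stats::quantile(A, sum_trim) - 1e-12 &
      A < stats::quantile(A, 1 - sum_trim) + 1e-12
    if (!any(keep)) keep <- rep(TRUE, length(M))
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))

  f <- f / exp(mean(log(f)))
  list(factors = stats::setNames(f, cm$sample_ids),
       lib_sizes = stats::setNames(N, cm$sample_ids))
}

#' Library-size-only normalization
#'
#' Fallback normalization using unit scale factors, so the GLM offset is
#' the raw library size.
#'
#' @inheritParams tmm_norm_factors
#' @return Same structure as [tmm_norm_factors()] with all factors 1.
#' @export
libsize_norm_factors <- function(cm) {
  list(factors = stats::setNames(rep(1, ncol(cm$counts)), cm$sample_ids),
       lib_sizes = stats::setNames(cm$library_sizes, cm$sample_ids))
}
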