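#' Differential abundance of every taxon against one metadata variable
#'
#' The pipeline's core step: for one numeric metadata variable, samples
#' with missing values are dropped, TMM factors are recomputed on the
#' retained samples, per-taxon dispersions are estimated with shrinkage,
#' and each taxon is tested with a univariate negative-binomial GLM
#' (`Count ~ MetadataVariable`, with effective library size as offset)
#' against its intercept-only null via a likelihood-ratio test. The slope
#' is reported as a log2 fold change per covariate unit. P-values are
#' raw; any multiple-testing correction is left to consumers.
#'
#' @param cm An [otu_counts] object (already filtered; no all-zero taxa
#'   after sample dropping — such taxa are removed here with a warning).
#' @param meta Data.frame of numeric metadata with sample ids as row
#'   names (see [read_metadata_table()]).
#' @param variable Name of the metadata column to test.
#' @param norm_method `"tmm"` or `"libsize"`.
#' @param min_samples Minimum retained samples after dropping missing
#'   values.
#' @return A data.frame of class `"da_result"` with columns `taxon`,
#'   `log2fc`, `lr`, `p`, and attributes `condition`, `n_samples` and
#'   `dispersions`. Rows align with `cm`'s taxa (dropped all-zero taxa
#'   carry `NA`).
#' @export
differential_abundance <- function(cm, meta, variable,
                                   norm_method = c("tmm", "libsize"),
                                   min_samples = 8L) {
  norm_method <- match.arg(norm_method)
  if (!variable %in% colnames(meta)) {
    stop(sprintf("metadata variable '%s' not found", variable),
         call. = FALSE)
  }
  x_all <- meta[[variable]][match(cm$sample_ids, rownames(meta))]
  keep <- !is.na(x_all)
  n <- sum(keep)
  if (n < min_samples) {
    stop(sprintf(
      "E_SAMPLES: variable '%s' has %d non-missing samples (minimum %d)",
      variable, n, min_samples), call. = FALSE)
  }
  x <- x_all[keep]
  if (length(unique(x)) < 2L) {
    stop(sprintf("E_DEGENERATE: variable '%s' is constant over %d samples",
                 variable, n), call. = FALSE)
  }
  sub <- subset_otu_counts(cm, samples = which(keep))
  nonzero <- rowSums(sub$counts) > 0
  if (!all(nonzero)) {
    warning(sprintf(
      "%d taxa are all-zero over the retained samples for '%s'; skipped",
      sum(!nonzero), variable), call. = FALSE)
  }
  subnz <- subset_otu_counts(sub, taxa = which(nonzero))
  norm <- switch(norm_method,
                 tmm = tmm_norm_factors(subnz),
                 libsize = libsize_norm_factors(subnz))
  phi <- estimate_dispersions(subnz, x, norm = norm)

  res <- t(vapply(seq_len(nrow(subnz$counts)), function(j) {
    y <- subnz$counts[j, ]
    full <- fit_nb_glm(y, x, norm, phi[j])
    null <- fit_nb_glm(y, NULL, norm, phi[j])
    lrt <- lr_test(full, null)
    c(full$coef[["b1"]] / log(2), lrt$lr, lrt$p)
  }, numeric(3)))

  out <- data.frame(taxon = cm$lineages,
                    log2fc = NA_real_, lr = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- match(subnz$lineages, cm$lineages)
  out$log2fc[idx] <- res[, 1]
  out$lr[idx] <- res[, 2]
  out$p[idx] <- res[, 3]
  structure(out, class = c("da_result", "data.frame"),
            condition = variable, n_samples = n, dispersions = phi)
}
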