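#' Abundance-based coverage estimator (ACE) of species richness
#'
#' Splits the taxa observed in one sample into abundant
#' (count > `rare_threshold`) and rare groups, estimates the sample
#' coverage of the rare group as \eqn{C = 1 - F_1 / N_{rare}} (with
#' \eqn{F_i} the number of rare taxa seen exactly \eqn{i} times and
#' \eqn{N_{rare} = \sum i F_i}), and returns
#' \deqn{ACE = S_{abund} + S_{rare}/C + (F_1/C)\,\gamma^2,}
#' where \eqn{\gamma^2} is the rare-taxa coefficient of variation
#' \eqn{\max[(S_{rare}/C)\sum i(i-1)F_i / (N_{rare}(N_{rare}-1)) - 1,\ 0]}.
#' Zero counts are ignored; with no rare taxa ACE equals the observed
#' richness; when every rare taxon is a singleton the coverage is zero
#' and the estimator is undefined.
#'
#' @param counts Non-negative integer abundances of one sample, at least
#'   one nonzero.
#' @param rare_threshold Abundance at or below which a taxon counts as
#'   rare (default 10).
#' @return A list of class `"ace_breakdown"`: `ace`, `s_abund`, `s_rare`,
#'   `f` (frequency counts \eqn{F_1..F_{threshold}}), `n_rare`, `c_ace`,
#'   `gamma_sq`.
#' @export
ace_index <- function(counts, rare_threshold = 10) {
  if (any(counts < 0 | counts != round(counts), na.rm = TRUE)) {
    stop("abundances must be non-negative integers", call. = FALSE)
  }
  counts <- counts[!is.na(counts) & counts > 0]
  if (length(counts) == 0L) {
    stop("sample has no observed taxa", call. = FALSE)
  }
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  f <- vapply(seq_len(rare_threshold), function(i) sum(rare == i),
              numeric(1))
  n_rare <- sum(seq_len(rare_threshold) * f)
  if (s_rare == 0L) {
    return(structure(list(ace = s_abund, s_abund = s_abund, s_rare = 0L,
                          f = f, n_rare = 0, c_ace = NA_real_,
                          gamma_sq = NA_real_),
                     class = "ace_breakdown"))
  }
  c_ace <- 1 - f[1] / n_rare
  if (c_ace <= 0) {
    stop(paste("E_UNDEFINED: ACE undefined — every rare taxon is a",
               "singleton (zero estimated coverage)"), call. = FALSE)
  }
  i <- seq_len(rare_threshold)
  gamma_sq <- if (n_rare > 1) {
    max((s_rare / c_ace) * sum(i * (i - 1) * f) /
          (n_rare * (n_rare - 1)) - 1, 0)
  } else 0
  ace <- s_abund + s_rare / c_ace + (f[1] / c_ace) * gamma_sq
  structure(list(ace = ace, s_abund = s_abund, s_rare = s_rare, f = f,
                 n_rare = n_rare, c_ace = c_ace, gamma_sq = gamma_sq),
            class = "ace_breakdown")
}

#' Correlate per-sample ACE diversity with metadata variables
#'
#' Computes ACE for every sample and Spearman-correlates the resulting
#' diversity vector with each metadata variable (pairwise-complete;
#' two-sided p by the t approximation). Samples where ACE is undefined
#' (all rare taxa singletons) are flagged and dropped pairwise rather
#' than aborting the cohort analysis.
#'
#' @param cm An [otu_counts] object.
#' @param meta Numeric metadata data.frame (sample ids as row names).
#' @param variables Columns to correlate; defaults to all.
#' @param rare_threshold Passed to [ace_index()].
#' @param min_samples Minimum complete pairs per variable.
#' @return A data.frame with columns `variable`, `rho`, `p`, `n`; the
#'   per-sample ACE vector is attached as attribute `ace` (with `NA` for
#'   undefined samples).
#' @export
diversity_metadata_correlation <- function(cm, meta,
                                           variables = colnames(meta),
                                           rare_threshold = 10,
                                           min_samples = 8L) {
  ace <- vapply(seq_len(ncol(cm$counts)), function(i) {
    tryCatch(ace_index(cm$counts[, i], rare_threshold)$ace,
             error = function(e) NA_real_)
  }, numeric(1))
  names(ace) <- cm$sample_ids
  if (anyNA(ace)) {
    warning(sprintf("ACE undefined for %d sample(s); dropped pairwise",
                    sum(is.na(ace))), call. = FALSE)
  }
  res <- lapply(variables, function(v) {
    x <- meta[[v]][match(cm$sample_ids, rownames(meta))]
    ok <- !is.na(x) & !is.na(ace)
    n <- sum(ok)
    if (n < min_samples || length(unique(x[ok])) < 2L ||
        length(unique(ace[ok])) < 2L) {
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      stats::cor.test(ace[ok], x[ok], method = "spearman", exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate), p = ct$p.value,
               n = n)
  })
  out <- do.call(rbind, res)
  attr(out, "ace") <- ace
  out
}

normalize_species_name <- function(x) {
  gsub("[ _]+", " ", trimws(tolower(x)))
}

#' Correlate a shift vector with trait annotation probabilities
#'
#' For each trait column, Pearson-correlates the trait values
#' (probabilities or 0/1 flags) with the per-taxon log2 fold changes of
#' one condition, over taxa matched by species name (case-insensitive,
#' underscore/space-normalized; lineage rows are matched on their
#' species field). Traits significant at `alpha` are returned sorted by
#' decreasing |r|; constant trait columns are excluded with a warning.
#'
#' @param log2fc Named numeric vector of log2 fold changes (names are
#'   lineage strings or species names).
#' @param traits Numeric matrix from [read_trait_table()] (taxa x traits).
#' @param alpha Significance cutoff on the raw two-sided p (default
#'   0.05); set `fdr = TRUE` to filter on Benjamini-Hochberg-adjusted
#'   p-values instead.
#' @param method `"pearson"` (default; point-biserial for binarized
#'   traits) or `"spearman"`.
#' @param fdr Apply BH adjustment before the `alpha` filter.
#' @return A data.frame with columns `trait`, `r`, `p`, `n`, filtered and
#'   sorted; the full unfiltered table is attached as attribute `all`.
#' @export
trait_shift_correlation <- function(log2fc, traits, alpha = 0.05,
                                    method = c("pearson", "spearman"),
                                    fdr = FALSE) {
  method <- match.arg(method)
  if (is.null(names(log2fc))) {
    stop("log2fc vector must be named by taxon", call. = FALSE)
  }
  species_of <- function(s) {
    tryCatch({
      lin <- parse_lineage(s)
      if ("species" %in% names(lin)) {
        gen <- if ("genus" %in% names(lin)) paste0(lin[["genus"]], " ") else ""
        paste0(gen, lin[["species"]])
      } else s
    }, error = function(e) s)
  }
  da_names <- normalize_species_name(
    vapply(names(log2fc), species_of, character(1)))
  trait_names <- normalize_species_name(
    vapply(rownames(traits), species_of, character(1)))
  idx <- match(trait_names, da_names)
  matched <- which(!is.na(idx))
  if (length(matched) < 3L) {
    stop(sprintf(
      "only %d taxa shared between shift vector (%d) and traits (%d)",
      length(matched), length(log2fc), nrow(traits)), call. = FALSE)
  }
  fc <- log2fc[idx[matched]]
  tm <- traits[matched, , drop = FALSE]
  res <- lapply(colnames(tm), function(tr) {
    v <- tm[, tr]
    ok <- is.finite(v) & is.finite(fc)
    if (sum(ok) < 3L || stats::sd(v[ok]) < 1e-300 ||
        stats::sd(fc[ok]) < 1e-300) {
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(v[ok], fc[ok], method = method, exact = FALSE))
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0L) {
    warning(sprintf("%d constant/degenerate trait column(s) excluded",
                    dropped), call. = FALSE)
  }
  all_res <- do.call(rbind, res)
  if (is.null(all_res)) {
    stop("no trait column had enough variation to test", call. = FALSE)
  }
  pfilter <- if (fdr) stats::p.adjust(all_res$p, "BH") else all_res$p
  out <- all_res[pfilter < alpha, , drop = FALSE]
  out <- out[order(-abs(out$r), out$trait), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_res
  out
}
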