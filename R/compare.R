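#' Construct a shift matrix
#'
#' A shift matrix holds, at one taxonomic rank, the log2 fold change and
#' p-value of every taxon under every condition (metadata variable) — the
#' database of differential-abundance "shift" vectors against which new
#' conditions or external queries are compared.
#'
#' @param rank Taxonomic rank of the rows.
#' @param taxa Character vector of taxon labels.
#' @param conditions Character vector of condition labels.
#' @param log2fc,p Numeric matrices (taxa x conditions).
#' @param n_samples Numeric vector of per-condition sample counts.
#' @return An object of class `"shift_matrix"`.
#' @export
shift_matrix <- function(rank, taxa, conditions, log2fc, p, n_samples) {
  log2fc <- as.matrix(log2fc); p <- as.matrix(p)
  stopifnot(nrow(log2fc) == length(taxa),
            ncol(log2fc) == length(conditions),
            identical(dim(log2fc), dim(p)),
            length(n_samples) == length(conditions))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  dimnames(log2fc) <- dimnames(p) <- list(taxa, conditions)
  structure(list(rank = rank, taxa = as.character(taxa),
                 conditions = as.character(conditions),
                 log2fc = log2fc, p = p,
                 n_samples = stats::setNames(as.numeric(n_samples),
                                             conditions)),
            class = "shift_matrix")
}

#' @export
print.shift_matrix <- function(x, ...) {
  cat(sprintf("shift_matrix at rank %s: %d taxa x %d conditions\n",
              x$rank, length(x$taxa), length(x$conditions)))
  invisible(x)
}

#' Build a per-rank shift matrix from counts and metadata
#'
#' Collapses the count matrix to `rank`, runs [differential_abundance()]
#' for every requested variable, and concatenates the resulting vectors
#' column-wise. Variables that fail their preconditions (too few
#' non-missing samples, constant values) are skipped with a warning
#' rather than aborting the build.
#'
#' @param cm An [otu_counts] object (species-level or already collapsed).
#' @param meta Numeric metadata data.frame (samples in rows).
#' @param variables Metadata columns to test; defaults to all.
#' @param rank Target taxonomic rank.
#' @param ... Passed on to [differential_abundance()].
#' @return A [shift_matrix].
#' @export
build_shift_matrix <- function(cm, meta, variables = colnames(meta),
                               rank = "genus", ...) {
  cmr <- collapse_to_level(cm, rank)
  cmr <- filter_taxa(cmr, 1)
  results <- list()
  for (v in variables) {
    r <- tryCatch(differential_abundance(cmr, meta, v, ...),
                  error = function(e) {
                    warning(sprintf("skipping variable '%s': %s", v,
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) results[[v]] <- r
  }
  if (length(results) == 0L) {
    stop("E_EMPTY: no metadata variable could be tested", call. = FALSE)
  }
  shift_matrix(
    rank = rank, taxa = cmr$lineages, conditions = names(results),
    log2fc = vapply(results, `[[`, numeric(length(cmr$lineages)), "log2fc"),
    p = vapply(results, `[[`, numeric(length(cmr$lineages)), "p"),
    n_samples = vapply(results, attr, numeric(1), "n_samples")
  )
}

pair_cor <- function(a, b, method, min_overlap = 3L) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min_overlap) return(NA_real_)
  stats::cor(a[ok], b[ok], method = method)
}

#' Pairwise similarity of condition shift vectors
#'
#' Correlates the log2 fold-change columns of a shift matrix between every
#' pair of conditions, over the taxa finite in both (minimum 3 shared
#' taxa, otherwise the cell is `NA` with a warning). Spearman is the
#' default for robustness to the heavy-tailed fold changes of rare taxa.
#'
#' @param sm A [shift_matrix] with at least two conditions.
#' @param method `"spearman"` or `"pearson"`.
#' @return A symmetric `similarity_matrix` (conditions x conditions) with
#'   unit diagonal and a `method` attribute.
#' @export
condition_similarity <- function(sm, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  k <- length(sm$conditions)
  if (k < 2L) stop("at least two conditions required", call. = FALSE)
  out <- diag(1, k)
  dimnames(out) <- list(sm$conditions, sm$conditions)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    r <- pair_cor(sm$log2fc[, i], sm$log2fc[, j], method)
    out[i, j] <- out[j, i] <- r
  }
  if (anyNA(out)) {
    warning("some condition pairs share fewer than 3 finite taxa",
            call. = FALSE)
  }
  structure(out, method = method, class = c("similarity_matrix", "matrix"))
}

#' Rank database conditions against a query shift vector
#'
#' Correlates a user-supplied per-taxon log2 fold-change vector with every
#' condition column of the shift matrix (same correlation as
#' [condition_similarity()]) and returns conditions sorted by decreasing
#' similarity, ties broken by condition label.
#'
#' @param sm A [shift_matrix].
#' @param query Named numeric vector of log2 fold changes, names matching
#'   the shift matrix's taxon labels; at least 3 taxa must overlap.
#' @param method `"spearman"` or `"pearson"`.
#' @return A data.frame with columns `condition`, `similarity`,
#'   `n_taxa` (overlap used per condition), sorted by similarity.
#' @export
query_shift <- function(sm, query, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(names(query))) {
    stop("query vector must be named by taxon", call. = FALSE)
  }
  idx <- match(sm$taxa, names(query))
  overlap <- sum(!is.na(idx) & is.finite(query[idx]))
  if (overlap < 3L) {
    stop(sprintf(
      "query shares only %d taxa with the shift matrix (minimum 3)",
      overlap), call. = FALSE)
  }
  q <- query[idx]
  sims <- vapply(seq_along(sm$conditions), function(j)
    pair_cor(q, sm$log2fc[, j], method), numeric(1))
  n_taxa <- vapply(seq_along(sm$conditions), function(j)
    sum(is.finite(q) & is.finite(sm$log2fc[, j])), integer(1))
  out <- data.frame(condition = sm$conditions, similarity = sims,
                    n_taxa = n_taxa, stringsAsFactors = FALSE)
  out[order(-out$similarity, out$condition), , drop = FALSE]
}

#' Select the taxa most discriminative of two condition clusters
#'
#' Reproduces the heatmap feature-selection step: conditions are split
#' into two groups by average-linkage hierarchical clustering on
#' correlation distance (1 - similarity) between their shift vectors, and
#' each taxon is scored by the one-way ANOVA F-statistic of its log2 fold
#' changes between the two groups. The top `k` taxa by F are returned;
#' rows with no between-group variation score F = 0, and ties fall back
#' to taxon label order.
#'
#' @param sm A [shift_matrix] with at least three conditions.
#' @param k Number of taxa to return (default 20).
#' @param method Correlation used for the condition clustering.
#' @return Character vector of taxon labels, ordered by decreasing F;
#'   the F-statistics and cluster assignment are attached as attributes
#'   `F` and `clusters`.
#' @export
select_discriminative_taxa <- function(sm, k = 20L,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(sm$conditions) < 3L) {
    stop("at least three conditions required", call. = FALSE)
  }
  simm <- condition_similarity(sm, method)
  d <- stats::as.dist(1 - simm)
  grp <- stats::cutree(stats::hclust(d, method = "average"), k = 2L)
  f <- apply(sm$log2fc, 1L, function(row) anova_f(row, grp))
  ord <- order(-f, sm$taxa)
  k <- min(k, length(sm$taxa))
  structure(sm$taxa[ord][seq_len(k)],
            F = stats::setNames(f, sm$taxa)[ord][seq_len(k)],
            clusters = grp)
}

anova_f <- function(values, groups) {
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  if (length(values) < 3L || length(unique(groups)) < 2L) return(0)
  if (max(values) - min(values) < 1e-15) return(0)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[as.character(groups)])^2)
  dfb <- length(means) - 1L
  dfw <- length(values) - length(means)
  if (dfw <= 0L || ssw < 1e-300) {
    return(if (ssb > 0) Inf else 0)
  }
  (ssb / dfb) / (ssw / dfw)
}

#' Z-score rows of a matrix
#'
#' Standardizes each row to mean 0 and sample standard deviation 1
#' (the usual heatmap row normalization). Constant rows become all-zero
#' with a warning. `NA` cells are ignored in the row statistics and kept
#' as `NA`.
#'
#' @param m Numeric matrix (taxa x conditions).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 1L, stats::sd, na.rm = TRUE)
  const <- is.na(sd_) | sd_ < 1e-300
  if (any(const)) {
    warning(sprintf("%d constant row(s) set to zero", sum(const)),
            call. = FALSE)
    sd_[const] <- 1
  }
  out <- (m - mu) / sd_
  out[const, ] <- out[const, , drop = FALSE] * 0  # keeps NA cells NA
  out
}
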