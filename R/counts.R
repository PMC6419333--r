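#' Construct an OTU count matrix
#'
#' The central container of the package: a taxa-by-samples matrix of
#' non-negative integer counts, with one lineage string per taxon row and
#' per-sample library sizes kept equal to the column sums at all times.
#'
#' @param counts Numeric matrix (taxa x samples) of non-negative integers.
#' @param lineages Character vector of lineage strings, one per row;
#'   defaults to `rownames(counts)`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `colnames(counts)`.
#' @return An object of class `"otu_counts"`: a list with elements
#'   `counts`, `lineages`, `sample_ids` and `library_sizes`.
#' @export
otu_counts <- function(counts, lineages = rownames(counts),
                       sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(lineages)) stop("taxon lineages are required", call. = FALSE)
  if (is.null(sample_ids)) stop("sample ids are required", call. = FALSE)
  lineages <- as.character(lineages)
  sample_ids <- as.character(sample_ids)
  rownames(counts) <- lineages
  colnames(counts) <- sample_ids
  x <- structure(
    list(counts = counts, lineages = lineages, sample_ids = sample_ids,
         library_sizes = colSums(counts)),
    class = "otu_counts"
  )
  validate_otu_counts(x)
}

validate_otu_counts <- function(x) {
  cm <- x$counts
  if (nrow(cm) != length(x$lineages)) {
    stop("one lineage per taxon row is required", call. = FALSE)
  }
  if (ncol(cm) != length(x$sample_ids)) {
    stop("one id per sample column is required", call. = FALSE)
  }
  bad <- which(!is.finite(cm) | cm < 0 | cm != round(cm), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell [%s, %s] = %s",
      x$lineages[bad[1, 1]], x$sample_ids[bad[1, 2]],
      format(cm[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  dup <- x$lineages[duplicated(x$lineages)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicated taxon lineages: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$sample_ids)) {
    stop(sprintf("duplicated sample ids: %s",
                 paste(unique(x$sample_ids[duplicated(x$sample_ids)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (!isTRUE(all.equal(unname(x$library_sizes), unname(colSums(cm))))) {
    stop("library sizes out of sync with column sums", call. = FALSE)
  }
  x
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("otu_counts: %d taxa x %d samples (median depth %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$library_sizes))))
  invisible(x)
}

#' @export
dim.otu_counts <- function(x) dim(x$counts)

# subset helper keeping library sizes in sync
subset_otu_counts <- function(x, taxa = NULL, samples = NULL) {
  cm <- x$counts
  if (!is.null(taxa)) cm <- cm[taxa, , drop = FALSE]
  if (!is.null(samples)) cm <- cm[, samples, drop = FALSE]
  otu_counts(cm)
}
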