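FILE_DIALECT <- "#otushift v1"

#' Missing-value tokens recognized in metadata tables
#'
#' Case-insensitive tokens treated as missing during numeric coercion, per
#' the conventions of crowd-sourced gut-survey metadata.
#' @export
MISSING_TOKENS <- c("", "na", "nan", "unknown", "unspecified")

read_table_lines <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("E_INPUT: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^#", lines)]
}

split_tsv <- function(lines, what) {
  if (length(lines) < 2L) {
    stop(sprintf("E_FORMAT: %s file has no data rows", what), call. = FALSE)
  }
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read an OTU count table from TSV
#'
#' Expects a header row, a first column of semicolon-delimited lineage
#' strings, and integer counts in the remaining columns. Lines starting
#' with `#` are ignored. Library sizes are computed as column sums.
#'
#' @param path Path to a tab-delimited file.
#' @return An [otu_counts] object.
#' @export
read_count_table <- function(path) {
  rows <- split_tsv(read_table_lines(path), "count table")
  header <- rows[[1]]
  sample_ids <- header[-1]
  body <- rows[-1]
  lineages <- vapply(body, `[[`, character(1), 1L)
  mat <- t(vapply(body, function(r) {
    if (length(r) != length(header)) {
      stop(sprintf("E_FORMAT: row '%s' has %d fields, expected %d",
                   r[[1]], length(r), length(header)), call. = FALSE)
    }
    suppressWarnings(as.numeric(r[-1]))
  }, numeric(length(sample_ids))))
  if (length(sample_ids) == 1L) mat <- matrix(mat, ncol = 1L)
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "E_FORMAT: non-integer or negative count at taxon '%s', sample '%s'",
      lineages[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  dup <- unique(lineages[duplicated(lineages)])
  if (length(dup) > 0L) {
    stop(sprintf("E_FORMAT: duplicated taxon rows: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  # validate lineage syntax up front so errors name the file
  for (lin in lineages) parse_lineage(lin)
  otu_counts(mat, lineages = lineages, sample_ids = sample_ids)
}

#' Write an OTU count table to TSV
#'
#' @param cm An [otu_counts] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(FILE_DIALECT, "counts"), con)
  writeLines(paste(c("taxon", cm$sample_ids), collapse = "\t"), con)
  body <- apply(cm$counts, 1L, function(r)
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(cm$lineages, body, sep = "\t"), con)
  invisible(path)
}

coerce_numeric <- function(x) {
  x <- trimws(as.character(x))
  miss <- tolower(x) %in% MISSING_TOKENS
  out <- suppressWarnings(as.numeric(x))
  out[miss] <- NA_real_
  # tokens that are neither missing nor numeric become NA, never 0
  out
}

#' Read a sample metadata table from TSV
#'
#' The first column holds sample identifiers; every other column is coerced
#' to numeric. Cells failing coercion (including the missing-value tokens
#' in [MISSING_TOKENS]) become `NA`; columns with no coercible value at all
#' are dropped with a warning.
#'
#' @param path Path to a tab-delimited file.
#' @return A data.frame of numeric variables with sample ids as row names.
#' @export
read_metadata_table <- function(path) {
  rows <- split_tsv(read_table_lines(path), "metadata")
  header <- rows[[1]]
  body <- rows[-1]
  body <- lapply(body, function(r) {
    length(r) <- length(header)
    r
  })
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("E_FORMAT: duplicated sample ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  vars <- header[-1]
  cols <- lapply(seq_along(vars) + 1L, function(j)
    coerce_numeric(vapply(body, `[[`, character(1), j)))
  names(cols) <- vars
  keep <- vapply(cols, function(v) any(!is.na(v)), logical(1))
  if (any(!keep)) {
    warning(sprintf("dropping non-numeric metadata column(s): %s",
                    paste(vars[!keep], collapse = ", ")), call. = FALSE)
  }
  out <- as.data.frame(cols[keep], check.names = FALSE, optional = TRUE)
  if (ncol(out) == 0L) out <- as.data.frame(matrix(nrow = length(ids),
                                                   ncol = 0L))
  rownames(out) <- ids
  out
}

#' Read a trait annotation table
#'
#' Reads a taxa-by-traits table of probabilities in [0, 1] (CSV or TSV,
#' auto-detected from the header line), optionally binarizing at a cutoff:
#' values at or above the cutoff become 1, all others 0.
#'
#' @param path Path to the file; first column holds taxon (species) names.
#' @param binarize_at Probability cutoff in (0, 1], or `NULL` to keep raw
#'   probabilities. Default 0.9, the published cutoff of text-mined trait
#'   collections such as ProTraits.
#' @return A numeric matrix (taxa x traits) with taxon names as row names.
#' @export
read_trait_table <- function(path, binarize_at = 0.9) {
  lines <- read_table_lines(path)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  if (length(rows) < 2L) {
    stop("E_FORMAT: trait table has no data rows", call. = FALSE)
  }
  header <- rows[[1]]
  body <- rows[-1]
  taxa <- vapply(body, `[[`, character(1), 1L)
  mat <- t(vapply(body, function(r) suppressWarnings(as.numeric(r[-1])),
                  numeric(length(header) - 1L)))
  if (length(header) == 2L) mat <- matrix(mat, ncol = 1L)
  dimnames(mat) <- list(taxa, header[-1])
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "E_FORMAT: trait value %s outside [0, 1] at taxon '%s', trait '%s'",
      format(mat[bad[1, , drop = FALSE]]), taxa[bad[1, 1]],
      colnames(mat)[bad[1, 2]]), call. = FALSE)
  }
  if (!is.null(binarize_at)) {
    mat[] <- as.numeric(mat >= binarize_at)
  }
  mat
}

#' Write a shift matrix to TSV
#'
#' The file carries two aligned blocks (log2 fold changes, then p-values),
#' full-precision values, the taxonomic rank and the per-condition sample
#' counts, so that [read_shift_matrix()] reproduces the object exactly.
#'
#' @param sm A [shift_matrix] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_matrix <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  writeLines(paste(FILE_DIALECT, "shift_matrix"), con)
  writeLines(paste0("#rank\t", sm$rank), con)
  writeLines(paste(c("#n_samples", fmt(sm$n_samples)), collapse = "\t"), con)
  for (block in c("log2fc", "p")) {
    writeLines(paste0("#block\t", block), con)
    writeLines(paste(c("taxon", sm$conditions), collapse = "\t"), con)
    m <- sm[[block]]
    if (length(sm$taxa) > 0L) {
      body <- apply(m, 1L, function(r) paste(fmt(r), collapse = "\t"))
      writeLines(paste(sm$taxa, body, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a shift matrix written by [write_shift_matrix()]
#'
#' @param path Path to the file.
#' @return A [shift_matrix] object.
#' @export
read_shift_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("E_INPUT: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    hit <- grep(paste0("^#", key, "\t"), lines, value = TRUE)
    if (length(hit) != 1L) {
      stop(sprintf("E_FORMAT: shift matrix file lacks '#%s' line", key),
           call. = FALSE)
    }
    strsplit(hit, "\t", fixed = TRUE)[[1]][-1]
  }
  rank <- grab("rank")
  n_samples <- as.numeric(grab("n_samples"))
  block_at <- grep("^#block\t", lines)
  if (length(block_at) != 2L) {
    stop("E_FORMAT: shift matrix file must contain exactly two blocks",
         call. = FALSE)
  }
  read_block <- function(from, to) {
    header <- strsplit(lines[from + 1L], "\t", fixed = TRUE)[[1]]
    body <- if (to >= from + 2L) lines[seq(from + 2L, to)] else character(0)
    body <- body[nzchar(body)]
    if (length(body) == 0L) {
      return(list(taxa = character(0),
                  m = matrix(numeric(0), 0L, length(header) - 1L,
                             dimnames = list(NULL, header[-1]))))
    }
    rows <- strsplit(body, "\t", fixed = TRUE)
    m <- t(vapply(rows, function(r) as.numeric(r[-1]),
                  numeric(length(header) - 1L)))
    if (length(header) == 2L) m <- matrix(m, ncol = 1L)
    colnames(m) <- header[-1]
    list(taxa = vapply(rows, `[[`, character(1), 1L), m = m)
  }
  b1 <- read_block(block_at[1], block_at[2] - 1L)
  b2 <- read_block(block_at[2], length(lines))
  if (!identical(b1$taxa, b2$taxa) ||
      !identical(colnames(b1$m), colnames(b2$m))) {
    stop("E_FORMAT: log2FC and p-value blocks disagree in rows or columns",
         call. = FALSE)
  }
  shift_matrix(rank = rank, taxa = b1$taxa, conditions = colnames(b1$m),
               log2fc = b1$m, p = b2$m, n_samples = n_samples)
}

#' Write a condition similarity matrix to TSV
#'
#' @param sim A `similarity_matrix` as returned by [condition_similarity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(FILE_DIALECT, "similarity", attr(sim, "method")), con)
  writeLines(paste(c("condition", colnames(sim)), collapse = "\t"), con)
  body <- apply(unclass(sim), 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(sim), body, sep = "\t"), con)
  invisible(path)
}
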