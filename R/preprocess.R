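#' Drop shallow samples
#'
#' Removes samples whose library size (total mapped reads) is below
#' `min_depth`. The default of 10,000 reads reflects the usual quality
#' floor for 16S gut surveys: "fewer than" is strict, so a sample with
#' exactly `min_depth` reads is kept.
#'
#' @param cm An [otu_counts] object.
#' @param min_depth Minimum library size to retain a sample.
#' @return The filtered [otu_counts]; taxon set and ordering unchanged.
#' @export
filter_samples <- function(cm, min_depth = 10000) {
  keep <- cm$library_sizes >= min_depth
  if (!any(keep)) {
    stop(sprintf(
      "E_EMPTY: no sample has at least %s reads", format(min_depth)),
      call. = FALSE)
  }
  subset_otu_counts(cm, samples = which(keep))
}

#' Drop low-abundance taxa
#'
#' Removes taxa whose total count across all samples is below `min_total`.
#' The default of 1 read drops only all-zero rows; low-abundance taxa
#' produce unstable fold-change estimates, so stricter totals can be used
#' when building shift vectors.
#'
#' @param cm An [otu_counts] object.
#' @param min_total Minimum row sum to retain a taxon.
#' @return The filtered [otu_counts]; sample set unchanged.
#' @export
filter_taxa <- function(cm, min_total = 1) {
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep)) {
    warning(sprintf("no taxon has at least %s reads in total",
                    format(min_total)), call. = FALSE)
    return(otu_counts(cm$counts[0, , drop = FALSE],
                      lineages = character(0),
                      sample_ids = cm$sample_ids))
  }
  subset_otu_counts(cm, taxa = which(keep))
}

#' Collapse counts to a taxonomic rank
#'
#' Sums the counts of all child taxa sharing the same lineage prefix at
#' `rank`. Taxa with no assignment at that rank are pooled into a single
#' `"Unassigned"` row so that per-sample totals are conserved exactly.
#'
#' @param cm An [otu_counts] object.
#' @param rank One of the seven canonical rank names (see
#'   [TAXONOMIC_RANKS]).
#' @return An [otu_counts] object with one row per distinct rank-level
#'   lineage, ordered by lineage string (the `"Unassigned"` pool, when
#'   present, comes last).
#' @export
collapse_to_level <- function(cm, rank) {
  rank_depth(rank)  # validates
  group <- lineage_at_rank(cm$lineages, rank)
  unassigned <- is.na(group)
  group[unassigned] <- "Unassigned"
  levels_ <- c(sort(unique(group[!unassigned])),
               if (any(unassigned)) "Unassigned")
  out <- rowsum(cm$counts, group = factor(group, levels = levels_))
  otu_counts(out, lineages = levels_, sample_ids = cm$sample_ids)
}

#' Default frequency-of-consumption recoding
#'
#' Maps the questionnaire response categories of gut-survey dietary
#' variables to events per day. Only "Daily" = 1.0 and "Never" = 0 are
#' canonical; intermediate categories use the midpoint of the stated range
#' divided by the period length (e.g. "Regularly (3-5 times/week)" becomes
#' 4/7). Override with your own map where the questionnaire differs.
#'
#' @format Named numeric vector, category to events per day.
#' @export
DEFAULT_FREQUENCY_MAP <- c(
  "Never" = 0,
  "Rarely (a few times/month)" = 2 / 30,
  "Occasionally (1-2 times/week)" = 1.5 / 7,
  "Regularly (3-5 times/week)" = 4 / 7,
  "Daily" = 1
)

#' Recode frequency categories to events per day
#'
#' @param responses Character vector of response categories; `NA` stays
#'   `NA`.
#' @param map Named numeric vector mapping each category to a value in
#'   [0, 24] events/day; defaults to [DEFAULT_FREQUENCY_MAP].
#' @return Numeric vector of per-day event rates.
#' @export
recode_frequency <- function(responses, map = DEFAULT_FREQUENCY_MAP) {
  if (any(map < 0 | map > 24)) {
    stop("frequency map values must lie in [0, 24] events/day",
         call. = FALSE)
  }
  present <- unique(responses[!is.na(responses)])
  unmapped <- setdiff(present, names(map))
  if (length(unmapped) > 0L) {
    stop(sprintf("unmapped frequency categories: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  unname(map[responses])
}

#' Read a frequency map from a two-column TSV
#'
#' @param path Path to a tab-delimited file with columns category and
#'   events-per-day.
#' @return Named numeric vector usable as the `map` argument of
#'   [recode_frequency()].
#' @export
read_frequency_map <- function(path) {
  rows <- strsplit(read_table_lines(path), "\t", fixed = TRUE)
  vals <- vapply(rows, function(r) suppressWarnings(as.numeric(r[[2]])),
                 numeric(1))
  if (anyNA(vals)) {
    stop("E_FORMAT: frequency map values must be numeric", call. = FALSE)
  }
  stats::setNames(vals, vapply(rows, `[[`, character(1), 1L))
}
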