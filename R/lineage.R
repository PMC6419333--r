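#' Canonical taxonomic ranks
#'
#' The seven-rank hierarchy used throughout the package, in order from
#' kingdom to species, together with their Greengenes-style single-letter
#' prefixes (`k__`, `p__`, ...).
#'
#' @format A named character vector mapping rank name to prefix letter.
#' @export
TAXONOMIC_RANKS <- c(
  kingdom = "k", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s"
)

#' Parse a Greengenes-style lineage string
#'
#' Splits a semicolon-delimited, rank-prefixed lineage string
#' (e.g. `"k__Bacteria;p__Firmicutes"`) into a named character vector of
#' rank names. Prefixes must appear in canonical kingdom-to-species order
#' with no gaps; an empty name (`"g__"`) truncates the assigned lineage at
#' the previous rank. Surrounding whitespace around fields is tolerated.
#'
#' @param lineage_string A single non-empty character string.
#' @return A named character vector (names drawn from
#'   [TAXONOMIC_RANKS]) holding the assigned ranks, possibly of length
#'   less than 7. Class `"taxon_lineage"`.
#' @examples
#' parse_lineage("k__Bacteria;p__Firmicutes")
#' @export
parse_lineage <- function(lineage_string) {
  if (!is.character(lineage_string) || length(lineage_string) != 1L ||
      is.na(lineage_string) || !nzchar(trimws(lineage_string))) {
    stop("lineage string must be a single non-empty string", call. = FALSE)
  }
  tokens <- trimws(strsplit(lineage_string, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  ranks <- character(0)
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!grepl("^[a-z]__", tok)) {
      stop(sprintf("malformed lineage token '%s' (expected '<rank>__<name>')",
                   tok), call. = FALSE)
    }
    prefix <- substr(tok, 1L, 1L)
    pos <- match(prefix, TAXONOMIC_RANKS)
    if (is.na(pos)) {
      stop(sprintf("unknown rank prefix '%s__' in token '%s'", prefix, tok),
           call. = FALSE)
    }
    if (pos != i) {
      stop(sprintf(
        "rank prefix '%s__' out of order at position %d (expected '%s__')",
        prefix, i, TAXONOMIC_RANKS[[i]]), call. = FALSE)
    }
    name <- substring(tok, 4L)
    if (!nzchar(name)) break  # empty name ends the assigned lineage
    ranks[[names(TAXONOMIC_RANKS)[pos]]] <- name
  }
  if (length(ranks) == 0L) {
    stop("lineage has no assigned ranks", call. = FALSE)
  }
  structure(ranks, class = "taxon_lineage")
}

#' Render a lineage back to its string form
#'
#' Inverse of [parse_lineage()]: `parse_lineage(render_lineage(x))`
#' reproduces `x`, and `render_lineage(parse_lineage(s))` reproduces any
#' canonical lineage string `s`.
#'
#' @param lineage A named character vector as returned by [parse_lineage()].
#' @return A single lineage string.
#' @export
render_lineage <- function(lineage) {
  ranks <- names(TAXONOMIC_RANKS)[seq_along(lineage)]
  paste0(TAXONOMIC_RANKS[ranks], "__", as.character(lineage),
         collapse = ";")
}

#' Truncate a lineage string at a rank
#'
#' Returns the lineage string cut at `rank`, or `NA` if the lineage is not
#' assigned down to that rank.
#'
#' @param lineage_strings Character vector of lineage strings.
#' @param rank One of the canonical rank names.
#' @return Character vector of truncated lineage strings with `NA` for
#'   taxa unassigned at `rank`.
#' @export
lineage_at_rank <- function(lineage_strings, rank) {
  depth <- rank_depth(rank)
  vapply(lineage_strings, function(s) {
    lin <- parse_lineage(s)
    if (length(lin) < depth) return(NA_character_)
    render_lineage(lin[seq_len(depth)])
  }, character(1), USE.NAMES = FALSE)
}

rank_depth <- function(rank) {
  depth <- match(rank, names(TAXONOMIC_RANKS))
  if (is.na(depth)) {
    stop(sprintf("unknown taxonomic rank '%s' (expected one of %s)", rank,
                 paste(names(TAXONOMIC_RANKS), collapse = ", ")),
         call. = FALSE)
  }
  depth
}

#' @export
print.taxon_lineage <- function(x, ...) {
  cat(render_lineage(x), "\n")
  invisible(x)
}
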