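log_level_env <- new.env(parent = emptyenv())
log_level_env$level <- "info"

#' Set the package log level
#'
#' @param level `"debug"`, `"info"` or `"warn"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn")) {
  old <- log_level_env$level
  log_level_env$level <- match.arg(level)
  invisible(old)
}

log_msg <- function(level, fmt, ...) {
  order_ <- c(debug = 1L, info = 2L, warn = 3L)
  if (order_[[level]] >= order_[[log_level_env$level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

#' Assemble a pipeline run configuration
#'
#' Flat key-value configuration mirroring the CLI flags. Every stochastic
#' stage receives its own seed derived from `seed` by a fixed rule
#' (`seed + stage offset`: +1 coherence, +2 Mantel), so a full run is
#' reproducible from the single top-level seed.
#'
#' @param counts,metadata Input paths (TSV).
#' @param traits Optional trait table path.
#' @param out Output directory (created if absent).
#' @param rank Taxonomic rank for the shift matrix.
#' @param min_depth,min_total Filter thresholds.
#' @param norm_method `"tmm"` or `"libsize"`.
#' @param similarity `"spearman"` or `"pearson"`.
#' @param alpha Trait-filter significance level.
#' @param n_perm Permutations for the validation stages.
#' @param seed Top-level integer seed.
#' @param run_diversity,run_traits,run_coherence Optional stages.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(counts, metadata, traits = NULL, out,
                       rank = "genus", min_depth = 10000, min_total = 1,
                       norm_method = "tmm", similarity = "spearman",
                       alpha = 0.05, n_perm = 100, seed = 1L,
                       run_diversity = FALSE, run_traits = FALSE,
                       run_coherence = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the standard pipeline
#'
#' filter samples -> filter taxa -> collapse -> shift matrix ->
#' condition similarity, plus the optional diversity, trait and
#' coherence stages. All intermediates are written to `config$out` and
#' every filter count and skipped variable is logged.
#'
#' @param config A [run_config].
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  art <- list()
  cm <- read_count_table(cfg$counts)
  meta <- read_metadata_table(cfg$metadata)
  log_msg("info", "loaded %d taxa x %d samples, %d metadata variables",
          nrow(cm$counts), ncol(cm$counts), ncol(meta))

  n0 <- ncol(cm$counts)
  cm <- filter_samples(cm, cfg$min_depth)
  log_msg("info", "sample filter (>= %s reads): %d -> %d",
          format(cfg$min_depth), n0, ncol(cm$counts))
  t0 <- nrow(cm$counts)
  cm <- filter_taxa(cm, cfg$min_total)
  log_msg("info", "taxon filter (>= %s total reads): %d -> %d",
          format(cfg$min_total), t0, nrow(cm$counts))
  art$filtered_counts <- file.path(cfg$out, "filtered_counts.tsv")
  write_count_table(cm, art$filtered_counts)

  sm <- withCallingHandlers(
    build_shift_matrix(cm, meta, rank = cfg$rank,
                       norm_method = cfg$norm_method),
    warning = function(w) {
      log_msg("warn", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  art$shift_matrix <- file.path(cfg$out, sprintf("shift_%s.tsv", cfg$rank))
  write_shift_matrix(sm, art$shift_matrix)
  log_msg("info", "shift matrix: %d taxa x %d conditions at %s",
          length(sm$taxa), length(sm$conditions), sm$rank)

  if (length(sm$conditions) >= 2L) {
    simm <- condition_similarity(sm, cfg$similarity)
    art$similarity <- file.path(cfg$out, "condition_similarity.tsv")
    write_similarity_matrix(simm, art$similarity)
  }

  if (isTRUE(cfg$run_diversity)) {
    div <- diversity_metadata_correlation(cm, meta)
    art$diversity <- file.path(cfg$out, "diversity_correlation.tsv")
    utils::write.table(div, art$diversity, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (isTRUE(cfg$run_traits) && !is.null(cfg$traits)) {
    traits <- read_trait_table(cfg$traits)
    res <- lapply(sm$conditions, function(cond) {
      fc <- stats::setNames(sm$log2fc[, cond], sm$taxa)
      tc <- tryCatch(
        trait_shift_correlation(fc, traits, alpha = cfg$alpha),
        error = function(e) {
          log_msg("warn", "trait correlation skipped for '%s': %s", cond,
                  conditionMessage(e))
          NULL
        })
      if (!is.null(tc) && nrow(tc) > 0L) cbind(condition = cond, tc)
    })
    res <- do.call(rbind, res)
    art$traits <- file.path(cfg$out, "trait_correlations.tsv")
    utils::write.table(
      if (is.null(res)) {
        data.frame(condition = character(0), trait = character(0),
                   r = numeric(0), p = numeric(0), n = integer(0))
      } else res,
      art$traits, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(cfg$run_coherence)) {
    prof <- taxon_coherence_profile(cm, n_perm = cfg$n_perm,
                                    seed = cfg$seed + 1L)
    art$coherence <- file.path(cfg$out, "coherence_profile.tsv")
    utils::write.table(prof, art$coherence, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  log_msg("info", "wrote %d artifact(s) to %s", length(art), cfg$out)
  invisible(art)
}
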