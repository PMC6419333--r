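#' Simulation parameters for a synthetic cohort
#'
#' Assembles and validates the full parameter set of the generative model
#' behind [simulate_dataset()]. The defaults describe the package's
#' standard benchmark cohort: 200 samples over a 3 phyla x 4 genera x
#' 5 species taxonomy (60 species), log-normal baseline abundances and
#' library sizes, negative-binomial counts with dispersion 0.5, five
#' metadata variables (2 binary, 3 per-day frequency), and ten planted
#' effects of |log2FC| = 1.5 per covariate unit.
#'
#' @param n_samples Number of samples.
#' @param n_phyla,genera_per_phylum,species_per_genus Taxonomy shape.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-species baseline relative abundance (before normalization).
#' @param phi Negative-binomial dispersion (variance mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of the
#'   per-sample library size.
#' @param n_binary,n_frequency Number of binary (0/1) and per-day
#'   frequency metadata variables.
#' @param n_effects Number of planted (variable, taxon) effects; taxa are
#'   drawn from species whose baseline relative abundance is above its
#'   25th percentile, since fold changes of vanishingly rare taxa are not
#'   stably estimable by any method.
#' @param effect_log2fc Absolute planted log2 fold change per covariate
#'   unit; signs alternate.
#' @param genus_cor Strength (log-scale SD) of a shared per-genus latent
#'   factor inducing within-genus profile correlation; 0 disables it.
#' @param missing_rate Fraction of metadata cells masked to missing.
#' @param seed Mandatory integer seed.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_samples = 200L, n_phyla = 3L,
                       genera_per_phylum = 4L, species_per_genus = 5L,
                       baseline_meanlog = 0, baseline_sdlog = 1.5,
                       phi = 0.5,
                       libsize_meanlog = log(3e4), libsize_sdlog = 0.3,
                       n_binary = 2L, n_frequency = 3L,
                       n_effects = 10L, effect_log2fc = 1.5,
                       genus_cor = 0, missing_rate = 0.02,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_samples >= 2, n_phyla >= 1, genera_per_phylum >= 1,
            species_per_genus >= 1, phi >= 0, genus_cor >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_params")
}

sim_taxonomy <- function(p) {
  phyla <- seq_len(p$n_phyla)
  out <- character(0)
  genus_of <- integer(0)
  for (ph in phyla) for (ge in seq_len(p$genera_per_phylum)) {
    gid <- (ph - 1L) * p$genera_per_phylum + ge
    for (sp in seq_len(p$species_per_genus)) {
      out <- c(out, sprintf(
        "k__Bacteria;p__Phylum%d;c__Class%d;o__Order%d;f__Family%d;g__Genus%d;s__species%d_%d",
        ph, ph, ph, gid, gid, gid, sp))
      genus_of <- c(genus_of, gid)
    }
  }
  list(lineages = out, genus = genus_of)
}

#' Simulate a synthetic cohort with planted metadata effects
#'
#' Generates counts from the same model the GLM engine fits:
#' \deqn{y_{ij} \sim NB(\mu_{ij}, \phi), \quad
#'   \log \mu_{ij} = \log N_i + a_j + \sum_k b_{jk} x_{ik},}
#' with \eqn{a_j} the log baseline relative abundance, \eqn{N_i} a
#' log-normal library size, and nonzero slopes \eqn{b_{jk}} only for the
#' planted (variable, taxon) pairs. Binary covariates are Bernoulli(0.5);
#' frequency covariates are drawn from the questionnaire categories of
#' [DEFAULT_FREQUENCY_MAP] and recoded to events/day. Counts are always
#' generated from the complete covariates; the metadata table is masked
#' to missing afterwards, so listwise deletion is exercised downstream.
#' Everything is deterministic given `params$seed`.
#'
#' @param params A [sim_params] object.
#' @return A list with `counts` ([otu_counts]), `metadata` (numeric
#'   data.frame, sample ids as row names) and `truth` (data.frame of
#'   planted effects: `variable`, `taxon`, `log2fc`).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    tax <- sim_taxonomy(p)
    n_taxa <- length(tax$lineages)
    a <- stats::rnorm(n_taxa, p$baseline_meanlog, p$baseline_sdlog)
    rel <- exp(a) / sum(exp(a))
    N <- stats::rlnorm(p$n_samples, p$libsize_meanlog, p$libsize_sdlog)
    sample_ids <- sprintf("S%03d", seq_len(p$n_samples))

    vars <- list()
    for (k in seq_len(p$n_binary)) {
      vars[[sprintf("bin%d", k)]] <- stats::rbinom(p$n_samples, 1L, 0.5)
    }
    cats <- names(DEFAULT_FREQUENCY_MAP)
    for (k in seq_len(p$n_frequency)) {
      resp <- sample(cats, p$n_samples, replace = TRUE)
      vars[[sprintf("freq%d", k)]] <- recode_frequency(resp)
    }
    x <- as.data.frame(vars)

    # planted effects: variables cycled, taxa sampled once without
    # replacement from the reliably-observable baseline range
    eligible <- which(rel > stats::quantile(rel, 0.25))
    if (p$n_effects > 0L) {
      planted_taxa <- sample(eligible, p$n_effects)
      planted_vars <- rep_len(names(vars), p$n_effects)
      signs <- rep_len(c(1, -1), p$n_effects)
      truth <- data.frame(variable = planted_vars,
                          taxon = tax$lineages[planted_taxa],
                          log2fc = signs * p$effect_log2fc,
                          stringsAsFactors = FALSE)
    } else {
      planted_taxa <- integer(0)
      truth <- data.frame(variable = character(0), taxon = character(0),
                          log2fc = numeric(0))
    }

    b <- matrix(0, n_taxa, ncol(x))  # natural-log slopes
    for (r in seq_len(nrow(truth))) {
      j <- match(truth$taxon[r], tax$lineages)
      k <- match(truth$variable[r], names(vars))
      b[j, k] <- truth$log2fc[r] * log(2)
    }

    log_mu <- outer(log(rel), log(N), `+`) +
      b %*% t(as.matrix(x))
    if (p$genus_cor > 0) {
      z <- matrix(stats::rnorm(max(tax$genus) * p$n_samples),
                  max(tax$genus), p$n_samples)
      log_mu <- log_mu + p$genus_cor * z[tax$genus, ]
    }
    mu <- exp(log_mu)
    counts <- matrix(
      if (p$phi > 0) {
        stats::rnbinom(length(mu), size = 1 / p$phi, mu = mu)
      } else {
        stats::rpois(length(mu), lambda = mu)
      },
      n_taxa, p$n_samples)

    meta <- x
    if (p$missing_rate > 0) {
      mask <- matrix(stats::runif(nrow(meta) * ncol(meta)) < p$missing_rate,
                     nrow(meta), ncol(meta))
      for (k in seq_len(ncol(meta))) meta[mask[, k], k] <- NA
    }
    rownames(meta) <- sample_ids

    list(counts = otu_counts(counts, lineages = tax$lineages,
                             sample_ids = sample_ids),
         metadata = meta, truth = truth)
  })
}

#' Simulate a trait probability matrix with planted linkage
#'
#' Emulates a text-mining-style trait table: unlinked traits are
#' independent Beta(0.5, 0.5) probabilities (U-shaped, as confidence
#' scores tend to be); each linked trait tracks the direction of the
#' planted response to its metadata variable — Beta(8, 2) on taxa with a
#' positive planted effect, Beta(1, 9) on taxa with a negative one, and
#' a Beta(2, 8) background elsewhere.
#'
#' @param taxa Character vector of taxon names (lineage strings).
#' @param truth Truth data.frame from [simulate_dataset()].
#' @param n_traits Total number of traits (>= 1).
#' @param linked_variables Metadata variables to link one trait each to;
#'   default none (all traits null).
#' @param seed Integer seed.
#' @return A numeric matrix (taxa x traits) in [0, 1], with a `linked`
#'   attribute naming the linked trait columns.
#' @export
simulate_traits <- function(taxa, truth, n_traits, linked_variables = NULL,
                            seed) {
  stopifnot(n_traits >= 1)
  if (length(linked_variables) > n_traits) {
    stop("more linked variables than traits", call. = FALSE)
  }
  withr::with_seed(seed, {
    m <- matrix(stats::rbeta(length(taxa) * n_traits, 0.5, 0.5),
                length(taxa), n_traits,
                dimnames = list(taxa, sprintf("trait%03d", seq_len(n_traits))))
    linked <- character(0)
    for (i in seq_along(linked_variables)) {
      v <- linked_variables[i]
      up <- truth$taxon[truth$variable == v & truth$log2fc > 0]
      down <- truth$taxon[truth$variable == v & truth$log2fc < 0]
      col <- sprintf("trait%03d", i)
      base <- stats::rbeta(length(taxa), 2, 8)
      base[taxa %in% up] <- stats::rbeta(sum(taxa %in% up), 8, 2)
      base[taxa %in% down] <- stats::rbeta(sum(taxa %in% down), 1, 9)
      m[, col] <- base
      linked <- c(linked, stats::setNames(col, v))
    }
    attr(m, "linked") <- linked
    m
  })
}
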