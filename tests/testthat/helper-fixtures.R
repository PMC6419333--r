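# Small fixture builders shared across the suite. Everything is generated
# in code; no data files.

toy_lineages <- function(n_genera = 2, species_per_genus = 2) {
  out <- character(0)
  for (g in seq_len(n_genera)) for (s in seq_len(species_per_genus)) {
    out <- c(out, sprintf(
      "k__Bacteria;p__Phylum1;c__Class1;o__Order1;f__Family%d;g__Genus%d;s__species%d_%d",
      g, g, g, s))
  }
  out
}

toy_counts <- function(mat = NULL, lineages = NULL) {
  if (is.null(mat)) {
    mat <- matrix(c(3, 4, 5, 6, 10, 0, 0, 2), nrow = 4, ncol = 2,
                  byrow = TRUE)
  }
  if (is.null(lineages)) lineages <- toy_lineages()[seq_len(nrow(mat))]
  otu_counts(mat, lineages = lineages,
             sample_ids = paste0("S", seq_len(ncol(mat))))
}

write_counts_tsv <- function(cm, path = tempfile(fileext = ".tsv")) {
  write_count_table(cm, path)
  path
}

write_meta_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(cbind(sample = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

# default benchmark cohort used by several suites; cached per session
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_params(seed = 42))
    cache
  }
})

# literal re-derivation of the coverage-based richness estimator, kept
# independent of the package implementation
ace_oracle <- function(v, thr = 10) {
  v <- v[v > 0]
  rare <- v[v <= thr]
  s_ab <- sum(v > thr); s_r <- length(rare)
  if (s_r == 0) return(s_ab)
  f1 <- sum(rare == 1)
  n_r <- sum(rare)
  c_ace <- 1 - f1 / n_r
  if (c_ace <= 0) return(NA_real_)
  fi <- tabulate(rare, nbins = thr)
  g2 <- max((s_r / c_ace) * sum((1:thr) * (0:(thr - 1)) * fi) /
              (n_r * (n_r - 1)) - 1, 0)
  s_ab + s_r / c_ace + (f1 / c_ace) * g2
}

# brute-force list of all permutations of a vector
enumerate_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in enumerate_permutations(v[-i])) {
      out <- c(out, list(c(v[i], rest)))
    }
  }
  out
}

random_distance <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 5), n)
    as.matrix(dist(x))
  })
}
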