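#' Pairwise affinity (distance) matrix between items
#'
#' Builds a symmetric distance matrix from an items-by-variables feature
#' table, for use with [mantel_test()]. `"spearman-distance"` is
#' 1 - Spearman correlation between item profiles (rank-based, so robust
#' across feature spaces of different scale); `"bray-curtis"` is the
#' standard ecological dissimilarity on raw counts.
#'
#' @param features Numeric matrix or data.frame, items in rows (at least
#'   3), non-negative for Bray-Curtis; no all-zero rows.
#' @param metric `"spearman-distance"` or `"bray-curtis"`.
#' @return Symmetric numeric matrix with zero diagonal and item labels,
#'   with a `metric` attribute.
#' @export
affinity_matrix <- function(features,
                            metric = c("spearman-distance", "bray-curtis")) {
  metric <- match.arg(metric)
  m <- as.matrix(features)
  if (nrow(m) < 3L) stop("at least 3 items required", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  zero <- rowSums(abs(m)) == 0
  if (any(zero)) {
    stop(sprintf("all-zero feature row for item '%s'",
                 rownames(m)[which(zero)[1]]), call. = FALSE)
  }
  d <- switch(metric,
    "spearman-distance" = 1 - stats::cor(t(m), method = "spearman"),
    "bray-curtis" = as.matrix(vegan::vegdist(m, method = "bray"))
  )
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "metric") <- metric
  d
}

upper_tri <- function(d) d[upper.tri(d)]

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the strict upper triangles
#' of `d1` and `d2`. Significance is assessed by simultaneously permuting
#' the rows and columns of `d2`: with random permutations the one-sided
#' (greater) p-value is \eqn{(b + 1)/(n_{perm} + 1)}, counting
#' permutations whose statistic is at least the observed one; with
#' `exact = TRUE` all \eqn{n!} relabelings are enumerated and the p-value
#' is the exact fraction at or above the observed statistic.
#'
#' @param d1,d2 Symmetric distance matrices over the same items in the
#'   same order (labels are checked when both are named).
#' @param n_perm Number of random permutations (ignored when exact).
#' @param seed Integer seed for the permutation draw.
#' @param exact Enumerate all permutations (feasible up to ~8 items).
#' @return A list with `r`, `p`, `n_perm` (permutations actually used)
#'   and `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L, exact = FALSE) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) {
    stop("distance matrices must have identical dimensions", call. = FALSE)
  }
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("distance matrices must be over the same items in the same order",
         call. = FALSE)
  }
  n <- nrow(d1)
  v1 <- upper_tri(d1)
  if (stats::sd(v1) < 1e-300 || stats::sd(upper_tri(d2)) < 1e-300) {
    stop("E_UNDEFINED: zero variance in a distance matrix upper triangle",
         call. = FALSE)
  }
  r_obs <- stats::cor(v1, upper_tri(d2))
  perm_r <- function(p) stats::cor(v1, upper_tri(d2[p, p]))
  if (exact) {
    perms <- all_permutations(n)
    stats_ <- vapply(perms, perm_r, numeric(1))
    p <- mean(stats_ >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = length(perms), exact = TRUE))
  }
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  b <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      perm_r(sample.int(n)) >= r_obs - 1e-12
    }, logical(1)))
  })
  list(r = r_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
       exact = FALSE)
}

all_permutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to 8 items", call. = FALSE)
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Within-taxon coherence of count profiles versus a permuted-table null
#'
#' Checks the biological consistency of a species-level count table:
#' species in the same higher-level group (genus, family, ...) should
#' have more similar abundance profiles than random sets of species of
#' the same sizes drawn from a table whose rows were independently
#' permuted across samples. For each rank from kingdom to genus the
#' observed statistic is the mean over groups (>= 2 members) of the mean
#' pairwise Spearman correlation between member species' log1p count
#' profiles; the null repeats this on the permuted table with freshly
#' drawn random groups, `n_perm` times.
#'
#' @param cm Species-level [otu_counts] with lineage strings.
#' @param n_perm Number of permutation replicates.
#' @param seed Integer seed.
#' @param ranks Ranks to evaluate (default kingdom through genus).
#' @return A data.frame of class `"coherence_profile"` with one row per
#'   evaluable rank: `rank`, `n_groups`, `observed`, `null_mean`,
#'   `null_sd`, `p` (empirical, add-one corrected).
#' @export
taxon_coherence_profile <- function(cm, n_perm = 100, seed = 1L,
                                    ranks = names(TAXONOMIC_RANKS)[1:6]) {
  logc <- log1p(cm$counts)
  sim <- stats::cor(t(logc), method = "spearman")
  group_stat <- function(simmat, groups) {
    vals <- vapply(groups, function(g) {
      s <- simmat[g, g]
      mean(s[upper.tri(s)])
    }, numeric(1))
    mean(vals)
  }
  # group memberships per rank (indices of member rows)
  rank_groups <- lapply(ranks, function(rk) {
    lab <- lineage_at_rank(cm$lineages, rk)
    g <- split(seq_along(lab), lab)
    g[names(g) != "NA" & lengths(g) >= 2L & !is.na(names(g))]
  })
  names(rank_groups) <- ranks
  eval_ranks <- ranks[vapply(rank_groups, length, integer(1)) >= 1L]
  if (length(eval_ranks) == 0L) {
    stop("no rank has a group with at least 2 member species",
         call. = FALSE)
  }
  observed <- vapply(eval_ranks, function(rk)
    group_stat(sim, rank_groups[[rk]]), numeric(1))

  n_taxa <- nrow(logc)
  null_mat <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- t(apply(logc, 1L, sample))
      psim <- stats::cor(t(perm), method = "spearman")
      vapply(eval_ranks, function(rk) {
        sizes <- lengths(rank_groups[[rk]])
        rand_groups <- lapply(sizes, function(sz) sample.int(n_taxa, sz))
        group_stat(psim, rand_groups)
      }, numeric(1))
    }, numeric(length(eval_ranks)))
  })
  if (length(eval_ranks) == 1L) null_mat <- matrix(null_mat, nrow = 1L)
  p <- vapply(seq_along(eval_ranks), function(i)
    (sum(null_mat[i, ] >= observed[i]) + 1) / (n_perm + 1), numeric(1))
  structure(data.frame(
    rank = eval_ranks,
    n_groups = vapply(rank_groups[eval_ranks], length, integer(1)),
    observed = observed,
    null_mean = rowMeans(null_mat),
    null_sd = apply(null_mat, 1L, stats::sd),
    p = p, row.names = NULL
  ), class = c("coherence_profile", "data.frame"))
}
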