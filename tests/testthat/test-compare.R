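# fabricated shift matrix with known column structure
toy_shift <- function(log2fc, p = NULL) {
  taxa <- paste0("g__G", seq_len(nrow(log2fc)))
  if (is.null(p)) p <- matrix(0.5, nrow(log2fc), ncol(log2fc))
  shift_matrix("genus", taxa, colnames(log2fc), log2fc, p,
               n_samples = rep(100, ncol(log2fc)))
}

test_that("shift matrices assemble one column per usable variable", {
  sim <- default_sim()
  cm <- filter_taxa(filter_samples(sim$counts), 1)
  meta <- sim$metadata
  meta$constant <- 1
  expect_warning(
    sm <- build_shift_matrix(cm, meta, variables = c("bin1", "bin2",
                                                     "freq1", "constant"),
                             rank = "genus"),
    "constant")
  expect_equal(sm$conditions, c("bin1", "bin2", "freq1"))
  expect_equal(length(sm$taxa), 12L)  # 3 phyla x 4 genera

  # the column equals differential_abundance on the collapsed matrix
  cmg <- filter_taxa(collapse_to_level(cm, "genus"), 1)
  da <- differential_abundance(cmg, meta, "bin1")
  expect_equal(unname(sm$log2fc[, "bin1"]),
               da$log2fc[match(sm$taxa, da$taxon)])

  sp <- suppressWarnings(
    build_shift_matrix(cm, meta, variables = c("bin1", "bin2"),
                       rank = "species"))
  expect_equal(sp$conditions, c("bin1", "bin2"))
  expect_gt(length(sp$taxa), length(sm$taxa))

  meta_bad <- meta["S001", , drop = FALSE]
  cm1 <- subset_cm <- otu_counts(cm$counts[, 1, drop = FALSE],
                                 lineages = cm$lineages,
                                 sample_ids = cm$sample_ids[1])
  expect_error(
    suppressWarnings(build_shift_matrix(cm1, meta_bad, rank = "genus")),
    "E_EMPTY")
})

test_that("condition similarity is 1 for duplicates and -1 for negations", {
  withr::with_seed(8, v <- rnorm(30))
  m <- cbind(a = v, b = v, c = -v)
  sim <- condition_similarity(toy_shift(m))
  expect_equal(sim["a", "b"], 1)
  expect_equal(sim["a", "c"], -1)
  expect_equal(unname(diag(sim)), rep(1, 3))
  expect_equal(sim, t(sim))
  simp <- condition_similarity(toy_shift(m), method = "pearson")
  expect_equal(simp["a", "c"], -1)
})

test_that("independent shift columns have near-zero similarity", {
  withr::with_seed(17, m <- cbind(a = rnorm(1000), b = rnorm(1000)))
  sim <- condition_similarity(toy_shift(m))
  expect_lt(abs(sim["a", "b"]), 0.1)
})

test_that("similarity is invariant to row permutation and monotone
           transforms (spearman)", {
  withr::with_seed(18, m <- cbind(a = rnorm(50), b = rnorm(50),
                                  c = rnorm(50)))
  s0 <- condition_similarity(toy_shift(m))
  perm <- withr::with_seed(19, sample(50))
  s1 <- condition_similarity(toy_shift(m[perm, ]))
  expect_equal(unclass(s0), unclass(s1))
  s2 <- condition_similarity(toy_shift(cbind(a = exp(m[, "a"]),
                                             b = m[, "b"]^3,
                                             c = m[, "c"])))
  expect_equal(unclass(s0), unclass(s2))
})

test_that("pairs sharing too few finite taxa are NA with a warning", {
  m <- cbind(a = c(1, 2, 3, NA, NA), b = c(NA, NA, NA, 1, 2))
  expect_warning(sim <- condition_similarity(toy_shift(m)), "fewer than 3")
  expect_true(is.na(sim["a", "b"]))
  expect_error(condition_similarity(toy_shift(m[, 1, drop = FALSE])),
               "two conditions")
})

test_that("query ranking puts an exact copy first with similarity 1", {
  withr::with_seed(20, m <- matrix(rnorm(200), 50, 4,
                                   dimnames = list(NULL, letters[1:4])))
  sm <- toy_shift(m)
  q <- setNames(m[, "c"], sm$taxa)
  res <- query_shift(sm, q)
  expect_equal(res$condition[1], "c")
  expect_equal(res$similarity[1], 1)
  # remaining similarities equal the condition_similarity row for c
  simm <- condition_similarity(sm)
  expect_equal(setNames(res$similarity, res$condition)[c("a", "b", "d")],
               simm["c", c("a", "b", "d")])

  expect_error(query_shift(sm, setNames(1:5, paste0("zz", 1:5))),
               "only 0 taxa")
  expect_error(query_shift(sm, unname(q)), "named")
})

test_that("noisy copies of a condition still rank first", {
  withr::with_seed(21, m <- matrix(rnorm(240), 60, 4,
                                   dimnames = list(NULL, letters[1:4])))
  sm <- toy_shift(m)
  wins <- withr::with_seed(22, {
    vapply(1:50, function(i) {
      q <- setNames(m[, "b"] + rnorm(60, 0, 0.1 * sd(m[, "b"])), sm$taxa)
      query_shift(sm, q)$condition[1] == "b"
    }, logical(1))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("discriminative-taxon selection recovers a planted two-block
           structure", {
  withr::with_seed(25, {
    conds <- c(paste0("A", 1:4), paste0("B", 1:4))
    u <- rep(c(-1, 1), each = 4)
    planted <- t(vapply(1:5, function(j)
      1.5 * u + rnorm(8, 0, 0.2), numeric(8)))
    null <- outer(rnorm(50, 0, 0.3), u) + matrix(rnorm(400), 50, 8)
    m <- rbind(planted, null)
    colnames(m) <- conds
  })
  taxa <- c(paste0("g__Planted", 1:5), paste0("g__Null", sprintf("%02d", 1:50)))
  sm <- shift_matrix("genus", taxa, conds, m,
                     matrix(0.5, nrow(m), 8), rep(100, 8))
  top <- select_discriminative_taxa(sm, k = 5)
  expect_setequal(top, paste0("g__Planted", 1:5))
  # deterministic given the same input
  expect_identical(as.character(top),
                   as.character(select_discriminative_taxa(sm, k = 5)))
  # k beyond the taxon count returns everything, ranked
  all_ranked <- select_discriminative_taxa(sm, k = 1000)
  expect_equal(length(all_ranked), 55L)
})

test_that("all-equal rows score F = 0 and ties fall back to label order", {
  m <- matrix(1, 4, 4, dimnames = list(NULL, letters[1:4]))
  m[1, ] <- c(0, 0, 5, 5)  # one informative row to define clusters
  sm <- shift_matrix("genus", paste0("g__", c("d", "c", "b", "a")),
                     letters[1:4], m, matrix(0.5, 4, 4), rep(10, 4))
  top <- suppressWarnings(select_discriminative_taxa(sm, k = 4))
  f <- attr(top, "F")
  expect_equal(unname(f[-1]), rep(0, 3))
  expect_equal(as.character(top[-1]), c("g__a", "g__b", "g__c"))
})

test_that("row z-scoring standardizes, warns on constants, and is
           idempotent", {
  m <- rbind(c(1, 2, 3), c(5, 5, 5))
  expect_warning(z <- zscore_rows(m), "constant")
  expect_equal(mean(z[1, ]), 0)
  expect_equal(sd(z[1, ]), 1)
  expect_equal(z[2, ], c(0, 0, 0))
  z2 <- suppressWarnings(zscore_rows(z))
  expect_equal(z[1, ], z2[1, ], tolerance = 1e-12)
})
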