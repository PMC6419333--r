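test_that("affinity matrices are symmetric distances with known values", {
  f <- rbind(a = c(1, 0), b = c(0, 1), c = c(2, 2), d = c(1, 1))
  bc <- affinity_matrix(f, "bray-curtis")
  expect_equal(bc["a", "b"], 1)          # disjoint supports
  expect_equal(bc["c", "d"], 1 / 3)      # sum|u-v| / sum(u+v) = 2/6
  expect_equal(unname(diag(bc)), rep(0, 4))
  expect_equal(bc, t(bc))

  dup <- rbind(a = c(3, 1, 4), b = c(3, 1, 4), c = c(1, 5, 9))
  sp <- affinity_matrix(dup, "spearman-distance")
  expect_equal(sp["a", "b"], 0)
  expect_true(all(sp >= 0))

  withzero <- rbind(a = c(1, 2), b = c(0, 0), c = c(2, 1))
  expect_error(affinity_matrix(withzero), "all-zero.*b")
  expect_error(affinity_matrix(f[1:2, ]), "at least 3")
})

test_that("mantel of a matrix with itself gives r = 1 at the minimum p", {
  d <- random_distance(12, seed = 61)
  res <- mantel_test(d, d, n_perm = 199, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
})

test_that("the mantel r statistic is symmetric in its arguments and
           matches vegan", {
  d1 <- random_distance(15, seed = 62)
  d2 <- random_distance(15, seed = 63)
  r12 <- mantel_test(d1, d2, n_perm = 99, seed = 1)$r
  r21 <- mantel_test(d2, d1, n_perm = 99, seed = 1)$r
  expect_equal(r12, r21)
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
  expect_equal(r12, unname(veg$statistic), tolerance = 1e-12)
})

test_that("exact enumeration reproduces a brute-force oracle on 4 items", {
  d1 <- random_distance(4, seed = 64)
  d2 <- random_distance(4, seed = 65)
  res <- mantel_test(d1, d2, exact = TRUE)
  expect_equal(res$n_perm, 24L)

  # independent brute force over all 24 relabelings
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut])
  rs <- vapply(enumerate_permutations(1:4),
               function(p) cor(d1[ut], d2[p, p][ut]), numeric(1))
  expect_equal(res$p, mean(rs >= r_obs - 1e-12))
  expect_equal(res$r, r_obs)
})

test_that("mantel p-values honor their bounds and validate input", {
  d1 <- random_distance(10, seed = 66)
  d2 <- random_distance(10, seed = 67)
  res <- mantel_test(d1, d2, n_perm = 99, seed = 5)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  expect_error(mantel_test(d1, d2[1:9, 1:9]), "identical dimensions")
  expect_error(mantel_test(d1, d2, n_perm = 10), "at least 99")
  flat <- matrix(1, 10, 10); diag(flat) <- 0; flat[] <- 0
  expect_error(mantel_test(flat, d2), "E_UNDEFINED")
  d2named <- d2; rownames(d2named) <- colnames(d2named) <- letters[1:10]
  d1named <- d1; rownames(d1named) <- colnames(d1named) <- letters[10:1]
  expect_error(mantel_test(d1named, d2named), "same items")
})

test_that("coherence exceeds the permuted-table null when genera share a
           latent factor", {
  sim <- simulate_dataset(sim_params(n_samples = 80, genus_cor = 0.8,
                                     n_effects = 0, missing_rate = 0,
                                     seed = 71))
  prof <- taxon_coherence_profile(sim$counts, n_perm = 60, seed = 11)
  gen <- prof[prof$rank == "genus", ]
  expect_gt(gen$observed, gen$null_mean)
  expect_lte(gen$p, 0.05)
  # deterministic given the seed
  prof2 <- taxon_coherence_profile(sim$counts, n_perm = 60, seed = 11)
  expect_equal(prof, prof2)
})

test_that("a pre-permuted table sits inside its own null band", {
  sim <- simulate_dataset(sim_params(n_samples = 60, n_effects = 0,
                                     missing_rate = 0, seed = 72))
  shuffled <- withr::with_seed(73, {
    m <- t(apply(sim$counts$counts, 1, sample))
    otu_counts(m, lineages = sim$counts$lineages,
               sample_ids = sim$counts$sample_ids)
  })
  prof <- taxon_coherence_profile(shuffled, n_perm = 60, seed = 12)
  expect_true(all(abs(prof$observed - prof$null_mean) <=
                    3 * prof$null_sd + 1e-12))
})

test_that("the coherence observed statistic ignores sample order", {
  sim <- simulate_dataset(sim_params(n_samples = 40, genus_cor = 0.5,
                                     n_effects = 0, missing_rate = 0,
                                     seed = 74))
  prof <- taxon_coherence_profile(sim$counts, n_perm = 20, seed = 9)
  perm <- withr::with_seed(75, sample(40))
  cmp <- otu_counts(sim$counts$counts[, perm],
                    lineages = sim$counts$lineages,
                    sample_ids = sim$counts$sample_ids[perm])
  prof2 <- taxon_coherence_profile(cmp, n_perm = 20, seed = 9)
  expect_equal(prof$observed, prof2$observed)
})
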