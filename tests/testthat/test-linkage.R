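test_that("pairwise recombination fractions match hand counts", {
  g <- geno_tbl_from(a = c("A", "A", "B", "B"), b = c("A", "B", "B", "A"),
                     c = c("A", "A", "B", "B"), d = c("A", "U", "B", "H"))
  rf <- pairwise_rf(g, min_informative = 1)
  expect_equal(rf$r["a", "b"], 0.5)     # lines 2 and 4 recombinant
  expect_equal(rf$r["a", "c"], 0)       # identical columns
  expect_equal(rf$r["a", "d"], 0)       # H and U excluded
  expect_equal(rf$n["a", "d"], 2)
  expect_true(isSymmetric(rf$r))
  expect_equal(unname(diag(rf$r)), rep(0, 4))
  # pairs under the informativeness floor are undefined
  rf20 <- pairwise_rf(g, min_informative = 3)
  expect_true(is.na(rf20$r["a", "d"]))
})

test_that("single-linkage grouping follows the transitive closure of the cutoff graph", {
  mk <- c("a", "b", "c", "d", "e")
  r <- matrix(0.45, 5, 5, dimnames = list(mk, mk)); diag(r) <- 0
  r["a", "b"] <- r["b", "a"] <- 0.15
  r["b", "c"] <- r["c", "b"] <- 0.15
  r["a", "c"] <- r["c", "a"] <- 0.35   # linked only through b
  r["d", "e"] <- r["e", "d"] <- 0.05
  rf <- structure(list(r = r, n = matrix(92, 5, 5, dimnames = list(mk, mk))),
                  class = "pairwise_rf")
  grp <- group_markers(rf, cutoff = 0.2)
  expect_equal(grp$group[grp$marker == "a"], grp$group[grp$marker == "c"])
  expect_false(grp$group[grp$marker == "a"] == grp$group[grp$marker == "d"])
  expect_equal(grp$group[grp$marker == "a"], 1)  # larger group ranked first
  expect_false(any(grp$singleton))
})

test_that("simulated chromosomes are recovered as separate linkage groups", {
  sim <- quick_sim(n_markers = 15, length_cM = 50, n_chrom = 3, n_lines = 92,
                   missing_rate = 0.1, seed = 23)
  rf <- pairwise_rf(sim$geno)
  grp <- group_markers(rf, cutoff = 0.2)
  expect_equal(dplyr::n_distinct(grp$group), 3)
  truth_chrom <- sim$truth$map$chrom[match(grp$marker, sim$truth$map$marker)]
  expect_equal(dplyr::n_distinct(paste(grp$group, truth_chrom)), 3)
})

test_that("COUNT sums transitions between consecutive informative calls and is reversal-invariant", {
  g <- geno_tbl_from(a = c("A", "A", "B", "B"), b = c("A", "B", "B", "A"))
  expect_equal(count_recombinations(g, c("a", "b")), 2)
  g1 <- geno_tbl_from(a = c("A", "B"))
  expect_equal(count_recombinations(g1, "a"), 0)
  # H/U are skipped, not counted as transitions
  g2 <- geno_tbl_from(a = c("A", "A"), b = c("H", "U"), c = c("A", "B"))
  expect_equal(count_recombinations(g2, c("a", "b", "c")), 1)
  # property: reversal invariance on random simulated matrices
  for (s in 1:3) {
    sim <- quick_sim(n_markers = 12, n_lines = 40, missing_rate = 0.2, seed = s)
    ord <- sample(sim$truth$map$marker)
    expect_equal(count_recombinations(sim$geno, ord),
                 count_recombinations(sim$geno, rev(ord)))
  }
})

test_that("greedy ordering resolves the metric order of three markers", {
  sim <- quick_sim(n_markers = 3, length_cM = 20, n_lines = 92, seed = 41)
  ord <- order_record(sim$geno, n_starts = 10, seed = 1)
  expect_identical(ord, sim$truth$map$marker)  # canonical orientation = truth
})

test_that("greedy ordering plus rippling attains the exhaustive COUNT minimum on small groups", {
  for (s in 1:3) {
    sim <- quick_sim(n_markers = 7, length_cM = 45, n_lines = 60,
                     missing_rate = 0.2, seed = 100 + s)
    ord <- ripple(sim$geno, order_record(sim$geno, n_starts = 10, seed = s))
    expect_equal(count_recombinations(sim$geno, ord),
                 brute_force_min_count(sim$geno))
  }
})

test_that("rippling never increases COUNT and repairs an adjacent swap", {
  sim <- quick_sim(n_markers = 12, length_cM = 60, n_lines = 92, seed = 53)
  truth <- sim$truth$map$marker
  swapped <- truth; swapped[6:7] <- swapped[7:6]
  rippled <- ripple(sim$geno, swapped, window = 5)
  expect_identical(rippled, truth)
  expect_lt(count_recombinations(sim$geno, rippled),
            count_recombinations(sim$geno, swapped))
  # already-optimal order is returned unchanged (strict-improvement rule)
  expect_identical(ripple(sim$geno, truth, window = 5), truth)
  # oversized window: exhaustive for small groups, error otherwise
  small <- as_geno_tbl(as_geno_matrix(sim$geno)[, truth[1:5]])
  expect_identical(ripple(small, truth[1:5], window = 10), truth[1:5])
  expect_error(ripple(sim$geno, truth, window = 20), "8 markers")
})

test_that("singleton correction replaces isolated flank-contradicting calls only", {
  g <- geno_tbl_from(m1 = c("A", "A"), m2 = c("A", "A"), m3 = c("B", "B"),
                     m4 = c("A", "B"), m5 = c("A", "A"), m6 = c("A", "A"))
  res <- correct_singletons(g, paste0("m", 1:6))
  m <- as_geno_matrix(res$geno)
  expect_identical(unname(m[1, ]), c("A", "A", "A", "A", "A", "A"))  # singleton fixed
  expect_identical(unname(m[2, ]), c("A", "A", "B", "B", "A", "A"))  # run of 2 kept
  expect_equal(nrow(res$log), 1)
  expect_identical(res$log$marker, "m3")
  # boundary calls are never corrected
  gb <- geno_tbl_from(m1 = c("B"), m2 = c("A"), m3 = c("A"))
  expect_identical(correct_singletons(gb, paste0("m", 1:3))$geno, gb)
  # nearest informative neighbours skip missing calls
  gu <- geno_tbl_from(m1 = c("A"), m2 = c("U"), m3 = c("B"), m4 = c("U"),
                      m5 = c("A"))
  mu <- as_geno_matrix(correct_singletons(gu, paste0("m", 1:5))$geno)
  expect_identical(unname(mu[1, ]), c("A", "U", "A", "U", "A"))
})

test_that("singleton correction reverts most injected genotyping errors", {
  # dense spacing so that injected errors rarely sit next to a genuine
  # crossover (whose disagreeing flanks hide the singleton)
  sim <- quick_sim(n_markers = 150, length_cM = 40, n_lines = 92, seed = 61)
  clean <- as_geno_matrix(sim$truth$geno)
  noisy_tbl <- apply_observation_noise(sim$truth$geno, error_rate = 0.01,
                                       seed = 62)
  noisy <- as_geno_matrix(noisy_tbl)
  injected <- which(noisy != clean)
  res <- correct_singletons(noisy_tbl, sim$truth$map$marker)
  fixed <- as_geno_matrix(res$geno)
  reverted <- mean(fixed[injected] == clean[injected])
  expect_gt(reverted, 0.9)
})

test_that("build_map recovers truth on clean data and is deterministic", {
  sim <- quick_sim(n_markers = 20, length_cM = 60, n_lines = 92, seed = 71)
  binned <- bin_identical(sim$geno, sim$marker_info)
  mp <- build_map(binned$geno, sim$marker_info, ril_correction = TRUE, seed = 71)
  truth <- sim$truth$map
  true_order <- truth$marker[truth$marker %in% mp$map$marker]
  got <- mp$map$marker
  expect_true(identical(got, true_order) || identical(got, rev(true_order)))
  expect_equal(sum(mp$groups$length_cM), max(truth$cM), tolerance = 0.25)
  mp2 <- build_map(binned$geno, sim$marker_info, ril_correction = TRUE, seed = 71)
  expect_identical(tidy(mp), tidy(mp2))
  # group takes its label from the majority physical chromosome
  expect_identical(unique(mp$map$group), "Ca1")
})

test_that("uncorrected genotyping errors inflate the map and correction restores it", {
  sim <- quick_sim(n_markers = 30, length_cM = 60, n_lines = 92,
                   error_rate = 0.01, seed = 83)
  truth_len <- max(sim$truth$map$cM)
  ord <- sim$truth$map$marker
  m <- as_geno_matrix(sim$geno)
  raw_len <- rilmap:::map_length_of(m, ord, TRUE)
  corr <- correct_singletons(sim$geno, ord)
  corr_len <- rilmap:::map_length_of(as_geno_matrix(corr$geno), ord, TRUE)
  expect_gt(raw_len, truth_len * 1.2)        # 1% error adds spurious cM
  expect_lt(abs(corr_len - truth_len) / truth_len, 0.2)
})

test_that("tidy, glance and autoplot expose the fitted map", {
  sim <- quick_sim(n_markers = 10, length_cM = 40, n_lines = 60, seed = 91)
  mp <- build_map(sim$geno, sim$marker_info, seed = 91)
  td <- tidy(mp)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("group", "rank", "marker", "r_adj", "cM_adj", "cM_cum"))
  expect_true(all(diff(td$cM_cum) >= 0))
  expect_equal(td$cM_cum[1], 0)
  gl <- glance(mp)
  expect_equal(gl$n_markers, nrow(td))
  expect_equal(gl$length_cM, max(td$cM_cum))
  expect_s3_class(autoplot(mp), "ggplot")
})
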