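test_that("map summary reports lengths, spacing and gaps per group", {
  sim <- quick_sim(n_markers = 12, length_cM = 44, n_lines = 80, seed = 7)
  mp <- build_map(sim$geno, sim$marker_info, ril_correction = TRUE, seed = 7)
  summ <- map_summary(mp)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$n_markers, 12)
  expect_equal(summ$length_cM, max(tidy(mp)$cM_cum))
  expect_equal(summ$mean_spacing_cM, summ$length_cM / 12)
  expect_equal(summ$largest_gap_cM, max(tidy(mp)$cM_adj))
})

test_that("Chakravarti method-4 estimates match closed-form arithmetic", {
  ref <- cpr01_reference("map_summary")
  est <- chakravarti_estimate(ref)
  lg1 <- est$groups$estimated_cM[est$groups$group == "LG1"]
  expect_equal(lg1, 75.5 * 171 / 169, tolerance = 1e-10)
  expect_equal(lg1, 76.39, tolerance = 0.01)
  expect_equal(est$estimated_cM, 664.6, tolerance = 0.001)
  expect_equal(est$coverage, 0.9825, tolerance = 0.001)
  # asymptote: dense groups inflate to themselves
  big <- tibble::tibble(length_cM = 100, n_markers = 1e6)
  expect_equal(chakravarti_estimate(big)$estimated_cM, 100, tolerance = 1e-4)
  # global mode applies the factor once to the totals
  glob <- chakravarti_estimate(ref, mode = "global")
  expect_equal(glob$estimated_cM, sum(ref$length_cM) * 1337 / 1335,
               tolerance = 1e-6)
  expect_gt(glob$coverage, 0.99)
  # degenerate groups are excluded with a warning
  expect_warning(
    chakravarti_estimate(tibble::tibble(length_cM = c(10, 0), n_markers = c(5, 1))),
    "excluded")
})

test_that("residual heterozygosity compares observed against the F_g expectation", {
  allhom <- geno_tbl_from(m1 = c("A", "B", "A"), m2 = c("B", "B", "A"))
  res <- residual_heterozygosity(allhom, g = 7)
  expect_equal(res$population_het, 0)
  expect_equal(res$fold, 0)
  sim <- quick_sim(n_markers = 40, n_lines = 600, generations = 7, seed = 15)
  res7 <- residual_heterozygosity(sim$truth$geno, g = 7)
  expect_equal(res7$fold, 1, tolerance = 0.3)
})

test_that("the distortion test applies the chi-square and allele-frequency band jointly", {
  bal <- distortion_test(c(rep("A", 46), rep("B", 46)))
  expect_equal(bal$chisq, 0)
  expect_false(bal$distorted)
  expect_identical(bal$direction, "none")

  skew <- distortion_test(c(rep("A", 70), rep("B", 22)))
  expect_equal(skew$chisq, 2 * 24^2 / 46, tolerance = 1e-10)
  expect_equal(skew$chisq, 25.04, tolerance = 0.01)
  expect_true(skew$distorted)
  expect_identical(skew$direction, "A")

  # significant p but frequency inside the (0.4, 0.6) band: not distorted
  inband <- distortion_test(c(rep("A", 50), rep("B", 42)))
  expect_gt(inband$allele_freq, 0.4)
  expect_lt(inband$allele_freq, 0.6)
  expect_false(inband$distorted)

  # undefined when no homozygous calls
  und <- distortion_test(c("H", "U", "H"))
  expect_true(is.na(und$chisq))
  expect_false(und$distorted)
})

test_that("the chi-square statistic and p-value agree with the stats oracle", {
  set.seed(99)
  for (i in 1:20) {
    nA <- rpois(1, 40) + 1L
    nB <- rpois(1, 40) + 1L
    rec <- distortion_test(c(rep("A", nA), rep("B", nB)))
    oracle <- suppressWarnings(
      stats::chisq.test(c(nA, nB), p = c(0.5, 0.5), correct = FALSE))
    expect_equal(rec$chisq, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(rec$p, unname(oracle$p.value), tolerance = 1e-10)
  }
})

test_that("distortion scanning supports band disabling and Bonferroni adjustment", {
  sim <- quick_sim(n_markers = 30, n_lines = 92, seed = 47)
  scan <- distortion_scan(sim$geno, af_bounds = NULL)
  expect_equal(nrow(scan), 30)
  expect_true(all(scan$nA + scan$nB + scan$nH + scan$nU == 92))
  bonf <- distortion_scan(sim$geno, af_bounds = NULL, adjust = "bonferroni")
  expect_true(all(bonf$p >= scan$p))
  expect_lte(sum(bonf$distorted), sum(scan$distorted))
})

test_that("SDR detection groups consecutive same-direction distorted markers", {
  mk <- paste0("m", 1:9)
  map_tbl <- fake_map_tbl(mk, step = 2)
  dist <- tibble::tibble(
    marker = mk,
    distorted = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    direction = c("none", "A", "A", "A", "none", "A", "A", "B", "B")
  )
  sdr <- detect_sdr(map_tbl, dist)
  expect_equal(nrow(sdr), 3)           # direction change splits a run
  expect_equal(sdr$n_markers, c(3, 2, 2))
  expect_equal(sdr$direction, c("A", "A", "B"))
  expect_equal(sdr$start_cM[1], 2)
  expect_equal(sdr$size_cM[1], 4)
  # a tolerated gap merges runs of the same direction
  sdr1 <- detect_sdr(map_tbl, dist, max_gap_markers = 1)
  expect_equal(nrow(sdr1), 2)
  expect_equal(sdr1$n_markers[1], 5)
  # orientation invariance: flipping the map yields the same regions
  flipped <- map_tbl
  flipped$rank <- rev(flipped$rank)
  flipped$cM_cum <- max(map_tbl$cM_cum) - map_tbl$cM_cum
  sdr_f <- detect_sdr(flipped, dist)
  expect_equal(nrow(sdr_f), 3)
  expect_setequal(sdr_f$size_cM, sdr$size_cM)
})

test_that("simulated viability distortion is detected as an SDR at the locus", {
  hits <- 0L
  for (s in 1:5) {
    dl <- tibble::tibble(marker = "Ca1_m008", w = 0.5, disfavored = "B")
    sim <- quick_sim(n_markers = 15, length_cM = 40, n_lines = 92,
                     distortion_loci = dl, seed = 200 + s)
    scan <- distortion_scan(sim$truth$geno)
    sdr <- detect_sdr(fake_map_tbl(sim$truth$map$marker, step = 40 / 14),
                      scan)
    ok <- nrow(sdr) > 0 &&
      any(vapply(sdr$markers, function(m) "Ca1_m008" %in% m, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})
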