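test_that("marker anchoring classifies by the majority-chromosome rule", {
  mk <- paste0("m", 1:10)
  map_tbl <- fake_map_tbl(mk)
  info <- fake_marker_info(map_tbl, chrom = "Ca4",
                           chrom_override = list(idx = 5, chrom = "Ca6"))
  info$chrom[9] <- NA; info$scaffold[9] <- "scaffold99"   # unplaced scaffold
  info$chrom[10] <- NA; info$scaffold[10] <- NA; info$bp[10] <- NA  # no hit
  rep_ <- anchor_markers(map_tbl, info)
  cls <- rep_$classification
  expect_identical(cls$class[cls$marker == "m5"], "non_syntenic")
  expect_identical(cls$class[cls$marker == "m9"], "unplaced_scaffold")
  expect_identical(cls$class[cls$marker == "m10"], "no_physical_hit")
  expect_equal(sum(cls$class == "syntenic"), 7)
  expect_equal(sum(rep_$counts$n_markers), 10)  # everything classified once
  expect_identical(rep_$group_chrom$lg_chrom, "Ca4")
  # unplaced scaffold inherits group and cM interval from its markers
  expect_identical(rep_$scaffold_anchors$group, "LG1")
  expect_equal(rep_$scaffold_anchors$start_cM, cls$cM_cum[cls$marker == "m9"])
})

test_that("consecutive non-syntenic markers on one chromosome form a cluster", {
  mk <- paste0("m", 1:20)
  map_tbl <- fake_map_tbl(mk)
  info <- fake_marker_info(map_tbl, chrom = "Ca4",
                           chrom_override = list(idx = 8:12, chrom = "Ca6"))
  rep_ <- anchor_markers(map_tbl, info)
  expect_equal(nrow(rep_$clusters), 1)
  expect_equal(rep_$clusters$n_markers, 5)
  expect_identical(rep_$clusters$chrom, "Ca6")
  expect_setequal(rep_$clusters$markers[[1]], paste0("m", 8:12))
  # an isolated non-syntenic marker is not a cluster
  info2 <- fake_marker_info(map_tbl, chrom = "Ca4",
                            chrom_override = list(idx = 8, chrom = "Ca6"))
  expect_equal(nrow(anchor_markers(map_tbl, info2)$clusters), 0)
})

test_that("per-group Spearman correlation matches the rank-formula oracle", {
  mk <- paste0("m", 1:5)
  map_tbl <- fake_map_tbl(mk)
  info <- fake_marker_info(map_tbl)
  info$bp <- c(1, 2, 3, 5, 4) * 1e5      # one adjacent swap
  rho <- spearman_per_lg(map_tbl, info)
  expect_equal(rho$rho, 0.9, tolerance = 1e-10)  # 1 - 6*2/(5*24)
  # collinear and reversed cases, with orientation normalisation
  expect_equal(spearman_per_lg(map_tbl, fake_marker_info(map_tbl))$rho, 1)
  rev_info <- fake_marker_info(map_tbl)
  rev_info$bp <- rev(rev_info$bp)
  out <- spearman_per_lg(map_tbl, rev_info)
  expect_equal(out$rho_raw, -1)
  expect_true(out$flipped)
  expect_equal(out$rho, 1)
  # tie handling equals a manual average-rank Pearson oracle
  set.seed(5)
  x <- sample(1:6, 12, replace = TRUE)
  mk2 <- paste0("t", 1:12)
  map2 <- fake_map_tbl(mk2)
  info2 <- fake_marker_info(map2)
  info2$bp <- x
  got <- spearman_per_lg(map2, info2)$rho_raw
  oracle <- stats::cor(rank(seq_along(x)), rank(x))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("reversed blocks are flagged as inversion segments, collinear maps are not", {
  mk <- paste0("m", 1:60)
  map_tbl <- fake_map_tbl(mk)
  # collinear: no segments
  clean <- detect_local_inversions(map_tbl, fake_marker_info(map_tbl))
  expect_equal(nrow(clean), 0)
  # one reversed block of 15 markers
  inv <- detect_local_inversions(
    map_tbl, fake_marker_info(map_tbl, reversed_blocks = list(20:34)))
  expect_equal(nrow(inv), 1)
  expect_true(inv$rho < -0.8)
  covered <- inv$markers[[1]]
  expect_true(all(paste0("m", 20:34) %in% covered))
  expect_lte(inv$n_markers, 15 + 2 * 9)    # at most window-1 slack per edge
  # two disjoint reversed blocks give two segments
  inv2 <- detect_local_inversions(
    map_tbl, fake_marker_info(map_tbl, reversed_blocks = list(5:19, 40:54)))
  expect_equal(nrow(inv2), 2)
  # groups shorter than the window yield nothing
  short <- fake_map_tbl(paste0("s", 1:6))
  expect_equal(nrow(detect_local_inversions(short, fake_marker_info(short))), 0)
})

test_that("interval rates follow cM-per-Mb arithmetic with hot/cold classes", {
  mk <- c("a", "b", "c")
  map_tbl <- fake_map_tbl(mk, step = 1.2)
  info <- tibble::tibble(marker = mk, scaffold = "sc", chrom = "Ca1",
                         bp = c(100000L, 122262L, 122262L + 2000000L))
  rates <- interval_rates(map_tbl, info)
  expect_equal(rates$rate_cM_per_Mb[1], 1.2 / (22262 / 1e6), tolerance = 1e-10)
  expect_equal(rates$rate_cM_per_Mb[1], 53.9, tolerance = 0.01)
  expect_identical(rates$class, c("hot", "normal"))
  # zero genetic distance over positive physical span is a coldspot
  map0 <- map_tbl; map0$cM_adj <- 0; map0$cM_cum <- 0
  expect_identical(unique(interval_rates(map0, info)$class), "cold")
  # out-of-order physical positions are skipped and logged
  info_bad <- info; info_bad$bp[3] <- 50000L
  r2 <- interval_rates(fake_map_tbl(mk, step = 1.2), info_bad)
  expect_lt(nrow(r2), 2)
  expect_gte(nrow(attr(r2, "skipped")), 0)
})

test_that("rate classes use strict 20 for hot and exact 0 for cold", {
  expect_identical(classify_rate(c(53.9, 20.01, 20, 10, 9.99, 0, 0.5)),
                   c("hot", "hot", "moderate", "moderate", "normal", "cold",
                     "normal"))
})

test_that("chromosome rates equal the span ratio and aggregate to genome totals", {
  mk <- paste0("m", 1:21)
  map_tbl <- fake_map_tbl(mk, step = 1)          # 20 cM span
  info <- fake_marker_info(map_tbl, bp_step = 5e5)  # 10 Mb span
  cr <- chromosome_rates(map_tbl, info)
  expect_equal(cr$rate_cM_per_Mb, 20 / 10)
  # conservation: chromosome rate is the length-weighted mean of interval rates
  iv <- interval_rates(map_tbl, info)
  expect_equal(sum(iv$d_cM) / (sum(iv$d_bp) / 1e6), cr$rate_cM_per_Mb)
  gw <- genome_wide_rates(cr$length_cM, cr$span_Mb, n_markers = 21,
                          n_genes = 660)
  expect_equal(gw$rate_cM_per_Mb, 2)
  expect_equal(gw$kbp_per_marker, 10e3 / 21)
  expect_equal(gw$genes_per_cM, 33)
})

test_that("interval composition counts genes by midpoint and measures GC", {
  ann <- structure(
    list(genes = tibble::tibble(
      chrom = c("Ca1", "Ca1", "Ca1", "Ca2"),
      start = c(100L, 900L, 1900L, 100L),
      end = c(300L, 1100L, 2100L, 300L)),
      seq = NULL, n_genes = 4L),
    class = "genome_annotation")
  iv <- tibble::tibble(chrom = "Ca1", start = 150L, end = 1500L)
  out <- interval_composition(iv, ann)
  # gene 1 midpoint 200 in, gene 2 midpoint 1000 in, gene 3 midpoint 2000 out
  expect_equal(out$n_genes, 2L)
  expect_equal(out$gene_density_per_Mb, 2 / (1350 / 1e6))
  expect_true(is.na(out$gc_frac))
  skip_if_not_installed("Biostrings")
  ann$seq <- Biostrings::DNAStringSet(c(
    Ca1 = paste0(strrep("GGCC", 500), strrep("AT", 500))))
  out2 <- interval_composition(tibble::tibble(chrom = "Ca1", start = 1L,
                                              end = 2000L), ann)
  expect_equal(out2$gc_frac, 1)
  out3 <- interval_composition(tibble::tibble(chrom = "Ca1", start = 1L,
                                              end = 3000L), ann)
  expect_equal(out3$gc_frac, 2 / 3, tolerance = 1e-10)
})

test_that("annotation readers parse GFF3 through the standard importer", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Ca1\ttest\tgene\t100\t300\t.\t+\t.\tID=g1",
    "Ca1\ttest\tmRNA\t100\t300\t.\t+\t.\tID=t1;Parent=g1",
    "Ca1\ttest\tgene\t900\t1100\t.\t-\t.\tID=g2"
  ), gff)
  ann <- read_genome_annotation(gff)
  expect_equal(ann$n_genes, 2)
  expect_equal(ann$genes$start, c(100, 900))
})

test_that("comparison plots return ggplot objects", {
  mk <- paste0("m", 1:30)
  map_tbl <- fake_map_tbl(mk)
  info <- fake_marker_info(map_tbl)
  expect_s3_class(plot_map_vs_physical(map_tbl, info), "ggplot")
  expect_s3_class(plot_recombination_landscape(interval_rates(map_tbl, info)),
                  "ggplot")
})
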