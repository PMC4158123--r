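# small simulated populations and hand-built map tables used across tests

quick_sim <- function(n_markers = 20, length_cM = 60, n_chrom = 1,
                      n_lines = 60, generations = 7, missing_rate = 0,
                      error_rate = 0, distortion_loci = NULL, seed = 1) {
  chroms <- lapply(seq_len(n_chrom), function(i) {
    sim_chromosome(paste0("Ca", i), n_markers, length_cM)
  })
  names(chroms) <- paste0("Ca", seq_len(n_chrom))
  simulate_ril_population(sim_config(
    chroms, n_lines = n_lines, generations = generations,
    missing_rate = missing_rate, error_rate = error_rate,
    distortion_loci = distortion_loci, seed = seed
  ))
}

geno_tbl_from <- function(...) {
  cols <- list(...)
  tibble::tibble(line = paste0("L", seq_along(cols[[1]])), !!!cols)
}

# a map tibble (as in ril_map$map) with markers evenly spaced `step` cM
fake_map_tbl <- function(markers, group = "LG1", step = 1) {
  tibble::tibble(
    group = group,
    rank = seq_along(markers),
    marker = markers,
    r_adj = c(NA, rep(inverse_kosambi(step), length(markers) - 1)),
    cM_adj = c(0, rep(step, length(markers) - 1)),
    cM_cum = (seq_along(markers) - 1) * step
  )
}

# marker_info for a map tibble: collinear physical positions, with optional
# block reversals (list of index vectors) and chromosome overrides
fake_marker_info <- function(map_tbl, chrom = "Ca1", bp_step = 5e5,
                             reversed_blocks = list(),
                             chrom_override = NULL) {
  n <- nrow(map_tbl)
  bp <- seq_len(n) * bp_step
  for (blk in reversed_blocks) bp[blk] <- rev(bp[blk])
  chroms <- rep(chrom, n)
  if (!is.null(chrom_override)) {
    chroms[chrom_override$idx] <- chrom_override$chrom
  }
  tibble::tibble(marker = map_tbl$marker, source = "test",
                 scaffold = paste0(chroms, "_sc1"), chrom = chroms, bp = bp)
}

# brute-force minimum COUNT over all marker permutations (oracle)
brute_force_min_count <- function(geno) {
  m <- as_geno_matrix(geno)
  perms <- rilmap:::permutations_of(ncol(m))
  min(vapply(perms, function(p) count_recombinations(m, colnames(m)[p]),
             integer(1)))
}
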