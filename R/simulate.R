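#' Chromosome specification for the RIL simulator
#'
#' Builds the marker grid of one simulated chromosome: marker ids, true map
#' positions (cM), physical positions (bp) and scaffold assignments. Markers
#' are evenly spaced in cM and physical positions are collinear with the
#' genetic positions; scaffolds are consecutive blocks of markers, which is
#' what scaffold-bounded imputation assumes.
#'
#' @param name Chromosome name (e.g. `"Ca1"`).
#' @param n_markers Number of markers (>= 1).
#' @param length_cM Genetic length in centimorgans.
#' @param length_bp Physical length in base pairs.
#' @param n_scaffolds Number of scaffolds the markers are split across.
#' @return A tibble with columns `marker`, `cM`, `bp`, `scaffold`.
#' @examples
#' sim_chromosome("Ca1", n_markers = 10, length_cM = 80)
#' @export
sim_chromosome <- function(name, n_markers, length_cM, length_bp = length_cM * 5e5,
                           n_scaffolds = max(1L, n_markers %/% 5L)) {
  stopifnot(n_markers >= 1, length_cM > 0, length_bp >= n_markers)
  cM <- if (n_markers == 1) 0 else seq(0, length_cM, length.out = n_markers)
  bp <- round(seq(1, length_bp, length.out = n_markers))
  bp <- bp + seq_len(n_markers) - 1L  # guarantee strictly increasing
  tibble::tibble(
    marker   = sprintf("%s_m%03d", name, seq_len(n_markers)),
    cM       = cM,
    bp       = as.integer(bp),
    scaffold = sprintf("%s_sc%02d", name,
                       rep(seq_len(n_scaffolds),
                           diff(round(seq(0, n_markers,
                                          length.out = n_scaffolds + 1)))))
  )
}

#' Simulation configuration for an F_g-derived RIL population
#'
#' Collects everything the meiosis-level simulator needs: the chromosome/
#' marker grid, the population size, the filial generation reached by
#' single-seed descent, observation-noise rates, and optional transmission
#' distortion loci.
#'
#' @param chromosomes Named list of chromosome marker tibbles as returned by
#'   [sim_chromosome()]; names are chromosome ids.
#' @param n_lines Number of RILs.
#' @param generations Filial generation g (>= 2); an F7 population has
#'   undergone 6 rounds of selfing, with expected residual heterozygosity
#'   (1/2)^(g-1).
#' @param missing_rate,error_rate Observation-noise rates in \[0, 1):
#'   fraction of calls set missing, and fraction of the surviving homozygous
#'   calls flipped A<->B.
#' @param distortion_loci Optional tibble with columns `marker`,
#'   `w` (gametic viability weight in (0, 1\]) and `disfavored` (`"A"` or
#'   `"B"`): each generation, gametes carrying the disfavored allele at the
#'   locus are accepted with probability `w`.
#' @param seed Integer seed; the simulation is bit-reproducible under it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(list(Ca1 = sim_chromosome("Ca1", 20, 80)),
#'                   n_lines = 50, seed = 7)
#' @export
sim_config <- function(chromosomes, n_lines = 92, generations = 7,
                       missing_rate = 0, error_rate = 0,
                       distortion_loci = NULL, seed = 1) {
  stopifnot(is.list(chromosomes), length(chromosomes) >= 1)
  if (is.null(names(chromosomes)) || any(names(chromosomes) == "")) {
    stop("`chromosomes` must be a named list", call. = FALSE)
  }
  for (nm in names(chromosomes)) {
    ch <- chromosomes[[nm]]
    stopifnot(all(c("marker", "cM", "bp", "scaffold") %in% names(ch)))
    if (nrow(ch) > 1 && (any(diff(ch$cM) < 0) || any(diff(ch$bp) <= 0))) {
      # equal cM positions are allowed (fully linked markers); bp must be
      # strictly increasing
      stop("cM must be non-decreasing and bp strictly increasing within ", nm,
           call. = FALSE)
    }
  }
  if (generations < 2 || generations != round(generations)) {
    stop("`generations` must be an integer >= 2", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1 || error_rate < 0 || error_rate >= 1) {
    stop("noise rates must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(distortion_loci)) {
    distortion_loci <- tibble::as_tibble(distortion_loci)
    stopifnot(all(c("marker", "w") %in% names(distortion_loci)))
    if (!"disfavored" %in% names(distortion_loci)) distortion_loci$disfavored <- "B"
    if (any(distortion_loci$w <= 0 | distortion_loci$w > 1)) {
      stop("viability weights must be in (0, 1]", call. = FALSE)
    }
    all_markers <- unlist(lapply(chromosomes, `[[`, "marker"), use.names = FALSE)
    if (!all(distortion_loci$marker %in% all_markers)) {
      stop("distortion loci must name simulated markers", call. = FALSE)
    }
  }
  structure(
    list(chromosomes = chromosomes, n_lines = as.integer(n_lines),
         generations = as.integer(generations), missing_rate = missing_rate,
         error_rate = error_rate, distortion_loci = distortion_loci,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' CPR-01-like default configuration
#'
#' Eight chromosomes with the genetic lengths, physical spans and per-group
#' marker counts of the CPR-01 chickpea intraspecific RIL map
#' (ICCV 96029 x CDC Frontier): 92 lines, F7 by single-seed descent.
#'
#' @param marker_scale Multiplier on the per-group marker counts (use < 1 for
#'   a lighter population with the same genome geometry).
#' @inheritParams sim_config
#' @return A `sim_config`.
#' @export
sim_config_cpr01 <- function(n_lines = 92, generations = 7, missing_rate = 0,
                             error_rate = 0, distortion_loci = NULL, seed = 1,
                             marker_scale = 1) {
  ref <- cpr01_reference("chromosomes")
  chroms <- purrr::pmap(
    list(ref$group, ref$n_markers, ref$length_cM, ref$span_Mb),
    function(grp, n, len, mb) {
      sim_chromosome(sub("LG", "Ca", grp),
                     n_markers = max(2L, as.integer(round(n * marker_scale))),
                     length_cM = len, length_bp = mb * 1e6)
    }
  )
  names(chroms) <- sub("LG", "Ca", ref$group)
  sim_config(chroms, n_lines = n_lines, generations = generations,
             missing_rate = missing_rate, error_rate = error_rate,
             distortion_loci = distortion_loci, seed = seed)
}

# one round of meiosis for every line: recombine (h1, h2) into a gamete,
# Bernoulli(r) crossover per adjacent interval, intervals independent
make_gametes <- function(h1, h2, chrom_cols, r_list) {
  n <- nrow(h1)
  gam <- h1
  for (ci in seq_along(chrom_cols)) {
    cols <- chrom_cols[[ci]]
    k <- length(cols)
    start <- stats::rbinom(n, 1L, 0.5)
    if (k > 1) {
      r <- r_list[[ci]]
      sw <- matrix(stats::rbinom(n * (k - 1), 1L, rep(r, each = n)), nrow = n)
      cum <- if (ncol(sw) > 1) t(apply(sw, 1, cumsum)) else sw
      phase <- (start + cbind(0L, cum)) %% 2L
    } else {
      phase <- matrix(start, ncol = 1)
    }
    block <- h1[, cols, drop = FALSE]
    b2 <- h2[, cols, drop = FALSE]
    block[phase == 1L] <- b2[phase == 1L]
    gam[, cols] <- block
  }
  gam
}

# gametic-viability rejection sampling: accepted rows are final, gametes of
# rejected rows are redrawn (recursively) until every row is accepted
weighted_gametes <- function(h1, h2, chrom_cols, r_list, dist_cols, dist_w,
                             dist_allele) {
  gam <- make_gametes(h1, h2, chrom_cols, r_list)
  if (length(dist_cols) == 0) return(gam)
  w <- rep(1, nrow(gam))
  for (j in seq_along(dist_cols)) {
    carries <- gam[, dist_cols[j]] == dist_allele[j]
    w[carries] <- w[carries] * dist_w[j]
  }
  reject <- stats::runif(nrow(gam)) > w
  if (any(reject)) {
    gam[reject, ] <- Recall(h1[reject, , drop = FALSE],
                            h2[reject, , drop = FALSE],
                            chrom_cols, r_list, dist_cols, dist_w, dist_allele)
  }
  gam
}

#' Simulate an F_g-derived RIL genotype matrix with known truth
#'
#' Starting from a fully heterozygous F1, each line is selfed
#' `generations - 1` times by single-seed descent. Every gamete is formed by
#' recombining the plant's two haplotypes with an independent
#' Bernoulli(r) crossover in each adjacent marker interval, where
#' r = [inverse_kosambi()] of the interval's true cM span (Markovian meiosis,
#' no interference beyond the map function). Distortion loci weight the
#' acceptance of gametes carrying the disfavored allele by `w` each
#' generation. Observation noise (missing calls, then A<->B flips of
#' surviving homozygous calls) is applied to a copy; the pre-noise matrix is
#' kept as truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `ril_sim`:
#'   * `geno` — observed genotype tibble (calls A/B/H/U),
#'   * `truth` — list with `map` (marker, chrom, cM, bp, scaffold),
#'     `geno` (pre-noise calls, never missing), `distortion_loci`,
#'   * `marker_info` — tibble ready for [impute_flanking()] /
#'     [anchor_markers()] (marker, source, scaffold, chrom, bp),
#'   * `config`.
#' @examples
#' sim <- simulate_ril_population(
#'   sim_config(list(Ca1 = sim_chromosome("Ca1", 12, 60)), n_lines = 30, seed = 2))
#' dim(sim$geno)
#' @export
simulate_ril_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  map <- dplyr::bind_rows(
    purrr::imap(config$chromosomes,
                ~ dplyr::mutate(.x, chrom = .y, .before = 1))
  )
  M <- nrow(map)
  N <- config$n_lines
  chrom_cols <- split(seq_len(M), factor(map$chrom, levels = unique(map$chrom)))
  r_list <- lapply(chrom_cols, function(cols) {
    if (length(cols) > 1) inverse_kosambi(diff(map$cM[cols])) else numeric(0)
  })

  dist <- config$distortion_loci
  if (is.null(dist)) {
    dist_cols <- integer(0); dist_w <- numeric(0); dist_allele <- integer(0)
  } else {
    dist_cols <- match(dist$marker, map$marker)
    dist_w <- dist$w
    dist_allele <- ifelse(dist$disfavored == "B", 1L, 0L)
  }

  h1 <- matrix(0L, N, M)
  h2 <- matrix(1L, N, M)
  for (gen in seq_len(config$generations - 1)) {
    g1 <- weighted_gametes(h1, h2, chrom_cols, r_list, dist_cols, dist_w, dist_allele)
    g2 <- weighted_gametes(h1, h2, chrom_cols, r_list, dist_cols, dist_w, dist_allele)
    h1 <- g1
    h2 <- g2
  }

  calls <- matrix("H", N, M, dimnames = list(sprintf("RIL%03d", seq_len(N)),
                                             map$marker))
  s <- h1 + h2
  calls[s == 0L] <- "A"
  calls[s == 2L] <- "B"

  observed <- apply_observation_noise(as_geno_tbl(calls),
                                      missing_rate = config$missing_rate,
                                      error_rate = config$error_rate)

  marker_info <- tibble::tibble(
    marker = map$marker, source = "sim", scaffold = map$scaffold,
    chrom = map$chrom, bp = map$bp
  )
  structure(
    list(geno = observed,
         truth = list(map = dplyr::select(map, "marker", "chrom", "cM", "bp",
                                          "scaffold"),
                      geno = as_geno_tbl(calls),
                      distortion_loci = dist),
         marker_info = marker_info,
         config = config),
    class = "ril_sim"
  )
}

#' @export
print.ril_sim <- function(x, ...) {
  cat("Simulated RIL population: ", nrow(x$geno), " lines x ",
      nrow(x$truth$map), " markers on ", length(x$config$chromosomes),
      " chromosome(s), F", x$config$generations, "\n", sep = "")
  invisible(x)
}

#' Apply observation noise to a genotype table
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving homozygous call is then flipped A<->B with probability
#' `error_rate` (heterozygous calls are never flipped). The input is not
#' modified.
#'
#' @param geno Genotype tibble or matrix.
#' @param missing_rate,error_rate Rates in \[0, 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_ril_population()]).
#' @return A genotype tibble of the same dimensions.
#' @examples
#' g <- tibble::tibble(line = c("L1", "L2"), m1 = c("A", "A"))
#' apply_observation_noise(g, missing_rate = 0, error_rate = 1, seed = 1)
#' @export
apply_observation_noise <- function(geno, missing_rate = 0, error_rate = 0,
                                    seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1 || error_rate < 0 || error_rate >= 1) {
    stop("noise rates must be in [0, 1)", call. = FALSE)
  }
  m <- as_geno_matrix(geno)
  if (!is.null(seed)) withr::local_seed(seed)
  if (missing_rate > 0) {
    m[stats::runif(length(m)) < missing_rate] <- "U"
  }
  if (error_rate > 0) {
    hom <- which(m == "A" | m == "B")
    flip <- hom[stats::runif(length(hom)) < error_rate]
    m[flip] <- ifelse(m[flip] == "A", "B", "A")
  }
  as_geno_tbl(m)
}
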