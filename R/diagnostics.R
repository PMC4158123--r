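#' Per-group summary of a linkage map
#'
#' Marker count, map length, mean adjacent-marker distance and largest gap
#' for each linkage group. The mean distance follows the usual map-summary
#' convention total length / total markers (not markers - 1).
#'
#' @param map A `ril_map` from [build_map()].
#' @return A tibble with one row per group (`group`, `n_markers`,
#'   `length_cM`, `mean_spacing_cM`, `largest_gap_cM`).
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "ril_map"))
  dplyr::summarise(
    dplyr::group_by(map$map, .data$group),
    n_markers = dplyr::n(),
    length_cM = max(.data$cM_cum),
    mean_spacing_cM = max(.data$cM_cum) / dplyr::n(),
    largest_gap_cM = max(.data$cM_adj),
    .groups = "drop"
  )
}

#' Chakravarti method-4 genome length and map coverage
#'
#' Each linkage group's observed length is inflated by the factor
#' (m + 1)/(m - 1), m = number of markers in the group; genome coverage is
#' the ratio of total observed to total estimated length (Sekino-Hara).
#' `mode = "per_group"` (default) sums per-group estimates;
#' `mode = "global"` applies the factor once to the totals, with m = total
#' marker count.
#'
#' @param x A `ril_map`, or a data frame with columns `length_cM` and
#'   `n_markers` (e.g. a published per-group map summary).
#' @param mode `"per_group"` or `"global"`.
#' @return A list of class `coverage_estimate`: `groups` (per-group tibble
#'   with `estimated_cM`; groups with m < 2 are excluded with a warning),
#'   `observed_cM`, `estimated_cM`, `coverage`.
#' @examples
#' chakravarti_estimate(cpr01_reference("map_summary"))
#' @export
chakravarti_estimate <- function(x, mode = c("per_group", "global")) {
  mode <- match.arg(mode)
  tbl <- if (inherits(x, "ril_map")) map_summary(x) else tibble::as_tibble(x)
  stopifnot(all(c("length_cM", "n_markers") %in% names(tbl)))
  bad <- tbl$n_markers < 2
  if (any(bad)) {
    warning(sum(bad), " group(s) with < 2 markers excluded", call. = FALSE)
    tbl <- tbl[!bad, , drop = FALSE]
  }
  tbl <- dplyr::mutate(
    tbl, estimated_cM = .data$length_cM * (.data$n_markers + 1) / (.data$n_markers - 1))
  observed <- sum(tbl$length_cM)
  estimated <- if (mode == "per_group") {
    sum(tbl$estimated_cM)
  } else {
    M <- sum(tbl$n_markers)
    observed * (M + 1) / (M - 1)
  }
  structure(list(groups = tbl, observed_cM = observed,
                 estimated_cM = estimated,
                 coverage = observed / estimated, mode = mode),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat("Estimated genome length (Chakravarti method 4, ", x$mode, "): ",
      round(x$estimated_cM, 1), " cM; observed ", round(x$observed_cM, 1),
      " cM; coverage ", sprintf("%.1f%%", 100 * x$coverage), "\n", sep = "")
  invisible(x)
}

#' Residual heterozygosity of a RIL population
#'
#' Population-level heterozygosity (H calls / non-missing calls), the
#' per-line distribution, and the fold relative to the (1/2)^(g-1)
#' expectation for an F_g population.
#'
#' @param geno Genotype tibble or matrix.
#' @param g Filial generation (>= 2).
#' @return A list: `per_line` ([line_qc_stats()] tibble), `population_het`,
#'   `expected_het`, `fold`.
#' @export
residual_heterozygosity <- function(geno, g = 7) {
  m <- as_geno_matrix(geno)
  expected <- expected_ril_heterozygosity(g)
  nonmiss <- sum(m != "U")
  pop <- if (nonmiss > 0) sum(m == "H") / nonmiss else NA_real_
  list(per_line = line_qc_stats(m), population_het = pop,
       expected_het = expected, fold = pop / expected)
}

distortion_record <- function(marker, nA, nB, nH, nU, alpha, af_bounds) {
  n <- nA + nB
  freq <- ifelse(n > 0, nA / n, NA_real_)
  E <- n / 2
  chisq <- ifelse(n > 0, (nA - E)^2 / E + (nB - E)^2 / E, NA_real_)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  in_band <- if (is.null(af_bounds)) {
    rep(TRUE, length(freq))
  } else {
    !is.na(freq) & (freq <= af_bounds[1] | freq >= af_bounds[2])
  }
  distorted <- !is.na(p) & p < alpha & in_band
  direction <- dplyr::case_when(
    !distorted ~ "none",
    freq > 0.5 ~ "A",
    freq < 0.5 ~ "B",
    TRUE ~ "none"
  )
  tibble::tibble(marker = marker, nA = nA, nB = nB, nH = nH, nU = nU,
                 allele_freq = freq, chisq = chisq, p = p,
                 distorted = distorted, direction = direction)
}

#' Segregation distortion test
#'
#' Chi-square goodness-of-fit of the homozygote counts against the 1:1 RIL
#' expectation (heterozygous and missing calls excluded, df = 1). A marker
#' is called distorted iff p < `alpha` AND its allele frequency lies outside
#' the open interval (`af_bounds[1]`, `af_bounds[2]`) — i.e. <= 0.4 or
#' >= 0.6 at the defaults; set `af_bounds = NULL` to disable the band. The
#' direction is the parent of the over-represented allele.
#'
#' `distortion_test()` tests one marker column; `distortion_scan()` tests
#' every marker of a genotype table, optionally with multiple-testing
#' adjustment of the p-values (off by default).
#'
#' @param calls Character vector of calls for one marker.
#' @param geno Genotype tibble or matrix.
#' @param alpha Significance level (default 0.05).
#' @param af_bounds Length-2 numeric distortion band, or `NULL`.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @param marker Marker id used in the output row.
#' @return A tibble with one row per marker: counts, allele frequency,
#'   `chisq`, `p`, `distorted`, `direction` (`"A"`, `"B"` or `"none"`).
#' @examples
#' distortion_test(c(rep("A", 70), rep("B", 22)))
#' @export
distortion_test <- function(calls, alpha = 0.05, af_bounds = c(0.4, 0.6),
                            marker = "marker") {
  distortion_record(marker, sum(calls == "A"), sum(calls == "B"),
                    sum(calls == "H"), sum(calls == "U"), alpha, af_bounds)
}

#' @rdname distortion_test
#' @export
distortion_scan <- function(geno, alpha = 0.05, af_bounds = c(0.4, 0.6),
                            adjust = "none") {
  m <- as_geno_matrix(geno)
  rec <- distortion_record(colnames(m), colSums(m == "A"), colSums(m == "B"),
                           colSums(m == "H"), colSums(m == "U"),
                           alpha, af_bounds)
  if (adjust != "none") {
    p_adj <- stats::p.adjust(rec$p, method = adjust)
    in_band <- if (is.null(af_bounds)) TRUE else
      !is.na(rec$allele_freq) &
      (rec$allele_freq <= af_bounds[1] | rec$allele_freq >= af_bounds[2])
    rec$p <- p_adj
    rec$distorted <- !is.na(p_adj) & p_adj < alpha & in_band
    rec$direction <- ifelse(rec$distorted,
                            ifelse(rec$allele_freq > 0.5, "A", "B"), "none")
  }
  rec
}

#' Detect segregation distortion regions (SDRs)
#'
#' Maximal runs of at least two consecutive mapped markers distorted toward
#' the same parent, allowing up to `max_gap_markers` interleaved
#' non-distorted markers between successive distorted members (default 0).
#'
#' @param map A `ril_map` or its [tidy()] tibble (`group`, `rank`, `marker`,
#'   `cM_cum`).
#' @param distortion A [distortion_scan()] tibble.
#' @param max_gap_markers Tolerated interruptions (default 0).
#' @return A tibble with one row per region: `group`, `start_cM`, `end_cM`,
#'   `size_cM`, `n_markers` (distorted members), `direction`, and the member
#'   marker ids in a list column.
#' @export
detect_sdr <- function(map, distortion, max_gap_markers = 0) {
  tbl <- if (inherits(map, "ril_map")) map$map else tibble::as_tibble(map)
  stopifnot(all(c("group", "rank", "marker", "cM_cum") %in% names(tbl)))
  tbl <- dplyr::left_join(tbl,
                          distortion[c("marker", "distorted", "direction")],
                          by = "marker")
  tbl$distorted[is.na(tbl$distorted)] <- FALSE
  out <- list()
  for (grp in split(tbl, tbl$group)) {
    grp <- grp[order(grp$rank), , drop = FALSE]
    hits <- which(grp$distorted)
    if (length(hits) < 2) next
    # break into runs: same direction, positional gap <= max_gap_markers
    new_run <- c(TRUE, diff(hits) - 1 > max_gap_markers |
                   grp$direction[hits[-1]] != grp$direction[hits[-length(hits)]])
    run_id <- cumsum(new_run)
    for (ids in split(hits, run_id)) {
      if (length(ids) < 2) next
      out[[length(out) + 1]] <- tibble::tibble(
        group = grp$group[1],
        start_cM = min(grp$cM_cum[ids]),
        end_cM = max(grp$cM_cum[ids]),
        size_cM = max(grp$cM_cum[ids]) - min(grp$cM_cum[ids]),
        n_markers = length(ids),
        direction = grp$direction[ids[1]],
        markers = list(grp$marker[ids])
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(group = character(), start_cM = numeric(),
                   end_cM = numeric(), size_cM = numeric(),
                   n_markers = integer(), direction = character(),
                   markers = list())
}
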