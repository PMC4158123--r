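#' Allele frequency of a marker column
#'
#' Frequency of the parent-1 (`A`) allele among non-missing homozygous
#' calls: nA / (nA + nB). Heterozygous and missing calls are excluded — in a
#' RIL the heterozygote class is transient and the 0.2-0.8 retention band
#' targets parental allele balance among fixed lines. Returns `NA` when the
#' column has no homozygous calls.
#'
#' @param calls Character vector of calls (`A/B/H/U`).
#' @return Frequency in \[0, 1\], or `NA` if undefined.
#' @examples
#' allele_frequency(c("A", "A", "A", "B", "H", "U"))  # 0.75
#' @export
allele_frequency <- function(calls) {
  nA <- sum(calls == "A")
  nB <- sum(calls == "B")
  if (nA + nB == 0) return(NA_real_)
  nA / (nA + nB)
}

#' Per-marker and per-line QC statistics
#'
#' @param geno Genotype tibble or matrix.
#' @return A tibble with one row per marker (`marker_qc_stats()`) or line
#'   (`line_qc_stats()`): missing fraction, heterozygous fraction (among
#'   non-missing calls) and, for markers, the `A` allele frequency.
#' @examples
#' sim <- simulate_ril_population(
#'   sim_config(list(Ca1 = sim_chromosome("Ca1", 8, 40)), n_lines = 20, seed = 1))
#' marker_qc_stats(sim$geno)
#' @export
marker_qc_stats <- function(geno) {
  m <- as_geno_matrix(geno)
  n <- nrow(m)
  miss <- colSums(m == "U")
  het <- colSums(m == "H")
  nA <- colSums(m == "A")
  nB <- colSums(m == "B")
  tibble::tibble(
    marker = colnames(m),
    n_lines = n,
    missing_frac = unname(miss / n),
    het_frac = unname(ifelse(n - miss > 0, het / (n - miss), NA_real_)),
    allele_freq = unname(ifelse(nA + nB > 0, nA / (nA + nB), NA_real_))
  )
}

#' @rdname marker_qc_stats
#' @export
line_qc_stats <- function(geno) {
  m <- as_geno_matrix(geno)
  k <- ncol(m)
  miss <- rowSums(m == "U")
  het <- rowSums(m == "H")
  tibble::tibble(
    line = rownames(m),
    n_markers = k,
    missing_frac = unname(miss / k),
    het_frac = unname(ifelse(k - miss > 0, het / (k - miss), NA_real_))
  )
}

#' Filter markers on missingness, heterozygosity and allele frequency
#'
#' Removes markers whose missing fraction exceeds `max_missing_frac`
#' (strictly; "up to" the threshold is retained), whose heterozygous
#' fraction exceeds `max_het_frac` (strictly), or whose `A` allele frequency
#' falls outside \[`af_low`, `af_high`\] (markers with undefined allele
#' frequency — no homozygous calls — are removed under the same reason).
#' Two named profiles bundle the standard thresholds: `"rad"` =
#' (0.66, 0.10, 0.2, 0.8) as used at the SNP-calling stage, and `"map"` =
#' (0.30, 0.10, 0.2, 0.8) as used before linkage analysis.
#'
#' @param geno Genotype tibble or matrix.
#' @param profile `"rad"`, `"map"`, or `NULL` to use the explicit thresholds.
#' @param max_missing_frac,max_het_frac,af_low,af_high Explicit thresholds.
#' @return A list with `geno` (retained markers) and `report`, the
#'   [marker_qc_stats()] tibble plus `retained` and `reason` columns.
#' @examples
#' g <- tibble::tibble(line = c("L1", "L2", "L3", "L4"),
#'                     ok = c("A", "A", "B", "B"),
#'                     gap = c("U", "U", "U", "B"))
#' filter_markers(g, profile = "rad")$report
#' @export
filter_markers <- function(geno, profile = c("rad", "map"),
                           max_missing_frac = NULL, max_het_frac = 0.10,
                           af_low = 0.2, af_high = 0.8) {
  if (is.null(max_missing_frac)) {
    profile <- match.arg(profile)
    max_missing_frac <- switch(profile, rad = 0.66, map = 0.30)
  }
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            max_het_frac >= 0, max_het_frac <= 1, af_low < af_high)
  m <- as_geno_matrix(geno)
  stats <- marker_qc_stats(m)
  reasons <- purrr::pmap_chr(
    stats[c("missing_frac", "het_frac", "allele_freq")],
    function(missing_frac, het_frac, allele_freq) {
      r <- character(0)
      if (missing_frac > max_missing_frac) r <- c(r, "missing")
      if (!is.na(het_frac) && het_frac > max_het_frac) r <- c(r, "het")
      if (is.na(allele_freq) || allele_freq < af_low || allele_freq > af_high) {
        r <- c(r, "allele_frequency")
      }
      paste(r, collapse = ";")
    }
  )
  report <- dplyr::mutate(stats, retained = reasons == "",
                          reason = dplyr::na_if(reasons, ""))
  kept <- m[, report$retained, drop = FALSE]
  if (ncol(kept) == 0) warning("no markers retained", call. = FALSE)
  list(geno = as_geno_tbl(kept), report = report)
}

#' Filter lines on residual heterozygosity (and optionally missingness)
#'
#' Removes lines whose heterozygous fraction among non-missing calls is
#' strictly greater than `max_het_frac` ("more than 10% residual
#' heterozygosity" read as a strict inequality), and, when
#' `max_missing_frac` is given, lines missing strictly more than that
#' fraction of calls (the per-RIL missing-score criterion of the
#' pre-mapping filter).
#'
#' @param geno Genotype tibble or matrix.
#' @param max_het_frac Heterozygosity threshold in \[0, 1\].
#' @param max_missing_frac Optional missingness threshold in \[0, 1\].
#' @return A list with `geno` (retained lines) and `report`, the
#'   [line_qc_stats()] tibble plus `retained` and `reason` columns.
#' @export
filter_lines <- function(geno, max_het_frac = 0.10, max_missing_frac = NULL) {
  stopifnot(max_het_frac >= 0, max_het_frac <= 1)
  m <- as_geno_matrix(geno)
  stats <- line_qc_stats(m)
  reasons <- purrr::map2_chr(stats$het_frac, stats$missing_frac,
    function(het, miss) {
      r <- character(0)
      if (!is.na(het) && het > max_het_frac) r <- c(r, "het")
      if (!is.null(max_missing_frac) && miss > max_missing_frac) {
        r <- c(r, "missing")
      }
      paste(r, collapse = ";")
    })
  report <- dplyr::mutate(stats, retained = reasons == "",
                          reason = dplyr::na_if(reasons, ""))
  kept <- m[report$retained, , drop = FALSE]
  if (nrow(kept) == 0) warning("no lines retained", call. = FALSE)
  list(geno = as_geno_tbl(kept), report = report)
}
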