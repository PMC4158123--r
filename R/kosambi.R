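#' Kosambi map function
#'
#' Convert between recombination fraction and additive map distance under
#' moderate crossover interference. `kosambi_distance()` maps a recombination
#' fraction `r` in \[0, 0.5) to centimorgans, d = 25 ln((1+2r)/(1-2r));
#' `inverse_kosambi()` maps a distance in cM back to a fraction,
#' r = tanh(2 d_Morgan) / 2.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @param d Map distance(s) in centimorgans, >= 0.
#' @return Numeric vector (cM for `kosambi_distance()`, a fraction in
#'   \[0, 0.5) for `inverse_kosambi()`).
#' @examples
#' kosambi_distance(0.1)              # ~10.14 cM
#' inverse_kosambi(kosambi_distance(0.25))
#' @export
kosambi_distance <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must be in [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_distance
#' @export
inverse_kosambi <- function(d) {
  if (any(is.na(d)) || any(d < 0)) {
    stop("map distance must be >= 0", call. = FALSE)
  }
  0.5 * tanh(2 * d / 100)
}

#' Recombination-fraction correction for selfed RILs
#'
#' In a population taken to homozygosity by repeated selfing, recombination
#' events accumulate over generations: the observed fraction of lines with
#' opposite homozygous calls estimates R = 2r/(1+2r) (Haldane-Waddington),
#' not the per-meiosis fraction r. `ril_rf_correction()` inverts that
#' relationship, r = R / (2 - 2R).
#'
#' @param R Observed recombinant fraction(s) in \[0, 1\].
#' @return Per-meiosis recombination fraction(s).
#' @examples
#' ril_rf_correction(2 * 0.1 / (1 + 2 * 0.1))  # recovers 0.1
#' @export
ril_rf_correction <- function(R) {
  if (any(!is.na(R) & (R < 0 | R > 1))) {
    stop("observed fraction must be in [0, 1]", call. = FALSE)
  }
  r <- R / (2 - 2 * R)
  pmin(r, 0.5)
}

#' Expected residual heterozygosity of an F_g RIL
#'
#' After g - 1 rounds of selfing from the F1, the expected fraction of
#' heterozygous loci per line is (1/2)^(g-1).
#'
#' @param g Filial generation number (>= 2; an F7-derived RIL has g = 7).
#' @return Expected heterozygous fraction.
#' @examples
#' expected_ril_heterozygosity(7)  # 0.015625
#' @export
expected_ril_heterozygosity <- function(g) {
  if (any(g < 2) || any(g != round(g))) {
    stop("generation number g must be an integer >= 2", call. = FALSE)
  }
  0.5^(g - 1)
}
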