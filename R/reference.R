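#' Bundled CPR-01 chickpea map reference tables
#'
#' Per-group and genome-level summary statistics of the published CPR-01
#' chickpea intraspecific RIL linkage map (ICCV 96029 x CDC Frontier,
#' 92 lines, 1,336 mapped SNPs over eight linkage groups), shipped as
#' plain-TSV reference data. Available tables:
#'
#' * `"map_summary"` — per linkage group: recombination bins, markers in
#'   bins, singleton markers, total markers, map length (cM);
#' * `"physical_summary"` — per group: markers on unplaced scaffolds,
#'   non-syntenic markers, markers placed on pseudochromosomes;
#' * `"chromosomes"` — per group: map length (cM), physical span between the
#'   most distal markers (Mb), total markers;
#' * `"rate_intervals"` — recombination hotspot and coldspot intervals:
#'   flanking markers, cM interval, bp span, G+C %, gene count;
#' * `"stats"` — genome-level key/value pairs (annotated gene total,
#'   population residual heterozygosity %, distorted marker count, ...).
#'
#' @param name Which table to load.
#' @return A tibble.
#' @examples
#' cpr01_reference("chromosomes")
#' @export
cpr01_reference <- function(name = c("map_summary", "physical_summary",
                                     "chromosomes", "rate_intervals",
                                     "stats")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("cpr01_", name, ".tsv"),
                      package = "rilmap", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
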