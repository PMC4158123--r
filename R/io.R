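#' Read and write genotype tables
#'
#' Genotype files are rectangular delimited text with lines as rows, markers
#' as columns, the first column holding line ids and calls coded `A/B/H/U`
#' (or any recoding declared through `aliases`). A read-only VCF dialect
#' maps sample `GT` fields against the declared parent-1 allele:
#' `0/0 -> A`, `1/1 -> B`, `0/1`/`1/0 -> H`, `./.` or absent `-> U`
#' (swapped when `parent1 = "alt"`).
#'
#' @param path File path.
#' @param dialect `"tsv"`, `"csv"` or `"vcf"`.
#' @param aliases Optional named character vector recoding file symbols to
#'   `A/B/H/U`, e.g. `c("0" = "A", "2" = "B", "1" = "H", "-" = "U")`.
#' @param parent1 For VCF: which allele the maternal parent carries,
#'   `"ref"` (default) or `"alt"`.
#' @param geno Genotype tibble or matrix to write.
#' @return `read_genotypes()`: a genotype tibble. `write_genotypes()`: the
#'   path, invisibly. Round trip (write then read) is the identity for the
#'   tsv/csv dialects.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv", "vcf"),
                           aliases = NULL, parent1 = "ref") {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_genotypes_vcf(path, parent1 = parent1))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  tbl <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE, show_col_types = FALSE)
  if (nrow(tbl) == 0 || ncol(tbl) < 2) {
    stop("empty genotype file: ", path, call. = FALSE)
  }
  names(tbl)[1] <- "line"
  m <- as_geno_matrix(tbl, validate = FALSE)
  if (!is.null(aliases)) {
    hit <- m %in% names(aliases)
    m[hit] <- unname(aliases[m[hit]])
  }
  m[is.na(m)] <- "U"
  as_geno_tbl(as_geno_matrix(m))  # validates, listing offending cells
}

read_genotypes_vcf <- function(path, parent1 = c("ref", "alt")) {
  parent1 <- match.arg(parent1)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required for the vcf dialect", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  x <- gsub("\\|", "/", as.vector(gt))
  out <- rep("U", length(x))
  out[!is.na(x) & x == "0/0"] <- if (parent1 == "ref") "A" else "B"
  out[!is.na(x) & x == "1/1"] <- if (parent1 == "ref") "B" else "A"
  out[!is.na(x) & x %in% c("0/1", "1/0")] <- "H"
  m <- matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
  as_geno_tbl(as_geno_matrix(t(m)))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(geno, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  tbl <- as_geno_tbl(as_geno_matrix(geno))
  if (dialect == "tsv") readr::write_tsv(tbl, path) else
    readr::write_csv(tbl, path)
  invisible(path)
}

#' Read marker physical metadata
#'
#' A TSV with columns `marker` and any of `source`, `scaffold`, `chrom`,
#' `bp` (1-based physical position). Missing physical fields are read as
#' `NA` (marker without a physical hit).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_marker_info <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot("marker" %in% names(tbl))
  tbl
}

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] with defaults equal to
#' the standard workflow settings: marker filter profile `"map"`
#' (missingness 0.30, heterozygosity 0.10, allele-frequency band 0.2-0.8),
#' line filters (heterozygosity 0.10, missingness 0.25), grouping cutoff
#' 0.2, 30 ordering starts, ripple window 5, distortion alpha 0.05 with
#' 0.4/0.6 band, hotspots above 20 cM/Mb and coldspots at exactly 0.
#'
#' @param genotypes Path to the genotype file (or a genotype tibble).
#' @param marker_info Optional path to marker metadata TSV (or tibble).
#' @param out_dir Output directory for stage reports and the manifest.
#' @param seed Integer seed driving every stochastic step.
#' @param profile Marker filter profile (`"map"` or `"rad"`).
#' @param max_line_het,max_line_missing Line filters.
#' @param cutoff,min_informative,n_starts,window,ril_correction Mapping
#'   parameters (see [build_map()]).
#' @param alpha,af_bounds Distortion-test parameters.
#' @param generations Filial generation for heterozygosity expectations.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, marker_info = NULL, out_dir = tempdir(),
                            seed = 1, profile = "map", max_line_het = 0.10,
                            max_line_missing = 0.25, cutoff = 0.2,
                            min_informative = 20, n_starts = 30, window = 5,
                            ril_correction = FALSE, alpha = 0.05,
                            af_bounds = c(0.4, 0.6), generations = 7) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage_tsv <- function(x, out_dir, name) {
  x <- tibble::as_tibble(x)
  x <- x[!vapply(x, is.list, logical(1))]  # drop list columns for TSV
  readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
}

#' Run the full mapping pipeline
#'
#' Executes the stages in order — read, marker/line QC, flanking imputation,
#' binning, map construction, diagnostics (summary, coverage, residual
#' heterozygosity, distortion, SDRs) and, when physical metadata is
#' available, the genome comparison (anchoring, collinearity, inversions,
#' interval rates) — writing every intermediate as TSV into
#' `config$out_dir` together with a machine-readable JSON manifest of
#' parameters and per-stage marker/line counts. A failing stage halts the
#' run with an error naming the stage. Reruns with the same seed produce
#' byte-identical manifests.
#'
#' @param config A [pipeline_config()] (or the path to a YAML file whose
#'   fields are `pipeline_config()` arguments).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  geno <- stage("read", {
    if (is.character(config$genotypes)) read_genotypes(config$genotypes)
    else as_geno_tbl(as_geno_matrix(config$genotypes))
  })
  info <- NULL
  if (!is.null(config$marker_info)) {
    info <- stage("read", {
      if (is.character(config$marker_info)) read_marker_info(config$marker_info)
      else tibble::as_tibble(config$marker_info)
    })
  }
  n_markers_in <- ncol(geno) - 1
  n_lines_in <- nrow(geno)

  qc <- stage("qc", {
    mk <- filter_markers(geno, profile = config$profile)
    ln <- filter_lines(mk$geno, max_het_frac = config$max_line_het,
                       max_missing_frac = config$max_line_missing)
    write_stage_tsv(mk$report, config$out_dir, "qc_markers")
    write_stage_tsv(ln$report, config$out_dir, "qc_lines")
    list(geno = ln$geno, marker_report = mk$report, line_report = ln$report)
  })

  binned <- stage("bin", {
    imp <- if (!is.null(info) && all(c("scaffold", "bp") %in% names(info))) {
      impute_flanking(qc$geno, info)
    } else {
      list(geno = qc$geno, log = tibble::tibble())
    }
    bins <- bin_identical(imp$geno, marker_info = info)
    write_stage_tsv(imp$log, config$out_dir, "imputation_log")
    write_stage_tsv(bins$bins, config$out_dir, "bins")
    list(geno = bins$geno, bins = bins$bins, imputed = nrow(imp$log))
  })

  map <- stage("map", {
    mp <- build_map(binned$geno, marker_info = info, cutoff = config$cutoff,
                    min_informative = config$min_informative,
                    n_starts = config$n_starts, window = config$window,
                    ril_correction = config$ril_correction,
                    seed = config$seed)
    write_stage_tsv(mp$map, config$out_dir, "map")
    mp
  })

  diag <- stage("diagnose", {
    summ <- map_summary(map)
    cov <- chakravarti_estimate(map)
    het <- residual_heterozygosity(map$geno, g = config$generations)
    dist <- distortion_scan(map$geno, alpha = config$alpha,
                            af_bounds = config$af_bounds)
    sdr <- detect_sdr(map, dist)
    write_stage_tsv(summ, config$out_dir, "map_summary")
    write_stage_tsv(cov$groups, config$out_dir, "coverage")
    write_stage_tsv(dist, config$out_dir, "distortion")
    write_stage_tsv(sdr, config$out_dir, "sdr")
    list(summary = summ, coverage = cov, het = het, distortion = dist,
         sdr = sdr)
  })

  comp <- NULL
  if (!is.null(info) && "chrom" %in% names(info) && any(!is.na(info$chrom))) {
    comp <- stage("compare", {
      anc <- anchor_markers(map, info)
      rho <- spearman_per_lg(map, info)
      inv <- detect_local_inversions(map, info)
      rates <- interval_rates(map, info)
      write_stage_tsv(anc$classification, config$out_dir, "comparison")
      write_stage_tsv(rho, config$out_dir, "spearman")
      write_stage_tsv(inv, config$out_dir, "inversions")
      write_stage_tsv(rates, config$out_dir, "interval_rates")
      list(anchor = anc, spearman = rho, inversions = inv, rates = rates)
    })
  }

  manifest <- list(
    package = "rilmap",
    version = as.character(utils::packageVersion("rilmap")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("genotypes", "marker_info",
                                                 "out_dir"))],
    counts = list(
      markers_in = n_markers_in,
      markers_removed_qc = sum(!qc$marker_report$retained),
      markers_retained_qc = sum(qc$marker_report$retained),
      lines_in = n_lines_in,
      lines_removed_qc = sum(!qc$line_report$retained),
      lines_retained_qc = sum(qc$line_report$retained),
      calls_imputed = binned$imputed,
      bins = ncol(binned$geno) - 1,
      linkage_groups = nrow(map$groups),
      markers_mapped = nrow(map$map),
      markers_unplaced = length(map$unplaced),
      map_length_cM = round(sum(map$groups$length_cM), 4),
      distorted_markers = sum(diag$distortion$distorted, na.rm = TRUE),
      sdr_regions = nrow(diag$sdr)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, map = map, diagnostics = diag,
                 comparison = comp))
}
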