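map_tbl_of <- function(map) {
  tbl <- if (inherits(map, "ril_map")) map$map else tibble::as_tibble(map)
  stopifnot(all(c("group", "rank", "marker", "cM_cum") %in% names(tbl)))
  tbl
}

#' Anchor mapped markers to physical coordinates and classify them
#'
#' Joins the genetic map with marker physical metadata and classifies every
#' mapped marker exactly once:
#' * `syntenic` — on a pseudochromosome matching the majority chromosome of
#'   its linkage group;
#' * `non_syntenic` — on a different chromosome than its group's majority;
#' * `unplaced_scaffold` — physical hit on a scaffold not assigned to any
#'   chromosome;
#' * `no_physical_hit` — no physical position at all;
#' * `unclassifiable` — member of a group with no physically placed marker
#'   (majority chromosome undefined).
#'
#' Also reports clusters of >= 2 consecutive non-syntenic markers sharing a
#' physical chromosome (consecutive among the chromosome-placed markers of
#' the group), and anchors each unplaced scaffold to the linkage group and
#' cM interval of its markers.
#'
#' @param map A `ril_map` or its [tidy()] tibble.
#' @param marker_info Tibble with `marker`, `scaffold`, `chrom`, `bp`
#'   (`chrom` `NA` for unplaced scaffolds; `scaffold`/`bp` `NA` for markers
#'   without a physical hit).
#' @return A list of class `anchor_report`: `classification` (per-marker
#'   tibble with `class`, `lg_chrom`, physical fields), `group_chrom`
#'   (majority chromosome per group), `clusters` (non-syntenic runs),
#'   `scaffold_anchors` (scaffold -> group + cM interval), and `counts`
#'   (markers per class).
#' @export
anchor_markers <- function(map, marker_info) {
  tbl <- map_tbl_of(map)
  info <- tibble::as_tibble(marker_info)
  stopifnot("marker" %in% names(info))
  for (col in c("scaffold", "chrom", "bp")) {
    if (!col %in% names(info)) info[[col]] <- NA
  }
  cls <- dplyr::left_join(tbl, info[c("marker", "scaffold", "chrom", "bp")],
                          by = "marker")

  group_chrom <- dplyr::summarise(
    dplyr::group_by(cls, .data$group),
    lg_chrom = {
      tab <- table(.data$chrom[!is.na(.data$chrom)])
      if (length(tab) == 0) NA_character_ else names(which.max(tab))
    },
    .groups = "drop"
  )
  cls <- dplyr::left_join(cls, group_chrom, by = "group")
  cls$class <- dplyr::case_when(
    !is.na(cls$chrom) & is.na(cls$lg_chrom) ~ "unclassifiable",
    !is.na(cls$chrom) & cls$chrom == cls$lg_chrom ~ "syntenic",
    !is.na(cls$chrom) ~ "non_syntenic",
    !is.na(cls$scaffold) ~ "unplaced_scaffold",
    TRUE ~ "no_physical_hit"
  )

  # non-syntenic clusters: runs among the chromosome-placed markers of a
  # group, same physical chromosome
  clusters <- list()
  for (grp in split(cls, cls$group)) {
    placed <- grp[!is.na(grp$chrom), , drop = FALSE]
    placed <- placed[order(placed$rank), , drop = FALSE]
    if (nrow(placed) < 2) next
    ns <- placed$class == "non_syntenic"
    run <- cumsum(c(TRUE, !(ns[-1] & ns[-length(ns)] &
                              placed$chrom[-1] == placed$chrom[-nrow(placed)])))
    for (ids in split(seq_len(nrow(placed)), run)) {
      if (length(ids) < 2 || !all(ns[ids])) next
      clusters[[length(clusters) + 1]] <- tibble::tibble(
        group = placed$group[1],
        chrom = placed$chrom[ids[1]],
        n_markers = length(ids),
        start_cM = min(placed$cM_cum[ids]),
        end_cM = max(placed$cM_cum[ids]),
        markers = list(placed$marker[ids])
      )
    }
  }
  clusters <- if (length(clusters)) dplyr::bind_rows(clusters) else
    tibble::tibble(group = character(), chrom = character(),
                   n_markers = integer(), start_cM = numeric(),
                   end_cM = numeric(), markers = list())

  unpl <- dplyr::filter(cls, .data$class == "unplaced_scaffold")
  anchors <- if (nrow(unpl) == 0) {
    tibble::tibble(scaffold = character(), group = character(),
                   n_markers = integer(), start_cM = numeric(),
                   end_cM = numeric())
  } else {
    dplyr::summarise(
      dplyr::group_by(unpl, .data$scaffold),
      group = names(which.max(table(.data$group))),
      n_markers = dplyr::n(),
      start_cM = min(.data$cM_cum),
      end_cM = max(.data$cM_cum),
      .groups = "drop"
    )
  }

  counts <- dplyr::count(cls, .data$class, name = "n_markers")
  structure(
    list(classification = dplyr::select(cls, "group", "rank", "marker",
                                        "cM_cum", "scaffold", "chrom", "bp",
                                        "lg_chrom", "class"),
         group_chrom = group_chrom, clusters = clusters,
         scaffold_anchors = anchors, counts = counts),
    class = "anchor_report"
  )
}

#' @export
print.anchor_report <- function(x, ...) {
  cat("Marker anchoring:\n")
  print(x$counts)
  invisible(x)
}

# per-group syntenic markers in map order, optionally orientation-normalised
# against the physical order (groups whose Spearman rho is negative are
# reversed: linkage-map orientation is arbitrary)
syntenic_by_group <- function(map, marker_info, orient = TRUE) {
  cls <- anchor_markers(map, marker_info)$classification
  syn <- dplyr::filter(cls, .data$class == "syntenic")
  out <- list()
  for (grp in split(syn, syn$group)) {
    grp <- grp[order(grp$rank), , drop = FALSE]
    grp$flipped <- FALSE
    if (nrow(grp) >= 3) {
      rho <- stats::cor(grp$rank, grp$bp, method = "spearman")
      if (orient && !is.na(rho) && rho < 0) {
        grp <- grp[rev(seq_len(nrow(grp))), , drop = FALSE]
        grp$rank <- rev(grp$rank)
        grp$flipped <- TRUE
      }
    }
    out[[grp$group[1]]] <- grp
  }
  out
}

#' Spearman collinearity between genetic and physical order, per group
#'
#' Rank correlation between map order and physical bp position over the
#' syntenic markers of each linkage group. `rho_raw` is computed in the
#' map's own orientation; since that orientation is arbitrary, groups with
#' negative `rho_raw` are reversed (`flipped`) and `rho` reports the
#' correlation after orientation, so the genome-wide median is
#' non-negative.
#'
#' @param map A `ril_map` or its [tidy()] tibble.
#' @param marker_info Physical metadata (see [anchor_markers()]).
#' @param min_markers Minimum syntenic markers per group (default 3);
#'   smaller groups get `NA`.
#' @return A tibble: `group`, `chrom`, `n`, `rho_raw`, `flipped`, `rho`.
#' @export
spearman_per_lg <- function(map, marker_info, min_markers = 3) {
  cls <- anchor_markers(map, marker_info)$classification
  syn <- dplyr::filter(cls, .data$class == "syntenic")
  dplyr::summarise(
    dplyr::group_by(syn, .data$group),
    chrom = .data$lg_chrom[1],
    n = dplyr::n(),
    rho_raw = if (dplyr::n() >= min_markers)
      stats::cor(.data$rank, .data$bp, method = "spearman") else NA_real_,
    flipped = !is.na(rho_raw) & rho_raw < 0,
    rho = ifelse(flipped, -rho_raw, rho_raw),
    .groups = "drop"
  )
}

#' Flag putative inversions from local rank correlation
#'
#' After normalising each group's orientation against the physical order, a
#' window of `window` consecutive syntenic markers slides along the map;
#' windows whose local Spearman correlation is at or below `rho_threshold`
#' are flagged and overlapping flagged windows are merged into maximal
#' segments, reported with their cM and bp extents and segment-wide
#' correlation. Groups with fewer syntenic markers than `window` yield no
#' output.
#'
#' @param map A `ril_map` or its [tidy()] tibble.
#' @param marker_info Physical metadata.
#' @param window Markers per window (>= 4, default 10).
#' @param rho_threshold Flagging threshold (< 0, default -0.8).
#' @return A tibble: `group`, `chrom`, `n_markers`, `start_cM`, `end_cM`,
#'   `start_bp`, `end_bp`, `rho`, `markers` (list column).
#' @export
detect_local_inversions <- function(map, marker_info, window = 10,
                                    rho_threshold = -0.8) {
  stopifnot(window >= 4, rho_threshold < 0)
  groups <- syntenic_by_group(map, marker_info, orient = TRUE)
  out <- list()
  for (grp in groups) {
    n <- nrow(grp)
    if (n < window) next
    flagged <- logical(n)
    for (i in seq_len(n - window + 1)) {
      w <- i:(i + window - 1)
      rho <- stats::cor(seq_along(w), grp$bp[w], method = "spearman")
      if (!is.na(rho) && rho <= rho_threshold) flagged[w] <- TRUE
    }
    if (!any(flagged)) next
    run <- cumsum(c(TRUE, flagged[-1] != flagged[-n]))
    for (ids in split(seq_len(n), run)) {
      if (!flagged[ids[1]] || length(ids) < 2) next
      out[[length(out) + 1]] <- tibble::tibble(
        group = grp$group[1],
        chrom = grp$chrom[1],
        n_markers = length(ids),
        start_cM = min(grp$cM_cum[ids]),
        end_cM = max(grp$cM_cum[ids]),
        start_bp = min(grp$bp[ids]),
        end_bp = max(grp$bp[ids]),
        rho = stats::cor(seq_along(ids), grp$bp[ids], method = "spearman"),
        markers = list(grp$marker[ids])
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(group = character(), chrom = character(),
                   n_markers = integer(), start_cM = numeric(),
                   end_cM = numeric(), start_bp = numeric(),
                   end_bp = numeric(), rho = numeric(), markers = list())
}

#' Recombination-rate classification
#'
#' Hot: rate strictly above 20 cM/Mb. Cold: exactly 0 cM/Mb (complete
#' suppression). Moderate: 10-20 cM/Mb. Everything else: normal.
#'
#' @param rate Numeric cM/Mb value(s).
#' @return Character vector of classes.
#' @export
classify_rate <- function(rate) {
  dplyr::case_when(
    rate > 20 ~ "hot",
    rate >= 10 ~ "moderate",
    rate == 0 ~ "cold",
    TRUE ~ "normal"
  )
}

#' Per-interval recombination rates (the cM/Mb landscape)
#'
#' For every adjacent pair of syntenic markers of a group (after orientation
#' normalisation), the interval rate is the cM span divided by the physical
#' span in Mb, classified with [classify_rate()]. Intervals whose physical
#' span is not positive (locally out-of-order assembly) are skipped and
#' returned in the `skipped` attribute.
#'
#' @param map A `ril_map` or its [tidy()] tibble.
#' @param marker_info Physical metadata.
#' @return A tibble: `group`, `chrom`, `marker_start`, `marker_end`,
#'   `cM_start`, `cM_end`, `bp_start`, `bp_end`, `d_cM`, `d_bp`,
#'   `rate_cM_per_Mb`, `class`; skipped intervals in `attr(, "skipped")`.
#' @export
interval_rates <- function(map, marker_info) {
  groups <- syntenic_by_group(map, marker_info, orient = TRUE)
  out <- list()
  for (grp in groups) {
    n <- nrow(grp)
    if (n < 2) next
    iv <- tibble::tibble(
      group = grp$group[1], chrom = grp$chrom[1],
      marker_start = grp$marker[-n], marker_end = grp$marker[-1],
      cM_start = pmin(grp$cM_cum[-n], grp$cM_cum[-1]),
      cM_end = pmax(grp$cM_cum[-n], grp$cM_cum[-1]),
      bp_start = grp$bp[-n], bp_end = grp$bp[-1]
    )
    iv$d_cM <- iv$cM_end - iv$cM_start
    iv$d_bp <- iv$bp_end - iv$bp_start
    out[[length(out) + 1]] <- iv
  }
  iv <- dplyr::bind_rows(out)
  skipped <- dplyr::filter(iv, .data$d_bp <= 0)
  iv <- dplyr::filter(iv, .data$d_bp > 0)
  iv$rate_cM_per_Mb <- iv$d_cM / (iv$d_bp / 1e6)
  iv$class <- classify_rate(iv$rate_cM_per_Mb)
  attr(iv, "skipped") <- skipped
  iv
}

#' Chromosome-level and genome-wide recombination rates
#'
#' `chromosome_rates()` divides each group's cM span by the physical span
#' (Mb) between its first and last syntenic marker. `genome_wide_rates()`
#' computes the genome totals from per-chromosome spans: overall cM/Mb,
#' mean physical spacing (Kbp/marker) and, when an annotated gene total is
#' given, the gene-per-cM rate.
#'
#' @param map A `ril_map` or its [tidy()] tibble.
#' @param marker_info Physical metadata.
#' @param length_cM,span_Mb Numeric vectors of per-chromosome genetic
#'   lengths and physical spans.
#' @param n_markers Optional total mapped marker count.
#' @param n_genes Optional total annotated gene count.
#' @return `chromosome_rates()`: tibble (`group`, `chrom`, `length_cM`,
#'   `span_Mb`, `rate_cM_per_Mb`). `genome_wide_rates()`: one-row tibble
#'   (`total_cM`, `total_Mb`, `rate_cM_per_Mb`, `kbp_per_marker`,
#'   `genes_per_cM`).
#' @examples
#' ref <- cpr01_reference("chromosomes")
#' genome_wide_rates(ref$length_cM, ref$span_Mb,
#'                   n_markers = sum(ref$n_markers))
#' @export
chromosome_rates <- function(map, marker_info) {
  groups <- syntenic_by_group(map, marker_info, orient = TRUE)
  dplyr::bind_rows(lapply(groups, function(grp) {
    tibble::tibble(
      group = grp$group[1], chrom = grp$chrom[1],
      length_cM = max(grp$cM_cum) - min(grp$cM_cum),
      span_Mb = (max(grp$bp) - min(grp$bp)) / 1e6
    )
  })) |>
    dplyr::mutate(rate_cM_per_Mb = .data$length_cM / .data$span_Mb)
}

#' @rdname chromosome_rates
#' @export
genome_wide_rates <- function(length_cM, span_Mb, n_markers = NULL,
                              n_genes = NULL) {
  total_cM <- sum(length_cM)
  total_Mb <- sum(span_Mb)
  tibble::tibble(
    total_cM = total_cM,
    total_Mb = total_Mb,
    rate_cM_per_Mb = total_cM / total_Mb,
    kbp_per_marker = if (is.null(n_markers)) NA_real_ else
      total_Mb * 1e3 / n_markers,
    genes_per_cM = if (is.null(n_genes)) NA_real_ else n_genes / total_cM
  )
}

#' Read gene annotation (and optionally genome sequence)
#'
#' GFF3/GTF/BED import goes through `rtracklayer`; only gene-level features
#' are kept from GFF3 (`type == "gene"`, or everything if no type column).
#' Coordinates are stored 1-based closed (the GRanges convention). FASTA
#' import goes through `Biostrings`.
#'
#' @param genes_file Path to a BED or GFF3 file of gene intervals.
#' @param fasta_file Optional path to the genome FASTA.
#' @return A list of class `genome_annotation`: `genes` (tibble `chrom`,
#'   `start`, `end`), `seq` (`DNAStringSet` or `NULL`), `n_genes`.
#' @export
read_genome_annotation <- function(genes_file, fasta_file = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("package 'rtracklayer' is required to read annotation", call. = FALSE)
  }
  gr <- rtracklayer::import(genes_file)
  md <- as.data.frame(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    md <- md[md$type == "gene", , drop = FALSE]
  }
  genes <- tibble::tibble(chrom = as.character(md$seqnames),
                          start = md$start, end = md$end)
  seq <- NULL
  if (!is.null(fasta_file)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("package 'Biostrings' is required to read FASTA", call. = FALSE)
    }
    seq <- Biostrings::readDNAStringSet(fasta_file)
    names(seq) <- sub("\\s.*$", "", names(seq))
  }
  structure(list(genes = genes, seq = seq, n_genes = nrow(genes)),
            class = "genome_annotation")
}

#' Gene density and GC content of physical intervals
#'
#' Adds gene count (genes whose midpoint falls inside the interval, so no
#' gene is counted in two adjacent intervals), gene density per Mb of the
#' interval span, and — when sequence is available — the GC fraction
#' (G+C)/(A+C+G+T) with ambiguity codes excluded.
#'
#' @param intervals Tibble with `chrom`, and either `bp_start`/`bp_end` or
#'   `start`/`end` (1-based closed).
#' @param annotation A [read_genome_annotation()] object.
#' @return The input with `n_genes`, `gene_density_per_Mb` and `gc_frac`
#'   columns added.
#' @export
interval_composition <- function(intervals, annotation) {
  iv <- tibble::as_tibble(intervals)
  if (!"start" %in% names(iv)) iv$start <- iv$bp_start
  if (!"end" %in% names(iv)) iv$end <- iv$bp_end
  stopifnot(all(iv$end > iv$start))
  genes <- annotation$genes
  mid <- (genes$start + genes$end) / 2
  iv$n_genes <- purrr::pmap_int(iv[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sum(genes$chrom == chrom & mid >= start & mid <= end)
    })
  iv$gene_density_per_Mb <- iv$n_genes / ((iv$end - iv$start) / 1e6)
  iv$gc_frac <- NA_real_
  if (!is.null(annotation$seq)) {
    iv$gc_frac <- purrr::pmap_dbl(iv[c("chrom", "start", "end")],
      function(chrom, start, end) {
        if (!chrom %in% names(annotation$seq)) return(NA_real_)
        s <- Biostrings::subseq(annotation$seq[[chrom]], start, end)
        counts <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
        tot <- sum(counts)
        if (tot == 0) NA_real_ else sum(counts[c("C", "G")]) / tot
      })
  }
  iv
}

#' Plot the genetic-vs-physical marker comparison
#'
#' Dot plot of map position (cM) against physical position (Mb) for the
#' chromosome-placed markers of each linkage group; non-syntenic markers
#' are highlighted.
#'
#' @param map A `ril_map` or its [tidy()] tibble.
#' @param marker_info Physical metadata.
#' @return A ggplot object.
#' @export
plot_map_vs_physical <- function(map, marker_info) {
  cls <- anchor_markers(map, marker_info)$classification
  cls <- dplyr::filter(cls, .data$class %in% c("syntenic", "non_syntenic"))
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$bp / 1e6, y = .data$cM_cum,
                                    colour = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = "Physical position (Mb)", y = "Map position (cM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the recombination landscape
#'
#' Interval recombination rate (cM/Mb) along each chromosome, with hotspot
#' and coldspot calls coloured.
#'
#' @param rates An [interval_rates()] tibble.
#' @return A ggplot object.
#' @export
plot_recombination_landscape <- function(rates) {
  rates$mid_Mb <- (rates$bp_start + rates$bp_end) / 2e6
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$mid_Mb,
                                      y = .data$rate_cM_per_Mb)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 0.9) +
    ggplot2::geom_hline(yintercept = 20, linetype = 2, colour = "red3") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Physical position (Mb)", y = "cM/Mb", colour = NULL) +
    ggplot2::theme_minimal()
}
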