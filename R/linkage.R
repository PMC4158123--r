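#' Pairwise recombination-fraction estimates
#'
#' For every marker pair, the observed recombinant fraction: the number of
#' lines with opposite homozygous calls divided by the number of lines with
#' homozygous non-missing calls at both markers. Heterozygous calls carry no
#' phase information in a RIL and are excluded. Pairs with fewer than
#' `min_informative` informative lines are set `NA`. With
#' `ril_correction = TRUE` the accumulated-recombination correction
#' r = R/(2-2R) ([ril_rf_correction()]) is applied.
#'
#' @param geno Genotype tibble or matrix (>= 2 markers).
#' @param min_informative Minimum informative lines per pair (default 20).
#' @param ril_correction Convert the observed fraction to a per-meiosis
#'   fraction (default `FALSE`, i.e. the raw fraction is reported).
#' @return A list of class `pairwise_rf` with symmetric matrices `r`
#'   (fractions, diagonal 0) and `n` (informative-line counts).
#' @examples
#' g <- tibble::tibble(line = paste0("L", 1:4),
#'                     a = c("A", "A", "B", "B"), b = c("A", "B", "B", "A"))
#' pairwise_rf(g, min_informative = 1)$r
#' @export
pairwise_rf <- function(geno, min_informative = 20, ril_correction = FALSE) {
  m <- as_geno_matrix(geno)
  if (ncol(m) < 2) stop("need at least 2 markers", call. = FALSE)
  A <- (m == "A") * 1
  B <- (m == "B") * 1
  n_rec <- crossprod(A, B) + crossprod(B, A)
  n_inf <- crossprod(A + B)
  r <- n_rec / n_inf
  r[n_inf < min_informative] <- NA_real_
  diag(r) <- 0
  if (ril_correction) r <- ril_rf_correction(r)
  structure(list(r = r, n = n_inf, min_informative = min_informative,
                 ril_correction = ril_correction),
            class = "pairwise_rf")
}

#' @export
print.pairwise_rf <- function(x, ...) {
  cat("Pairwise recombination fractions for", ncol(x$r), "markers (",
      sum(!is.na(x$r[upper.tri(x$r)])), "defined pairs )\n")
  invisible(x)
}

#' Cluster markers into linkage groups by single linkage
#'
#' Two markers belong to the same group iff they are connected by a chain of
#' pairs with defined recombination fraction <= `cutoff` (transitive
#' closure). Groups are numbered by size, descending; single-marker groups
#' are flagged.
#'
#' @param rf A [pairwise_rf()] object.
#' @param cutoff Recombination-fraction cutoff in (0, 0.5\] (default 0.2).
#' @return A tibble with columns `marker`, `group` (integer rank by size),
#'   `group_size`, `singleton`.
#' @export
group_markers <- function(rf, cutoff = 0.2) {
  stopifnot(inherits(rf, "pairwise_rf"), cutoff > 0, cutoff <= 0.5)
  r <- rf$r
  adj <- !is.na(r) & r <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  rank <- rank(-sizes, ties.method = "first")
  tibble::tibble(
    marker = colnames(r),
    group = as.integer(rank[comp$membership]),
    group_size = as.integer(sizes[comp$membership]),
    singleton = sizes[comp$membership] == 1
  )
}

#' COUNT: total recombination events along a marker order
#'
#' The RECORD objective: for each line, the number of A<->B transitions
#' between consecutive non-missing homozygous calls along the order, summed
#' over lines. Heterozygous calls are treated as missing.
#'
#' @param geno Genotype tibble or matrix.
#' @param order Character vector: a permutation of the marker ids.
#' @return Integer COUNT.
#' @examples
#' g <- tibble::tibble(line = paste0("L", 1:4),
#'                     a = c("A", "A", "B", "B"), b = c("A", "B", "B", "A"))
#' count_recombinations(g, c("a", "b"))  # 2
#' @export
count_recombinations <- function(geno, order) {
  m <- as_geno_matrix(geno)
  idx <- match(order, colnames(m))
  if (anyNA(idx) || length(idx) != ncol(m) || anyDuplicated(idx)) {
    stop("`order` must be a permutation of the marker ids", call. = FALSE)
  }
  count_recomb_cpp(geno_int(m), as.integer(idx))
}

# orientation convention: first marker id lexicographically <= last
canonical_orientation <- function(order) {
  if (length(order) > 1 && order[1] > order[length(order)]) rev(order) else order
}

#' Order markers by greedy recombination-count insertion (RECORD-style)
#'
#' Markers are taken in random order and inserted one at a time at the
#' position of the growing order that minimises [count_recombinations()];
#' the procedure is repeated for `n_starts` random shuffles and the
#' lowest-COUNT order is kept (ties prefer the earlier candidate). The
#' returned orientation is canonical: first marker id lexicographically
#' before the last.
#'
#' @param geno Genotype tibble or matrix for one linkage group (>= 2
#'   markers).
#' @param n_starts Number of random starts (default 30).
#' @param seed Optional seed; with `NULL` the current RNG stream is used.
#' @return Character vector: the marker order.
#' @export
order_record <- function(geno, n_starts = 30, seed = NULL) {
  m <- as_geno_matrix(geno)
  if (ncol(m) < 2) stop("need at least 2 markers to order", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  gi <- geno_int(m)
  best <- NULL
  best_count <- Inf
  for (s in seq_len(n_starts)) {
    shuffle <- sample.int(ncol(m))
    ord <- greedy_insert_cpp(gi, shuffle)
    cnt <- count_recomb_cpp(gi, ord)
    if (cnt < best_count) {
      best_count <- cnt
      best <- ord
    }
  }
  canonical_orientation(colnames(m)[best])
}

#' Refine a marker order by window rippling
#'
#' Slides a window of `window` consecutive markers along the order, trying
#' every permutation of the window and accepting one iff it strictly lowers
#' [count_recombinations()]; full sweeps are repeated until none improves.
#' The result's COUNT is never above the input's. When `window` exceeds the
#' group size, the whole group is permuted exhaustively if it has at most 8
#' markers (otherwise an error).
#'
#' @param geno Genotype tibble or matrix.
#' @param order Character vector: current marker order.
#' @param window Window size (>= 2, <= 8; default 5).
#' @return Character vector: the refined order.
#' @export
ripple <- function(geno, order, window = 5) {
  m <- as_geno_matrix(geno)
  idx <- match(order, colnames(m))
  if (anyNA(idx) || length(idx) != ncol(m)) {
    stop("`order` must be a permutation of the marker ids", call. = FALSE)
  }
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  gi <- geno_int(m)
  if (window > length(idx)) {
    if (length(idx) > 8) {
      stop("window exceeds group size; exhaustive search only supported for <= 8 markers",
           call. = FALSE)
    }
    perms <- permutations_of(length(idx))
    counts <- vapply(perms, function(p) count_recomb_cpp(gi, idx[p]), integer(1))
    return(colnames(m)[idx[perms[[which.min(counts)]]]])
  }
  out <- ripple_cpp(gi, as.integer(idx), as.integer(window))
  colnames(m)[out]
}

# all permutations of 1..n (n <= 8), lexicographic
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[p])
    }
  }
  out
}

#' Correct singleton calls (apparent double recombinants)
#'
#' Along an ordered group, a non-missing call that differs from both its
#' nearest non-missing neighbour calls, where those two neighbours agree, is
#' a singleton — an apparent double crossover in a single-marker interval,
#' usually a genotyping error. Singletons are detected on the input pattern
#' (one simultaneous pass) and replaced by the flanking consensus; boundary
#' markers are never corrected.
#'
#' @param geno Genotype tibble or matrix.
#' @param order Character vector: the marker order of the group.
#' @return A list with `geno` (corrected table) and `log`
#'   (`line`, `marker`, `old`, `new`).
#' @examples
#' g <- tibble::tibble(line = "L1", m1 = "A", m2 = "A", m3 = "B",
#'                     m4 = "A", m5 = "A")
#' correct_singletons(g, paste0("m", 1:5))$log
#' @export
correct_singletons <- function(geno, order) {
  m <- as_geno_matrix(geno)
  idx <- match(order, colnames(m))
  if (anyNA(idx) || length(idx) != ncol(m)) {
    stop("`order` must be a permutation of the marker ids", call. = FALSE)
  }
  out <- m
  logs <- list()
  for (i in seq_len(nrow(m))) {
    calls <- m[i, idx]
    obs <- which(calls != "U")
    if (length(obs) < 3) next
    j <- seq(2, length(obs) - 1)
    cur <- calls[obs[j]]
    prv <- calls[obs[j - 1]]
    nxt <- calls[obs[j + 1]]
    hit <- prv == nxt & cur != prv
    if (any(hit)) {
      pos <- obs[j][hit]
      logs[[length(logs) + 1]] <- tibble::tibble(
        line = rownames(m)[i],
        marker = colnames(m)[idx[pos]],
        old = calls[pos],
        new = prv[hit]
      )
      out[i, idx[pos]] <- prv[hit]
    }
  }
  log <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(line = character(), marker = character(),
                   old = character(), new = character())
  list(geno = as_geno_tbl(out), log = log)
}

# flanking re-imputation along the map order (same rule as impute_flanking,
# but bounded by the linkage group rather than a scaffold)
impute_along_order <- function(m, order) {
  idx <- match(order, colnames(m))
  sub <- m[, idx, drop = FALSE]
  sub <- t(apply(sub, 1, fill_missing_runs))
  m[, idx] <- sub
  m
}

# observed recombinant fraction for consecutive pairs of `order`
adjacent_rf <- function(m, order) {
  k <- length(order)
  if (k < 2) return(tibble::tibble(r = numeric(0), n = integer(0)))
  a <- m[, order[-k], drop = FALSE]
  b <- m[, order[-1], drop = FALSE]
  hom <- (a == "A" | a == "B") & (b == "A" | b == "B")
  rec <- hom & a != b
  n <- colSums(hom)
  r <- ifelse(n > 0, colSums(rec) / n, NA_real_)
  tibble::tibble(r = unname(r), n = unname(as.integer(n)))
}

map_length_of <- function(m, order, ril_correction) {
  adj <- adjacent_rf(m, order)
  r <- adj$r
  r[is.na(r)] <- 0
  if (ril_correction) r <- ril_rf_correction(r)
  r <- pmin(r, 0.4999)
  sum(kosambi_distance(r))
}

#' Build a genetic linkage map
#'
#' The two-round mapping procedure applied to a QC'd (and normally binned)
#' genotype table:
#' round 1 clusters markers into linkage groups ([group_markers()] at
#' `cutoff` on raw pairwise fractions), orders each group
#' ([order_record()]) and refines it ([ripple()]); singletons are then
#' corrected ([correct_singletons()]) and missing calls re-imputed from
#' agreeing flanks along the map order; round 2 re-orders and re-ripples
#' that matrix. Per group, the candidate order (round 1 vs round 2) with
#' the shortest total Kosambi length is selected (ties keep round 1).
#' Adjacent recombination fractions — and with them all cM distances — are
#' estimated from the singleton-corrected but *non*-imputed calls, because
#' flank-based imputation preferentially restores non-recombinant cells and
#' would shrink the map; they are converted with [kosambi_distance()],
#' optionally after the RIL accumulation correction.
#'
#' Groups are labelled by the majority physical chromosome of their markers
#' when `marker_info$chrom` is available (falling back to `LG<size rank>`
#' when undefined or duplicated), else by size rank.
#'
#' @param geno Genotype tibble or matrix.
#' @param marker_info Optional tibble (`marker`, `chrom`, ...) used for
#'   group labelling.
#' @param cutoff Single-linkage grouping cutoff (default 0.2).
#' @param min_informative Minimum informative lines per pair (default 20).
#' @param n_starts Random starts for [order_record()] (default 30).
#' @param window Ripple window (default 5).
#' @param ril_correction Apply r = R/(2-2R) before the Kosambi conversion
#'   (default `FALSE`; enable when absolute cM lengths in a selfed RIL are
#'   of interest).
#' @param seed Integer seed; the whole build is deterministic under it.
#' @return An object of class `ril_map`: list with
#'   * `map` — tibble (`group`, `rank`, `marker`, `r_adj`, `cM_adj`,
#'     `cM_cum`), first marker of each group at 0 cM;
#'   * `groups` — per-group tibble (`group`, `n_markers`, `length_cM`,
#'     `count`, `round_selected`);
#'   * `unplaced` — markers in single-marker groups;
#'   * `geno` — the corrected, re-imputed genotype table the distances were
#'     computed from;
#'   * `correction_log`, `params`.
#' @examples
#' sim <- simulate_ril_population(
#'   sim_config(list(Ca1 = sim_chromosome("Ca1", 10, 50)), n_lines = 60, seed = 4))
#' mp <- build_map(sim$geno, sim$marker_info, seed = 4)
#' tidy(mp)
#' @export
build_map <- function(geno, marker_info = NULL, cutoff = 0.2,
                      min_informative = 20, n_starts = 30, window = 5,
                      ril_correction = FALSE, seed = 1) {
  m <- as_geno_matrix(geno)
  withr::local_seed(seed)
  rf <- pairwise_rf(m, min_informative = min_informative)
  grouping <- group_markers(rf, cutoff = cutoff)
  unplaced <- grouping$marker[grouping$singleton]
  groups <- split(grouping$marker[!grouping$singleton],
                  grouping$group[!grouping$singleton])
  groups <- groups[order(as.integer(names(groups)))]

  corrected <- m
  results <- list()
  logs <- list()
  for (gid in names(groups)) {
    markers <- groups[[gid]]
    sub <- m[, markers, drop = FALSE]
    ord1 <- ripple(sub, order_record(sub, n_starts = n_starts), window = window)
    cs <- correct_singletons(sub, ord1)
    sub2 <- as_geno_matrix(cs$geno)
    # re-imputed matrix is used for round-2 ordering only: filling missing
    # runs from agreeing flanks preferentially recovers non-recombinant
    # cells, which would bias adjacent rf (and hence cM distances) downward
    sub2_imp <- impute_along_order(sub2, ord1)
    ord2 <- ripple(sub2_imp, order_record(sub2_imp, n_starts = n_starts),
                   window = window)
    len1 <- map_length_of(sub2, ord1, ril_correction)
    len2 <- map_length_of(sub2, ord2, ril_correction)
    ord <- if (len2 < len1) ord2 else ord1
    ord <- canonical_orientation(ord)
    corrected[, markers] <- sub2[, markers]
    logs[[gid]] <- cs$log
    adj <- adjacent_rf(sub2, ord)
    r <- adj$r
    r[is.na(r)] <- 0
    r_conv <- if (ril_correction) ril_rf_correction(r) else r
    d <- kosambi_distance(pmin(r_conv, 0.4999))
    results[[gid]] <- tibble::tibble(
      group_id = as.integer(gid),
      rank = seq_along(ord),
      marker = ord,
      r_adj = c(NA_real_, r),
      cM_adj = c(0, d),
      cM_cum = cumsum(c(0, d)),
      count = count_recomb_cpp(geno_int(sub2), match(ord, colnames(sub2))),
      round_selected = if (len2 < len1) 2L else 1L
    )
  }
  map <- dplyr::bind_rows(results)
  if (nrow(map) == 0) stop("no linkage groups with >= 2 markers", call. = FALSE)

  labels <- label_groups(map, marker_info)
  map$group <- labels[as.character(map$group_id)]
  groups_tbl <- dplyr::summarise(
    dplyr::group_by(map, .data$group_id, .data$group),
    n_markers = dplyr::n(),
    length_cM = max(.data$cM_cum),
    count = .data$count[1],
    round_selected = .data$round_selected[1],
    .groups = "drop"
  )
  structure(
    list(
      map = dplyr::select(map, "group", "rank", "marker", "r_adj", "cM_adj",
                          "cM_cum"),
      groups = groups_tbl,
      unplaced = unplaced,
      geno = as_geno_tbl(corrected),
      correction_log = dplyr::bind_rows(logs),
      params = list(cutoff = cutoff, min_informative = min_informative,
                    n_starts = n_starts, window = window,
                    ril_correction = ril_correction, seed = seed)
    ),
    class = "ril_map"
  )
}

# majority physical chromosome labels, unique, else LG<size rank>
label_groups <- function(map, marker_info) {
  ids <- sort(unique(map$group_id))
  sizes <- vapply(ids, function(g) sum(map$group_id == g), integer(1))
  rank_label <- paste0("LG", rank(-sizes, ties.method = "first"))
  labels <- setNames(rank_label, as.character(ids))
  if (!is.null(marker_info) && "chrom" %in% names(marker_info)) {
    chrom <- marker_info$chrom[match(map$marker, marker_info$marker)]
    maj <- vapply(ids, function(g) {
      tab <- table(chrom[map$group_id == g])
      if (length(tab) == 0) NA_character_ else names(which.max(tab))
    }, character(1))
    ok <- !is.na(maj) & !duplicated(maj) & !duplicated(maj, fromLast = TRUE)
    labels[ok] <- maj[ok]
  }
  labels
}

#' @export
print.ril_map <- function(x, ...) {
  cat("Genetic linkage map: ", nrow(x$map), " markers in ",
      nrow(x$groups), " group(s), total ",
      round(sum(x$groups$length_cM), 1), " cM\n", sep = "")
  if (length(x$unplaced)) cat(length(x$unplaced), "unplaced marker(s)\n")
  invisible(x)
}

#' @describeIn build_map Marker-level map tibble.
#' @param x,object A `ril_map`.
#' @param ... Unused.
#' @export
tidy.ril_map <- function(x, ...) x$map

#' @describeIn build_map One-row map summary.
#' @export
glance.ril_map <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    n_markers = nrow(x$map),
    n_unplaced = length(x$unplaced),
    length_cM = sum(x$groups$length_cM),
    mean_spacing_cM = sum(x$groups$length_cM) / nrow(x$map),
    total_count = sum(x$groups$count)
  )
}

#' @describeIn build_map Plot marker positions along each linkage group.
#' @export
autoplot.ril_map <- function(object, ...) {
  ggplot2::ggplot(object$map,
                  ggplot2::aes(x = .data$group, y = .data$cM_cum)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$group),
                       linewidth = 3, colour = "grey85") +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Position (cM)",
                  title = "Genetic linkage map") +
    ggplot2::theme_minimal()
}
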