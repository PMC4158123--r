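# fill each maximal run of missing calls whose two nearest non-missing
# neighbours agree; `calls` runs along one scaffold in physical order
fill_missing_runs <- function(calls) {
  miss <- which(calls == "U")
  if (length(miss) == 0) return(calls)
  obs <- which(calls != "U")
  if (length(obs) < 2) return(calls)
  left <- findInterval(miss, obs)
  right <- left + 1L
  ok <- left >= 1L & right <= length(obs)
  if (!any(ok)) return(calls)
  li <- obs[left[ok]]
  ri <- obs[right[ok]]
  agree <- calls[li] == calls[ri]
  calls[miss[ok][agree]] <- calls[li[agree]]
  calls
}

#' Impute missing calls from identical flanking calls within a scaffold
#'
#' For each line, a run of missing calls at consecutive markers of one
#' scaffold (markers ordered by physical position) is filled with the shared
#' flanking call when the nearest non-missing calls on both sides exist and
#' are identical — the assumption being that no recombination occurred in
#' that region. Runs at scaffold boundaries, or with disagreeing flanks,
#' are left missing; imputation never crosses a scaffold boundary and never
#' changes a non-missing call. Only markers with a scaffold and bp position
#' in `marker_info` participate.
#'
#' @param geno Genotype tibble or matrix.
#' @param marker_info Tibble with columns `marker`, `scaffold`, `bp`.
#' @return A list with `geno` (imputed table) and `log`, a tibble of filled
#'   cells (`line`, `marker`, `call`).
#' @examples
#' g <- tibble::tibble(line = "L1", m1 = "A", m2 = "U", m3 = "A")
#' mi <- tibble::tibble(marker = c("m1", "m2", "m3"), scaffold = "sc1", bp = 1:3)
#' impute_flanking(g, mi)$geno
#' @export
impute_flanking <- function(geno, marker_info) {
  m <- as_geno_matrix(geno)
  info <- tibble::as_tibble(marker_info)
  stopifnot(all(c("marker", "scaffold", "bp") %in% names(info)))
  info <- dplyr::filter(info, .data$marker %in% colnames(m),
                        !is.na(.data$scaffold), !is.na(.data$bp))
  info <- dplyr::arrange(info, .data$scaffold, .data$bp)
  out <- m
  for (cols in split(info$marker, info$scaffold)) {
    if (length(cols) < 3) next
    sub <- out[, cols, drop = FALSE]
    out[, cols] <- t(apply(sub, 1, fill_missing_runs))
  }
  changed <- which(out != m, arr.ind = TRUE)
  log <- tibble::tibble(
    line = rownames(m)[changed[, 1]],
    marker = colnames(m)[changed[, 2]],
    call = out[changed]
  )
  list(geno = as_geno_tbl(out), log = log)
}

#' Merge markers with identical segregation patterns into bins
#'
#' Markers whose full call vectors are exactly identical — including the
#' positions of missing calls, so no silent imputation happens at this step
#' — form one recombination bin, reduced to a single representative column.
#' The representative is the member with the fewest missing calls, ties
#' broken by lowest physical position (when `marker_info` provides `bp`)
#' and then lexicographically by marker id.
#'
#' @param geno Genotype tibble or matrix (normally after
#'   [impute_flanking()]).
#' @param marker_info Optional tibble with `marker`, `scaffold`, `bp`; used
#'   for tie-breaking and for `scope = "scaffold"`.
#' @param scope `"genome"` (default): patterns are compared genome-wide;
#'   `"scaffold"`: only markers on the same scaffold can share a bin.
#' @return A list with `geno` (one column per bin, named by the
#'   representative) and `bins`, a tibble with one row per member marker
#'   (`bin`, `representative`, `marker`, `n_members`).
#' @examples
#' g <- tibble::tibble(line = c("L1", "L2"), m1 = c("A", "B"),
#'                     m2 = c("A", "B"), m3 = c("B", "B"))
#' bin_identical(g)$bins
#' @export
bin_identical <- function(geno, marker_info = NULL,
                          scope = c("genome", "scaffold")) {
  scope <- match.arg(scope)
  m <- as_geno_matrix(geno)
  key <- apply(m, 2, paste, collapse = "")
  if (scope == "scaffold") {
    if (is.null(marker_info)) {
      stop("`marker_info` is required for scaffold-scoped binning", call. = FALSE)
    }
    sc <- marker_info$scaffold[match(colnames(m), marker_info$marker)]
    key <- paste(ifelse(is.na(sc), colnames(m), sc), key)
  }
  bp <- rep(NA_real_, ncol(m))
  if (!is.null(marker_info) && "bp" %in% names(marker_info)) {
    bp <- as.numeric(marker_info$bp[match(colnames(m), marker_info$marker)])
  }
  members <- tibble::tibble(
    marker = colnames(m),
    key = key,
    n_missing = colSums(m == "U"),
    bp = bp
  )
  members <- dplyr::group_by(members, .data$key)
  members <- dplyr::mutate(
    members,
    bin = dplyr::cur_group_id(),
    n_members = dplyr::n()
  )
  members <- dplyr::ungroup(members)
  reps <- dplyr::slice(
    dplyr::group_by(members, .data$bin),
    order(.data$n_missing, .data$bp, .data$marker)[1]
  )
  reps <- dplyr::ungroup(reps)
  members$representative <- reps$marker[match(members$bin, reps$bin)]
  bins <- dplyr::select(members, "bin", "representative", "marker", "n_members")
  reduced <- m[, unique(bins$representative), drop = FALSE]
  list(geno = as_geno_tbl(reduced), bins = bins)
}
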