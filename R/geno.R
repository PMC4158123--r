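#' Genotype tables
#'
#' A genotype table is a wide tibble with one row per line (individual) and
#' one column per marker: the first column, `line`, holds line identifiers,
#' and every other column holds genotype calls coded `A` (parent-1
#' homozygote), `B` (parent-2 homozygote), `H` (heterozygote) or `U`
#' (missing). `as_geno_matrix()` converts such a table to a character matrix
#' with line ids as rownames; `as_geno_tbl()` is the inverse.
#'
#' @param geno A genotype tibble (column `line` + marker columns) or a
#'   character matrix of calls with rownames as line ids.
#' @param validate Check that every call is one of `A/B/H/U`.
#' @return `as_geno_matrix()`: a character matrix (lines x markers).
#'   `as_geno_tbl()`: a tibble.
#' @examples
#' g <- tibble::tibble(line = c("L1", "L2"), m1 = c("A", "B"), m2 = c("H", "U"))
#' m <- as_geno_matrix(g)
#' identical(as_geno_tbl(m), g)
#' @export
as_geno_matrix <- function(geno, validate = TRUE) {
  if (is.matrix(geno)) {
    m <- geno
    if (is.null(rownames(m))) rownames(m) <- paste0("line", seq_len(nrow(m)))
  } else {
    geno <- tibble::as_tibble(geno)
    if (!"line" %in% names(geno)) {
      stop("genotype table must have a `line` column", call. = FALSE)
    }
    lines <- as.character(geno$line)
    m <- as.matrix(geno[setdiff(names(geno), "line")])
    storage.mode(m) <- "character"
    rownames(m) <- lines
  }
  if (anyDuplicated(rownames(m))) stop("duplicated line ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicated marker ids", call. = FALSE)
  if (validate) {
    bad <- !(m %in% GENO_CALLS)
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)
      idx <- utils::head(idx, 5)
      cells <- paste0(rownames(m)[idx[, 1]], "/", colnames(m)[idx[, 2]],
                      "='", m[idx], "'", collapse = ", ")
      stop("invalid genotype calls (expected A/B/H/U): ", cells, call. = FALSE)
    }
  }
  m
}

#' @rdname as_geno_matrix
#' @export
as_geno_tbl <- function(geno) {
  m <- if (is.matrix(geno)) geno else as_geno_matrix(geno, validate = FALSE)
  dplyr::bind_cols(
    tibble::tibble(line = rownames(m)),
    tibble::as_tibble(m)
  )
}

# integer coding used by the C++ kernels: A=0, B=1, H/U=-1 (missing for
# recombination counting, per RIL convention)
geno_int <- function(m) {
  out <- matrix(-1L, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "A"] <- 0L
  out[m == "B"] <- 1L
  out
}
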