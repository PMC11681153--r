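#' Fuzzy matrices
#'
#' A labelled rectangular grid of TSFNs, stored internally as six numeric
#' matrices sharing dimnames.  Fuzzy matrices house the fuzzified pairwise
#' preference matrix (criteria by criteria) and the fuzzified performance
#' matrix (alternatives by criteria).  When built from a linguistic matrix
#' the originating term codes are retained (`codes` attribute) so that
#' min-max normalization can locate the weakest and strongest linguistic
#' assessment in a column.
#'
#' @param cells A `tsfn` vector in column-major order.
#' @param nrow Number of rows.
#' @param dimnames List of row and column labels.
#' @param codes Optional character matrix of originating term codes
#'   (`NA` for cells not backed by a term, e.g. a diagonal fill).
#' @return An object of class `fuzzy_matrix`.
#' @export
fuzzy_matrix <- function(cells, nrow, dimnames = NULL, codes = NULL) {
  stopifnot(is_tsfn(cells), length(cells) %% nrow == 0)
  ncol <- length(cells) / nrow
  shape <- function(v) matrix(v, nrow, ncol, dimnames = dimnames)
  structure(
    list(a = shape(cells$a), b = shape(cells$b), c = shape(cells$c),
         mu = shape(cells$mu), eta = shape(cells$eta), nu = shape(cells$nu)),
    codes = codes,
    class = "fuzzy_matrix")
}

#' @export
is_fuzzy_matrix <- function(x) inherits(x, "fuzzy_matrix")

#' @export
dim.fuzzy_matrix <- function(x) dim(x$a)

#' @export
dimnames.fuzzy_matrix <- function(x) dimnames(x$a)

#' @export
print.fuzzy_matrix <- function(x, ...) {
  d <- dim(x)
  cat("<fuzzy_matrix ", d[1], " x ", d[2], ">\n", sep = "")
  print(matrix(format(fm_cells(x)), d[1], d[2], dimnames = dimnames(x)),
        quote = FALSE)
  invisible(x)
}

#' Extract cells of a fuzzy matrix
#'
#' `fm_cells()` returns all cells (column-major); `fm_column()` one column;
#' `fm_cell()` a single cell.
#'
#' @param m A `fuzzy_matrix`.
#' @param i,j Row/column index or label.
#' @return A `tsfn`.
#' @export
fm_cells <- function(m) {
  stopifnot(is_fuzzy_matrix(m))
  tsfn(as.vector(m$a), as.vector(m$b), as.vector(m$c),
       as.vector(m$mu), as.vector(m$eta), as.vector(m$nu))
}

#' @rdname fm_cells
#' @export
fm_column <- function(m, j) {
  stopifnot(is_fuzzy_matrix(m))
  tsfn(m$a[, j], m$b[, j], m$c[, j], m$mu[, j], m$eta[, j], m$nu[, j])
}

#' @rdname fm_cells
#' @export
fm_cell <- function(m, i, j) {
  stopifnot(is_fuzzy_matrix(m))
  tsfn(m$a[i, j], m$b[i, j], m$c[i, j], m$mu[i, j], m$eta[i, j], m$nu[i, j])
}

#' Convert a fuzzy matrix to a long tibble
#'
#' @param m A `fuzzy_matrix`.
#' @return A tibble with columns `row`, `column`, `a` ... `nu`.
#' @export
fm_tbl <- function(m) {
  stopifnot(is_fuzzy_matrix(m))
  d <- dim(m); dn <- dimnames(m)
  rows <- if (is.null(dn[[1]])) as.character(seq_len(d[1])) else dn[[1]]
  cols <- if (is.null(dn[[2]])) as.character(seq_len(d[2])) else dn[[2]]
  tibble::tibble(row = rep(rows, times = d[2]),
                 column = rep(cols, each = d[1]),
                 tsfn_tbl(fm_cells(m)))
}

# coerce a user-supplied linguistic matrix (tibble with leading row-label
# column, character matrix, or data.frame) to a labelled character matrix
as_code_matrix <- function(m) {
  if (is.matrix(m)) {
    storage.mode(m) <- "character"
    return(m)
  }
  stopifnot(is.data.frame(m))
  lab <- as.character(m[[1]])
  out <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(out) <- "character"
  rownames(out) <- lab
  out
}

#' Fuzzify a linguistic matrix
#'
#' Replaces every term code with its scale TSFN.  Absent cells (the marker
#' `"-"` or `NA`, allowed on the diagonal of pairwise matrices) are
#' replaced by `diagonal_fill` (default: the zero element, which
#' defuzzifies to 0 and acts as the weakest assessment of its column).
#'
#' @param m A linguistic matrix: a tibble whose first column holds row
#'   labels (as read by [read_linguistic_csv()]) or a character matrix.
#' @param scale An [linguistic_scale()].
#' @param diagonal_fill A length-1 `tsfn` used for absent cells.
#' @return A [fuzzy_matrix()] with the term codes retained.
#' @export
fuzzify <- function(m, scale = default_scale(), diagonal_fill = tsfn_zero()) {
  codes <- as_code_matrix(m)
  absent <- is.na(codes) | codes == "-"
  vals <- tsfn_zero(length(codes))
  if (any(!absent)) {
    filled <- scale_value(scale, codes[!absent])
    idx <- which(!absent)
    for (f in c("a", "b", "c", "mu", "eta", "nu")) vals[[f]][idx] <- filled[[f]]
  }
  if (any(absent)) {
    idx <- which(absent)
    for (f in c("a", "b", "c", "mu", "eta", "nu")) {
      vals[[f]][idx] <- diagonal_fill[[f]][1]
    }
  }
  codes[absent] <- NA_character_
  fuzzy_matrix(vals, nrow(codes), dimnames = dimnames(codes), codes = codes)
}

# rebuild a fuzzy matrix from per-cell tsfn list-of-columns
fm_from_columns <- function(cols, dimnames = NULL, codes = NULL) {
  cells <- Reduce(c, cols)
  fuzzy_matrix(cells, length(cols[[1]]), dimnames = dimnames, codes = codes)
}

#' Read and write crisp matrices as CSV
#'
#' Crisp (defuzzified) matrices round-trip through CSV with full double
#' precision; the row labels travel in the first column.
#'
#' @param path File path.
#' @return A base matrix with dimnames.
#' @export
read_crisp_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(out) <- "double"
  rownames(out) <- as.character(tb[[1]])
  out
}

#' @rdname read_crisp_csv
#' @param m A numeric matrix with dimnames.
#' @export
write_crisp_csv <- function(m, path) {
  tb <- tibble::as_tibble(m, rownames = "row")
  readr::write_csv(tb, path)
  invisible(path)
}
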