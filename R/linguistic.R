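#' Linguistic scales
#'
#' A linguistic scale is an ordered mapping from term codes (`K0` ...
#' `K10`) to TSFNs.  The list order is the intended intensity order; it is
#' what min-max normalization uses to identify the weakest and strongest
#' assessment in a column.
#'
#' @param code Character vector of unique term codes, in intensity order.
#' @param label Character vector of human-readable labels.
#' @param value A `tsfn` vector of the same length.
#' @param source Free-text provenance note.
#' @return A tibble of class `appss_scale` with columns `code`, `label`,
#'   `a`, `b`, `c`, `mu`, `eta`, `nu`.
#' @export
linguistic_scale <- function(code, label, value, source = "") {
  stopifnot(is.character(code), !anyDuplicated(code), is_tsfn(value),
            length(code) == length(label), length(code) == length(value))
  out <- tibble::tibble(code = code, label = label, tsfn_tbl(value))
  structure(out, class = c("appss_scale", class(out)), source = source)
}

#' The eleven-term assessment scale of the case study
#'
#' Terms `K0` ("Ultra low") through `K10` ("Ultra high"), each valued by a
#' TSFN.  Values are stored exactly as published.  The published belonging
#' degree of `K1` (0.05) breaks the otherwise monotone decreasing pattern
#' of the low terms (0.95, ?, 0.85, 0.80, ...) and makes the score of `K1`
#' fall below both its neighbours; `correct_k1 = TRUE` restores the
#' pattern value 0.90.  The bundled COVID-19 case study uses the corrected
#' scale (see the methods vignette); the default returns the published
#' values unchanged.
#'
#' @param correct_k1 Restore the monotone belonging degree 0.90 for `K1`?
#' @return An [linguistic_scale()] tibble with 11 rows.
#' @export
#' @examples
#' default_scale()
default_scale <- function(correct_k1 = FALSE) {
  vals <- tsfn(
    a = c(0.00, 0.07, 0.18, 0.25, 0.29, 0.38, 0.50, 0.61, 0.73, 0.85, 0.95),
    b = c(0.05, 0.14, 0.22, 0.28, 0.36, 0.45, 0.56, 0.68, 0.83, 0.94, 0.985),
    c = c(0.10, 0.21, 0.26, 0.30, 0.43, 0.52, 0.62, 0.75, 0.88, 0.98, 1.00),
    mu = c(0.95, if (correct_k1) 0.90 else 0.05,
           0.85, 0.80, 0.70, 0.65, 0.55, 0.45, 0.25, 0.10, 0.05),
    eta = c(0.05, 0.10, 0.20, 0.30, 0.35, 0.40, 0.50, 0.40, 0.20, 0.10, 0.05),
    nu = c(0.10, 0.20, 0.25, 0.30, 0.40, 0.50, 0.60, 0.70, 0.75, 0.85, 0.95))
  linguistic_scale(
    code = paste0("K", 0:10),
    label = c("Ultra low", "Supreme low", "Very low", "Slightly low", "Low",
              "Intermediate", "High", "Slightly high", "Very high",
              "Supreme high", "Ultra high"),
    value = vals,
    source = "eleven-term TSFN assessment scale")
}

#' Look up scale terms as TSFNs
#'
#' @param scale An [linguistic_scale()].
#' @param codes Character vector of term codes.
#' @return A `tsfn` vector, one element per code.
#' @export
scale_value <- function(scale, codes) {
  idx <- match(codes, scale$code)
  if (anyNA(idx)) {
    stop("unknown term code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tsfn(scale$a[idx], scale$b[idx], scale$c[idx],
       scale$mu[idx], scale$eta[idx], scale$nu[idx])
}

#' Intensity rank of scale terms
#'
#' Position of each code in the scale's intensity order (1-based).
#'
#' @inheritParams scale_value
#' @return An integer vector.
#' @export
scale_rank <- function(scale, codes) {
  idx <- match(codes, scale$code)
  if (anyNA(idx)) {
    stop("unknown term code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Count-binning tables
#'
#' A bin table maps non-negative integer counts to scale terms.  The bins
#' must partition `[0, Inf)` with no gaps or overlaps: each lower bound is
#' one above the previous upper bound, the first lower bound is 0 and the
#' last upper bound is `Inf`.
#'
#' @param lower,upper Integer bin bounds (inclusive); the last `upper` may
#'   be `Inf`.
#' @param code Term code per bin, in intensity order.
#' @return A tibble of class `appss_bins`.
#' @export
bin_table <- function(lower, upper, code) {
  stopifnot(length(lower) == length(upper), length(lower) == length(code))
  if (lower[1] != 0) stop("first bin must start at 0", call. = FALSE)
  if (!is.infinite(upper[length(upper)])) {
    stop("last bin must be open-ended (upper = Inf)", call. = FALSE)
  }
  if (any(upper < lower)) stop("bin with upper < lower", call. = FALSE)
  n <- length(lower)
  if (n > 1 && any(lower[-1] != upper[-n] + 1)) {
    stop("bins must partition [0, Inf): each lower bound must be one above ",
         "the previous upper bound", call. = FALSE)
  }
  out <- tibble::tibble(lower = lower, upper = upper, code = code)
  structure(out, class = c("appss_bins", class(out)))
}

#' Case-count bins of the COVID-19 case study
#'
#' Counts up to 1000 are "Ultra low" (`K0`); the following bins are
#' 1001-25000 (`K1`), 25001-100000 (`K2`), 100001-250000 (`K3`),
#' 250001-500000 (`K4`), 500001-1000000 (`K5`), 1000001-2000000 (`K6`),
#' 2000001-3000000 (`K7`), 3000001-4000000 (`K8`), 4000001-5000000 (`K9`)
#' and above 5000000 (`K10`).  Counts are integers, so the published range
#' "1000 - 25000" is read lower-exclusive: 1000 still bins to `K0` and
#' 1001 starts `K1`.
#'
#' @return A [bin_table()].
#' @export
covid_bins <- function() {
  bin_table(
    lower = c(0, 1001, 25001, 100001, 250001, 500001,
              1000001, 2000001, 3000001, 4000001, 5000001),
    upper = c(1000, 25000, 100000, 250000, 500000, 1000000,
              2000000, 3000000, 4000000, 5000000, Inf),
    code = paste0("K", 0:10))
}

#' Bin counts into linguistic terms
#'
#' @param v Non-negative counts (vectorized).
#' @param bins A [bin_table()].
#' @return A character vector of term codes.
#' @export
#' @examples
#' bin_value(c(0, 1000, 1001, 25000, 25001), covid_bins())
bin_value <- function(v, bins = covid_bins()) {
  stopifnot(is.numeric(v))
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  bins$code[findInterval(v, bins$lower)]
}

#' Read and write linguistic matrices as CSV
#'
#' A linguistic matrix CSV has the column labels in the header, the row
#' labels in the first column, and term codes (or the absent marker `"-"`
#' for pairwise diagonals) in the cells.  Quantitative matrices use the
#' same layout with integer cells.
#'
#' @param path File path.
#' @return A tibble whose first column holds the row labels.
#' @export
read_linguistic_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @rdname read_linguistic_csv
#' @param m A tibble as returned by `read_linguistic_csv()`.
#' @export
write_linguistic_csv <- function(m, path) {
  readr::write_csv(m, path)
  invisible(path)
}

#' Scale and bin-table JSON round trips
#'
#' @param x An `appss_scale` or `appss_bins`.
#' @param path Optional output file.
#' @return JSON string, or (for the readers) the reconstructed object.
#' @export
write_scale_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "appss_scale"))
  obj <- list(source = attr(x, "source"),
              terms = purrr::pmap(as.list(x), function(code, label, a, b, c,
                                                       mu, eta, nu) {
                list(code = code, label = label,
                     value = list(a = a, b = b, c = c,
                                  mu = mu, eta = eta, nu = nu))
              }))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' @rdname write_scale_json
#' @param json JSON string or file path.
#' @export
read_scale_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  terms <- obj$terms
  linguistic_scale(
    code = vapply(terms, `[[`, character(1), "code"),
    label = vapply(terms, `[[`, character(1), "label"),
    value = tsfn(
      vapply(terms, function(t) t$value$a, numeric(1)),
      vapply(terms, function(t) t$value$b, numeric(1)),
      vapply(terms, function(t) t$value$c, numeric(1)),
      vapply(terms, function(t) t$value$mu, numeric(1)),
      vapply(terms, function(t) t$value$eta, numeric(1)),
      vapply(terms, function(t) t$value$nu, numeric(1))),
    source = if (is.null(obj$source)) "" else obj$source)
}

#' @rdname write_scale_json
#' @export
write_bins_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "appss_bins"))
  obj <- purrr::pmap(as.list(x), function(lower, upper, code) {
    list(lower = lower,
         upper = if (is.infinite(upper)) "Inf" else upper,
         code = code)
  })
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' @rdname write_scale_json
#' @export
read_bins_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  up <- vapply(obj, function(b) {
    if (identical(b$upper, "Inf")) Inf else as.numeric(b$upper)
  }, numeric(1))
  bin_table(lower = vapply(obj, function(b) as.numeric(b$lower), numeric(1)),
            upper = up,
            code = vapply(obj, `[[`, character(1), "code"))
}
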