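#' Column statistics of a fuzzy matrix
#'
#' Per column: the fuzzy mean ([tsfn_mean()] with `mean_divisor`, the
#' number of entries contributing to the column, diagonal fill included)
#' and the fuzzy standard deviation about it ([tsfn_sd()] with
#' `sd_divisor`, conventionally one less).
#'
#' @param m A [fuzzy_matrix()].
#' @param mean_divisor,sd_divisor Positive integers; default `nrow` and
#'   `nrow - 1`.
#' @param policy A [membership_policy()].
#' @return A list of class `fm_column_stats` with `tsfn` vectors `means`
#'   and `sds` (one element per column) and the divisors used.
#' @export
column_stats <- function(m, mean_divisor = nrow(m$a),
                         sd_divisor = max(1L, nrow(m$a) - 1L),
                         policy = default_policy()) {
  stopifnot(is_fuzzy_matrix(m), mean_divisor >= 1, sd_divisor >= 1)
  if (length(m$a) == 0) stop("empty matrix", call. = FALSE)
  g <- ncol(m$a)
  means <- vector("list", g)
  sds <- vector("list", g)
  for (j in seq_len(g)) {
    col <- fm_column(m, j)
    means[[j]] <- tsfn_mean(col, mean_divisor, policy)
    sds[[j]] <- tsfn_sd(col, means[[j]], sd_divisor, policy)
  }
  structure(list(means = Reduce(c, means), sds = Reduce(c, sds),
                 mean_divisor = mean_divisor, sd_divisor = sd_divisor),
            class = "fm_column_stats")
}

#' Standardize a fuzzy matrix by its column statistics
#'
#' Cellwise \eqn{(\tilde h - M) / SD} on the TSFN algebra: each cell has
#' its column mean subtracted ([tsfn_subtract()]) and is divided by the
#' column standard deviation ([tsfn_divide()]).  Total by construction:
#' the guarded membership ratios and the `clamp_eps` support guard make
#' degenerate columns (zero spread) well defined.
#'
#' @param m A [fuzzy_matrix()].
#' @param stats A [column_stats()] result matching `m`'s columns.
#' @param policy A [membership_policy()].
#' @return A [fuzzy_matrix()] (term codes carried through).
#' @export
standardize <- function(m, stats = column_stats(m), policy = default_policy()) {
  stopifnot(is_fuzzy_matrix(m), inherits(stats, "fm_column_stats"))
  g <- ncol(m$a)
  if (length(stats$means) != g) {
    stop("stats do not match the matrix columns", call. = FALSE)
  }
  cols <- lapply(seq_len(g), function(j) {
    tsfn_divide(tsfn_subtract(fm_column(m, j), stats$means[j], policy),
                stats$sds[j], policy)
  })
  fm_from_columns(cols, dimnames = dimnames(m), codes = attr(m, "codes"))
}

# locate extreme cells in a scope: by the intensity order of the
# originating term codes when available (absent cells rank lowest),
# otherwise by pairwise score comparison
locate_extremes <- function(cells, codes = NULL) {
  if (!is.null(codes)) {
    rk <- match(codes, unique_code_order(codes))
    rk[is.na(codes)] <- 0L
    return(list(imin = which.min(rk), imax = which.max(rk), rank = rk))
  }
  n <- length(cells)
  imin <- 1L; imax <- 1L
  for (i in seq_len(n)[-1]) {
    if (tsfn_compare(cells[i], cells[imin]) < 0) imin <- i
    if (tsfn_compare(cells[i], cells[imax]) > 0) imax <- i
  }
  list(imin = imin, imax = imax, rank = NULL)
}

# intensity order of codes of the form K<digits>; falls back to sorted
# unique codes for foreign scales
unique_code_order <- function(codes) {
  u <- unique(stats::na.omit(codes))
  num <- suppressWarnings(as.integer(sub("^K", "", u)))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Min-max normalize a fuzzy matrix
#'
#' Implements \eqn{(\tilde s - \min)/(\max - \min)} on the TSFN algebra.
#' Within each scope (column by default) the minimum and maximum cells are
#' located by the intensity order of the originating linguistic terms when
#' the matrix carries them (absent/diagonal cells rank below every term),
#' and otherwise by score comparison ([tsfn_compare()]).  Every cell tied
#' with the minimum maps to the zero element exactly -- this pins the
#' weakest assessment of a column at score 0; if the scope is degenerate
#' (max ties min) the whole scope maps to the zero element.
#'
#' @param m A [fuzzy_matrix()] (normally a [standardize()] output).
#' @param scope `"column"` (default) or `"matrix"`.
#' @param policy A [membership_policy()].
#' @return A [fuzzy_matrix()].
#' @export
minmax_normalize <- function(m, scope = c("column", "matrix"),
                             policy = default_policy()) {
  stopifnot(is_fuzzy_matrix(m))
  scope <- match.arg(scope)
  codes <- attr(m, "codes")
  Z <- tsfn_zero()
  norm_block <- function(cells, blk_codes) {
    ex <- locate_extremes(cells, blk_codes)
    lo <- cells[ex$imin]; hi <- cells[ex$imax]
    n <- length(cells)
    out <- tsfn_zero(n)
    degenerate <- if (!is.null(ex$rank)) {
      ex$rank[ex$imax] == ex$rank[ex$imin]
    } else tsfn_compare(hi, lo) == 0
    if (degenerate) return(out)
    rng <- tsfn_subtract(hi, lo, policy)
    is_min <- if (!is.null(ex$rank)) ex$rank == ex$rank[ex$imin] else
      vapply(seq_len(n), function(i) tsfn_compare(cells[i], lo) == 0, logical(1))
    for (i in seq_len(n)) {
      if (is_min[i]) next  # stays the zero element
      v <- tsfn_divide(tsfn_subtract(cells[i], lo, policy), rng, policy)
      for (f in c("a", "b", "c", "mu", "eta", "nu")) out[[f]][i] <- v[[f]]
    }
    out
  }
  if (scope == "matrix") {
    cells <- fm_cells(m)
    out <- norm_block(cells, if (is.null(codes)) NULL else as.vector(codes))
    return(fuzzy_matrix(out, nrow(m$a), dimnames = dimnames(m),
                        codes = codes))
  }
  cols <- lapply(seq_len(ncol(m$a)), function(j) {
    norm_block(fm_column(m, j), if (is.null(codes)) NULL else codes[, j])
  })
  fm_from_columns(cols, dimnames = dimnames(m), codes = codes)
}

#' Defuzzify a fuzzy matrix
#'
#' Cellwise [tsfn_score()].
#'
#' @param m A [fuzzy_matrix()].
#' @return A numeric matrix with the same dimnames.
#' @export
defuzzify <- function(m) {
  stopifnot(is_fuzzy_matrix(m))
  matrix(tsfn_score(fm_cells(m)), nrow(m$a), ncol(m$a),
         dimnames = dimnames(m))
}

#' Aggregate expert matrices
#'
#' Cellwise arithmetic mean of identically shaped crisp matrices, one per
#' expert.
#'
#' @param mats A list of numeric matrices with identical dimensions and
#'   dimnames.
#' @return A numeric matrix.
#' @export
aggregate_experts <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  d <- dim(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), d) ||
        !identical(dimnames(m), dimnames(mats[[1]]))) {
      stop("expert matrices must share shape and labels", call. = FALSE)
    }
  }
  Reduce(`+`, mats) / length(mats)
}

#' Crisp decision matrix from a linguistic matrix
#'
#' The pipeline stage shared by the preference and performance segments:
#' fuzzify, standardize per column, min-max normalize per column,
#' defuzzify.  Two stage conventions are offered:
#'
#' * `stage = "score"` (default): the scoring function is applied at the
#'   fuzzification stage and the column standardization
#'   (\eqn{(s - \bar s)/\mathrm{sd}}) and min-max normalization are
#'   ordinary arithmetic on the scores.  Because min-max absorbs any
#'   affine transform, the resulting cell value depends only on the
#'   cell's own term and the lowest/highest-scored terms present in its
#'   column -- equal codes in a column always map to equal values, and
#'   the lowest-scored assessment maps to exactly 0.
#' * `stage = "fuzzy"`: the full TSFN chain ([column_stats()],
#'   [standardize()], [minmax_normalize()]) runs on fuzzy numbers and the
#'   scoring function is applied last.  The guarded subtraction/division
#'   laws make this total but their clamping gives the stage different
#'   (and less interpretable) within-column orderings; see the methods
#'   vignette.
#'
#' @param m A linguistic matrix (tibble with leading row-label column, or
#'   character matrix); absent diagonal cells marked `"-"`.
#' @param scale An [linguistic_scale()].
#' @param stage `"score"` or `"fuzzy"`.
#' @param scope Min-max scope, `"column"` or `"matrix"`.
#' @param mean_divisor,sd_divisor Divisors for the column statistics;
#'   default: number of rows and one less.
#' @param policy A [membership_policy()].
#' @return A numeric matrix of defuzzified, normalized cell values.
#' @export
decision_matrix <- function(m, scale = default_scale(),
                            stage = c("score", "fuzzy"),
                            scope = c("column", "matrix"),
                            mean_divisor = NULL, sd_divisor = NULL,
                            policy = default_policy()) {
  stage <- match.arg(stage)
  scope <- match.arg(scope)
  fm <- fuzzify(m, scale)
  f <- nrow(fm$a)
  if (is.null(mean_divisor)) mean_divisor <- f
  if (is.null(sd_divisor)) sd_divisor <- max(1L, f - 1L)
  if (stage == "fuzzy") {
    st <- column_stats(fm, mean_divisor, sd_divisor, policy)
    return(defuzzify(minmax_normalize(standardize(fm, st, policy),
                                      scope, policy)))
  }
  s <- defuzzify(fm)
  normalize_scores(s, scope = scope, mean_divisor = mean_divisor,
                   sd_divisor = sd_divisor)
}

# crisp z-standardization + min-max; the z step cancels under min-max but
# is kept explicit so intermediate stages can be audited
normalize_scores <- function(s, scope = c("column", "matrix"),
                             mean_divisor = nrow(s),
                             sd_divisor = max(1L, nrow(s) - 1L)) {
  scope <- match.arg(scope)
  norm_vec <- function(v) {
    m <- sum(v) / mean_divisor
    sd <- sqrt(sum((v - m)^2) / sd_divisor)
    z <- if (sd > 0) (v - m) / sd else v * 0
    rng <- max(z) - min(z)
    if (rng <= 0) return(v * 0)
    (z - min(z)) / rng
  }
  if (scope == "matrix") {
    out <- norm_vec(as.vector(s))
    return(matrix(out, nrow(s), ncol(s), dimnames = dimnames(s)))
  }
  out <- apply(s, 2, norm_vec)
  dimnames(out) <- dimnames(s)
  out
}
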