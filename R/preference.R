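#' Criteria hierarchies
#'
#' Local (leaf) criteria are grouped under global criteria, e.g.
#' `list("COVID-positive" = c("C1", "C2"), Hospitalized = c("C3", "C4"),
#' Deaths = c("C5", "C6"))`.  The groups must partition the criteria.
#'
#' @param groups A named list of character vectors.
#' @return The validated list, classed `appss_hierarchy`.
#' @export
criteria_hierarchy <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  locals <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(locals)) {
    stop("each local criterion must belong to exactly one group",
         call. = FALSE)
  }
  structure(groups, class = "appss_hierarchy")
}

#' @rdname criteria_hierarchy
#' @param json JSON string or file path of the form
#'   `{"Deaths": ["C5", "C6"], ...}`.
#' @export
read_hierarchy_json <- function(json) {
  criteria_hierarchy(jsonlite::fromJSON(json, simplifyVector = TRUE))
}

#' @rdname criteria_hierarchy
#' @param h An `appss_hierarchy`.
#' @param path Optional output file.
#' @export
write_hierarchy_json <- function(h, path = NULL) {
  json <- jsonlite::toJSON(unclass(h), auto_unbox = FALSE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' Local criteria weights
#'
#' The raw weight of criterion `b` is the total preference it expresses
#' over the others: the sum of row `b` of the defuzzified pairwise
#' preference matrix, excluding the diagonal.
#'
#' @param q A square numeric matrix (defuzzified pairwise preferences,
#'   zero diagonal) with criteria labels as dimnames.
#' @return A named numeric vector.
#' @export
local_weights <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) != ncol(q)) stop("pairwise matrix must be square", call. = FALSE)
  diag(q) <- 0
  rowSums(q)
}

#' Global criteria weights
#'
#' Two conventions:
#' * `"group_sum"` (default): the global weight of a local criterion is
#'   the sum of the local weights over its group -- criteria in the same
#'   group share it;
#' * `"reciprocal"`: \eqn{GC(C_b) = \sum_b LC / LC(C_b)} (errors when any
#'   local weight is zero).
#'
#' The group-sum convention is the default because it reproduces the
#' published preference vector of the bundled case study to within its
#' rounding; the reciprocal form does not (see the methods vignette).
#'
#' @param lc Named numeric vector from [local_weights()].
#' @param hierarchy A [criteria_hierarchy()] covering the names of `lc`.
#' @param mode `"group_sum"` or `"reciprocal"`.
#' @return A named numeric vector aligned with `lc`.
#' @export
global_weights <- function(lc, hierarchy, mode = c("group_sum", "reciprocal")) {
  mode <- match.arg(mode)
  if (mode == "reciprocal") {
    if (any(lc == 0)) {
      stop("reciprocal global weights undefined: zero local weight",
           call. = FALSE)
    }
    return(sum(lc) / lc)
  }
  locals <- unlist(hierarchy, use.names = FALSE)
  if (!setequal(locals, names(lc))) {
    stop("hierarchy must cover exactly the local criteria", call. = FALSE)
  }
  gc <- lc
  for (grp in hierarchy) gc[grp] <- sum(lc[grp])
  gc
}

#' Blend local and global weights
#'
#' \eqn{(LC \cdot \alpha + GC \cdot (1-\alpha)) / 2}: `alpha = 1` weighs
#' only the local criteria, `alpha = 0` only the global groups.  The
#' division by two is retained from the published form; it cancels in the
#' final normalization.
#'
#' @param lc,gc Named numeric vectors.
#' @param alpha Blend parameter in `[0, 1]`.
#' @return A named numeric vector.
#' @export
overall_scores <- function(lc, gc, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  (lc * alpha + gc * (1 - alpha)) / 2
}

#' Normalized preference vector
#'
#' Normalizes the blended scores to sum to one and records the local and
#' global components for audit.
#'
#' @param overall Named numeric vector from [overall_scores()].
#' @param alpha The blend parameter used.
#' @param lc,gc Optional components for the audit trail.
#' @return A tibble of class `appss_preference` with columns `criterion`,
#'   `lc`, `gc`, `overall`, `weight`; attributes `alpha`.
#' @export
preference_vector <- function(overall, alpha = NA_real_, lc = NULL, gc = NULL) {
  if (sum(overall) <= 0) {
    stop("overall scores must have a positive sum", call. = FALSE)
  }
  w <- overall / sum(overall)
  out <- tibble::tibble(
    criterion = names(overall),
    lc = if (is.null(lc)) NA_real_ else unname(lc[names(overall)]),
    gc = if (is.null(gc)) NA_real_ else unname(gc[names(overall)]),
    overall = unname(overall),
    weight = unname(w))
  structure(out, class = c("appss_preference", class(out)), alpha = alpha)
}

#' Criteria preference analysis
#'
#' Runs the weighting segment from a defuzzified pairwise preference
#' matrix: local weights (off-diagonal row sums), global weights over the
#' hierarchy, alpha-blend, normalization.
#'
#' @param q Square defuzzified pairwise preference matrix.
#' @param hierarchy A [criteria_hierarchy()].
#' @param alpha Blend parameter in `[0, 1]` (default 0.5: equal local and
#'   global emphasis).
#' @param gc_mode Passed to [global_weights()].
#' @return An [preference_vector()] tibble.
#' @export
criteria_preference <- function(q, hierarchy, alpha = 0.5,
                                gc_mode = c("group_sum", "reciprocal")) {
  lc <- local_weights(q)
  gc <- global_weights(lc, hierarchy, match.arg(gc_mode))
  preference_vector(overall_scores(lc, gc, alpha), alpha = alpha,
                    lc = lc, gc = gc)
}

#' @method tidy appss_preference
#' @export
tidy.appss_preference <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance appss_preference
#' @export
glance.appss_preference <- function(x, ...) {
  tibble::tibble(n_criteria = nrow(x), alpha = attr(x, "alpha"),
                 weight_sum = sum(x$weight))
}

#' @export
print.appss_preference <- function(x, ...) {
  cat("Criteria preference vector (alpha = ", attr(x, "alpha"), ")\n",
      sep = "")
  NextMethod()
}

#' @method autoplot appss_preference
#' @export
autoplot.appss_preference <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$criterion,
                                                  -.data$weight),
                               y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "criterion", y = "normalized weight") +
    ggplot2::theme_minimal()
}
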