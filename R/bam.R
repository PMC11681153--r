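#' BAM configuration
#'
#' The bidirectional associative memory iteration alternates between the
#' alternative layer and the criterion layer of the crisp performance
#' matrix, squashing each activation through the sigmoid
#' \eqn{f(\hat x) = 1/(1 + e^{-\lambda \hat x})}.
#'
#' @param lambda Sigmoid steepness, positive.  Default 2: the smallest
#'   integer steepness that reproduces the published ordering of the
#'   bundled case study at every blend parameter (see the methods
#'   vignette); the ordering is stable for any steepness above about 1.2.
#' @param tol Convergence threshold on the infinity norm of successive
#'   state differences (both layers), default 0.001.
#' @param max_iter Iteration cap; exhaustion is reported as
#'   non-convergence, never silently.
#' @param y_normalization How the criterion-layer state is renormalized
#'   after each backward activation: `"sum_to_one"` (default; keeps the
#'   state commensurate with the seeding weight vector), `"max_to_one"`,
#'   or `"none"`.
#' @return A `bam_config` object.
#' @export
bam_config <- function(lambda = 2, tol = 0.001, max_iter = 100L,
                       y_normalization = c("sum_to_one", "max_to_one",
                                           "none")) {
  stopifnot(lambda > 0, tol > 0, max_iter >= 1)
  structure(list(lambda = lambda, tol = tol, max_iter = as.integer(max_iter),
                 y_normalization = match.arg(y_normalization)),
            class = "bam_config")
}

sigmoid <- function(x, lambda) 1 / (1 + exp(-lambda * x))

renormalize_y <- function(y, how) {
  switch(how,
         sum_to_one = y / sum(y),
         max_to_one = y / max(y),
         none = y)
}

#' BAM layer passes
#'
#' `bam_forward()` projects the criterion state onto the alternatives:
#' \eqn{\hat x_a = \sum_b y_b\, o_{ab}} followed by the sigmoid.
#' `bam_backward()` projects the alternative state back:
#' \eqn{\hat y_b = \sum_a x_a\, o_{ab}}, sigmoid, then the configured
#' renormalization.
#'
#' @param y,x Numeric state vectors over criteria / alternatives.
#' @param o Crisp performance matrix (alternatives by criteria).
#' @param config A [bam_config()].
#' @return A numeric vector (the updated layer state).
#' @export
bam_forward <- function(y, o, config = bam_config()) {
  o <- as.matrix(o)
  if (length(y) != ncol(o)) stop("state/criteria dimension mismatch",
                                 call. = FALSE)
  sigmoid(as.numeric(o %*% y), config$lambda)
}

#' @rdname bam_forward
#' @export
bam_backward <- function(x, o, config = bam_config()) {
  o <- as.matrix(o)
  if (length(x) != nrow(o)) stop("state/alternatives dimension mismatch",
                                 call. = FALSE)
  y <- sigmoid(as.numeric(crossprod(o, x)), config$lambda)
  renormalize_y(y, config$y_normalization)
}

#' Iterate the BAM to its fixed point
#'
#' Seeds the criterion layer with the preference vector and alternates
#' [bam_forward()] / [bam_backward()] until the infinity norms of both
#' successive state differences drop to `config$tol`, or `max_iter` is
#' reached (reported via `converged = FALSE`).  The full trajectory is
#' recorded.
#'
#' @param o Crisp performance matrix (alternatives by criteria, dimnames
#'   used as labels).
#' @param y0 Initial criterion weights: a numeric vector or an
#'   [preference_vector()] tibble.
#' @param config A [bam_config()].
#' @return A `bam_state`: list with elements `x`, `y`, `iterations`,
#'   `converged`, `trajectory` (long tibble), `config`.
#' @export
bam_iterate <- function(o, y0, config = bam_config()) {
  o <- as.matrix(o)
  if (inherits(y0, "appss_preference")) {
    y <- stats::setNames(y0$weight, y0$criterion)
    if (!is.null(colnames(o))) y <- y[colnames(o)]
  } else {
    y <- y0
  }
  if (length(y) != ncol(o) || anyNA(y)) {
    stop("seed weights do not align with the performance matrix columns",
         call. = FALSE)
  }
  alt <- if (is.null(rownames(o))) paste0("d", seq_len(nrow(o))) else
    rownames(o)
  crit <- if (is.null(colnames(o))) paste0("C", seq_len(ncol(o))) else
    colnames(o)
  traj <- list()
  x_prev <- NULL; y_prev <- NULL
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    x <- bam_forward(y, o, config)
    y_new <- bam_backward(x, o, config)
    traj[[it]] <- tibble::tibble(
      iteration = it,
      layer = c(rep("alternative", length(x)), rep("criterion",
                                                   length(y_new))),
      name = c(alt, crit),
      value = c(x, y_new))
    if (!is.null(x_prev) &&
        max(abs(x - x_prev)) <= config$tol &&
        max(abs(y_new - y_prev)) <= config$tol) {
      converged <- TRUE
      x_prev <- x; y_prev <- y_new
      break
    }
    x_prev <- x; y_prev <- y_new
    y <- y_new
  }
  structure(list(x = stats::setNames(x_prev, alt),
                 y = stats::setNames(y_prev, crit),
                 iterations = it, converged = converged,
                 trajectory = dplyr::bind_rows(traj), config = config),
            class = "bam_state")
}

#' Competition ranking of alternatives
#'
#' Descending by converged score; ties share the minimal rank and the
#' following rank is skipped (so scores `(3, 3, 1)` rank `(1, 1, 3)`).
#'
#' @param x Numeric scores (named).
#' @return An integer rank vector with the names of `x`.
#' @export
rank_alternatives <- function(x) {
  r <- vapply(x, function(s) 1L + sum(x > s), integer(1))
  stats::setNames(r, names(x))
}

#' @export
print.bam_state <- function(x, ...) {
  cat("<bam_state> ", if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iteration(s), lambda = ",
      x$config$lambda, "\n", sep = "")
  print(round(x$x, 4))
  invisible(x)
}

#' @method tidy bam_state
#' @export
tidy.bam_state <- function(x, ...) {
  tibble::tibble(alternative = names(x$x), score = unname(x$x),
                 rank = unname(rank_alternatives(x$x)))
}

#' @method glance bam_state
#' @export
glance.bam_state <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 lambda = x$config$lambda, tol = x$config$tol)
}

#' @method autoplot bam_state
#' @export
autoplot.bam_state <- function(object, ...) {
  dat <- dplyr::filter(object$trajectory, .data$layer == "alternative")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$iteration, y = .data$value,
                                    colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "iteration", y = "alternative state",
                  colour = "alternative") +
    ggplot2::theme_minimal()
}
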