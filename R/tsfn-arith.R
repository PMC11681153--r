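#' TSFN arithmetic
#'
#' The algebra of triangular spherical fuzzy numbers.  Supports combine by
#' interval arithmetic; membership degrees combine by the probabilistic
#' sum/product laws:
#'
#' * addition: support sums; \eqn{\mu_1 + \mu_2 - \mu_1\mu_2},
#'   \eqn{\eta_1\eta_2}, \eqn{\nu_1\nu_2};
#' * multiplication: support products; \eqn{\mu_1\mu_2} with probabilistic
#'   sums on \eqn{\eta} and \eqn{\nu};
#' * scalar multiple \eqn{\lambda x}: support scaled;
#'   \eqn{1-(1-\mu)^\lambda}, \eqn{\eta^\lambda}, \eqn{\nu^\lambda};
#' * power \eqn{x^\lambda}: componentwise support powers (re-sorted, since
#'   even powers can disorder sign-mixed supports; fractional powers floor
#'   negative components at 0); \eqn{\mu^\lambda} with complements on
#'   \eqn{\eta}, \eqn{\nu}.
#'
#' Subtraction and division are total functions: the membership ratios
#' \eqn{(\mu_1-\mu_2)/(1-\mu_2)}, \eqn{\eta_1/\eta_2}, ... are guarded
#' (`t/0 -> 1`, `0/0 -> 0`) and clamped to \eqn{[0,1]}, so the
#' standardization pipeline never fails even where the textbook side
#' conditions (e.g. \eqn{\mu_2 \ne 1}) cannot hold.  The division support is
#' the interval-arithmetic quotient \eqn{(a_1/c_2,\, b_1/b_2,\, c_1/a_2)}
#' with denominators below `clamp_eps` replaced by `clamp_eps`.
#'
#' All operations are vectorized and recycle their arguments.
#'
#' @param x,y `tsfn` vectors.
#' @param lambda A non-negative scalar (or vector) exponent/multiplier.
#' @param policy A [membership_policy()].
#' @return A `tsfn`.
#' @name tsfn-arith
NULL

#' @rdname tsfn-arith
#' @export
tsfn_add <- function(x, y, policy = default_policy()) {
  stopifnot(is_tsfn(x), is_tsfn(y))
  new_tsfn(x$a + y$a, x$b + y$b, x$c + y$c,
           x$mu + y$mu - x$mu * y$mu, x$eta * y$eta, x$nu * y$nu,
           policy)
}

#' @rdname tsfn-arith
#' @export
tsfn_multiply <- function(x, y, policy = default_policy()) {
  stopifnot(is_tsfn(x), is_tsfn(y))
  new_tsfn(x$a * y$a, x$b * y$b, x$c * y$c,
           x$mu * y$mu,
           x$eta + y$eta - x$eta * y$eta,
           x$nu + y$nu - x$nu * y$nu,
           policy)
}

#' @rdname tsfn-arith
#' @export
tsfn_scale <- function(lambda, x, policy = default_policy()) {
  stopifnot(is_tsfn(x), is.numeric(lambda), all(lambda >= 0))
  new_tsfn(lambda * x$a, lambda * x$b, lambda * x$c,
           1 - (1 - x$mu)^lambda, x$eta^lambda, x$nu^lambda,
           policy)
}

#' @rdname tsfn-arith
#' @export
tsfn_pow <- function(x, lambda, policy = default_policy()) {
  stopifnot(is_tsfn(x), is.numeric(lambda), all(lambda >= 0))
  a <- x$a; b <- x$b; cc <- x$c
  frac <- lambda != round(lambda)
  if (any(frac)) {
    neg <- a < 0 | b < 0 | cc < 0
    bad <- frac & neg
    if (any(bad)) {
      # fractional powers arise only through the fuzzy standard deviation,
      # where negative squared-deviation components are floored at zero
      a[bad] <- pmax(a[bad], 0); b[bad] <- pmax(b[bad], 0)
      cc[bad] <- pmax(cc[bad], 0)
    }
  }
  new_tsfn(a^lambda, b^lambda, cc^lambda,
           x$mu^lambda, 1 - (1 - x$eta)^lambda, 1 - (1 - x$nu)^lambda,
           policy)
}

#' @rdname tsfn-arith
#' @export
tsfn_subtract <- function(x, y, policy = default_policy()) {
  stopifnot(is_tsfn(x), is_tsfn(y))
  eps <- policy$clamp_eps
  new_tsfn(x$a - y$c, x$b - y$b, x$c - y$a,
           guarded_ratio(x$mu - y$mu, 1 - y$mu, eps),
           guarded_ratio(x$eta, y$eta, eps),
           guarded_ratio(x$nu, y$nu, eps),
           policy)
}

#' @rdname tsfn-arith
#' @export
tsfn_divide <- function(x, y, policy = default_policy()) {
  stopifnot(is_tsfn(x), is_tsfn(y))
  eps <- policy$clamp_eps
  den <- function(d) ifelse(abs(d) < eps, eps, d)
  new_tsfn(x$a / den(y$c), x$b / den(y$b), x$c / den(y$a),
           guarded_ratio(x$mu, y$mu, eps),
           guarded_ratio(x$eta - y$eta, 1 - y$eta, eps),
           guarded_ratio(x$nu - y$nu, 1 - y$nu, eps),
           policy)
}

#' Graded-mean-integration score of a TSFN
#'
#' The defuzzification used throughout the pipeline:
#' \deqn{2\left(\frac{a}{12} + \frac{b}{3} + \frac{c}{12}\right)
#'       \frac{\mu + \eta + \nu}{3}.}
#' The first factor is twice the graded mean of the triangular support
#' (weights 1:4:1); the second averages the total commitment of the three
#' membership degrees.  For valid scale terms the score lies in
#' \eqn{[-1, 1]}; compositions with supports outside \eqn{[0,1]} can exceed
#' that range, which is not enforced.
#'
#' @param x A `tsfn`.
#' @return A numeric vector of scores.
#' @export
#' @examples
#' tsfn_score(tsfn(0.38, 0.45, 0.52, 0.65, 0.40, 0.50))  # 0.2325
tsfn_score <- function(x) {
  stopifnot(is_tsfn(x))
  2 * (x$a / 12 + x$b / 3 + x$c / 12) * ((x$mu + x$eta + x$nu) / 3)
}

#' Compare two TSFNs by score
#'
#' Ordering by [tsfn_score()] with tolerance `1e-12`; exact score ties are
#' broken lexicographically on `(b, c, a, mu, nu, eta)` so that the
#' ordering is deterministic.
#'
#' @param x,y `tsfn` vectors (recycled).
#' @return An integer vector: `-1` (less), `0` (equal), `1` (greater).
#' @export
tsfn_compare <- function(x, y) {
  stopifnot(is_tsfn(x), is_tsfn(y))
  d <- tsfn_score(x) - tsfn_score(y)
  out <- sign(d)
  out[abs(d) <= 1e-12] <- 0
  tie <- out == 0
  if (any(tie)) {
    for (f in c("b", "c", "a", "mu", "nu", "eta")) {
      dd <- sign(rep_len(x[[f]], length(out)) - rep_len(y[[f]], length(out)))
      out[tie & out == 0] <- dd[tie & out == 0]
      tie <- tie & out == 0
      if (!any(tie)) break
    }
  }
  as.integer(out)
}

#' Weighted aggregation of TSFNs
#'
#' Supports combine by the weighted sum; degrees combine by
#' \eqn{\mu = 1 - \prod_i (1-\mu_i)^{w_i}}, \eqn{\eta = \prod_i
#' \eta_i^{w_i}}, \eqn{\nu = \prod_i \nu_i^{w_i}}.  The
#' exponent-on-complement convention makes the operator consistent with the
#' scalar-multiple law and idempotent: aggregating copies of the same value
#' with any weights returns that value.
#'
#' @param values A `tsfn` vector.
#' @param weights Non-negative weights of the same length, summing to 1
#'   (tolerance `1e-9`).
#' @param policy A [membership_policy()].
#' @return A length-1 `tsfn`.
#' @export
tsfn_aggregate <- function(values, weights, policy = default_policy()) {
  stopifnot(is_tsfn(values))
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  new_tsfn(sum(weights * values$a), sum(weights * values$b),
           sum(weights * values$c),
           1 - prod((1 - values$mu)^weights),
           prod(values$eta^weights),
           prod(values$nu^weights),
           policy)
}

tsfn_sum <- function(values, policy = default_policy()) {
  out <- values[1]
  if (length(values) > 1) {
    for (i in 2:length(values)) out <- tsfn_add(out, values[i], policy)
  }
  out
}

#' Fuzzy mean and standard deviation
#'
#' `tsfn_mean()` sums the values with [tsfn_add()] and scales by
#' `1/divisor`; the divisor is explicit because pairwise preference columns
#' are averaged over the number of criteria while performance columns are
#' averaged over the number of alternatives.  `tsfn_sd()` composes
#' subtraction, squaring, summation, scaling and the square root:
#' \eqn{\sqrt{\frac{1}{d}\sum_i (x_i - \bar x)^2}} on the TSFN algebra
#' (negative support components are floored at zero before the root).
#'
#' @param values A `tsfn` vector (non-empty).
#' @param center The reference TSFN the deviations are taken from.
#' @param divisor A positive integer.
#' @param policy A [membership_policy()].
#' @return A length-1 `tsfn`.
#' @export
tsfn_mean <- function(values, divisor = length(values),
                      policy = default_policy()) {
  stopifnot(is_tsfn(values), length(values) >= 1, divisor >= 1)
  tsfn_scale(1 / divisor, tsfn_sum(values, policy), policy)
}

#' @rdname tsfn_mean
#' @export
tsfn_sd <- function(values, center, divisor = length(values) - 1,
                    policy = default_policy()) {
  stopifnot(is_tsfn(values), length(values) >= 1, is_tsfn(center),
            divisor >= 1)
  devs <- lapply(seq_len(length(values)), function(i) {
    tsfn_pow(tsfn_subtract(values[i], center, policy), 2, policy)
  })
  total <- Reduce(function(u, v) tsfn_add(u, v, policy), devs)
  tsfn_pow(tsfn_scale(1 / divisor, total, policy), 0.5, policy)
}

#' @export
Ops.tsfn <- function(e1, e2) {
  if (nargs() == 1L) stop("unary ", .Generic, " is not defined for tsfn")
  switch(.Generic,
    "+" = tsfn_add(e1, e2),
    "-" = tsfn_subtract(e1, e2),
    "*" = {
      if (is.numeric(e1)) tsfn_scale(e1, e2)
      else if (is.numeric(e2)) tsfn_scale(e2, e1)
      else tsfn_multiply(e1, e2)
    },
    "/" = tsfn_divide(e1, e2),
    "^" = tsfn_pow(e1, e2),
    "==" = tsfn_compare(e1, e2) == 0L,
    "<" = tsfn_compare(e1, e2) < 0L,
    ">" = tsfn_compare(e1, e2) > 0L,
    stop(.Generic, " is not defined for tsfn")
  )
}
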