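#' Membership policy for triangular spherical fuzzy numbers
#'
#' A TSFN carries three membership degrees (belonging \eqn{\varrho}, neutral
#' \eqn{\varsigma}, non-belonging \eqn{\xi}) constrained by
#' \eqn{\varrho^2 + \varsigma^2 + \xi^2 \le 1}.  Compositions of the
#' arithmetic laws can violate that sphere constraint (for example the
#' product of two valid scale terms), and the subtraction/division laws can
#' push individual degrees outside \eqn{[0, 1]}.  The policy decides how
#' such violations are handled:
#'
#' * `"allow"` (default): degrees are clamped to \eqn{[0, 1]} but the sphere
#'   excess is stored, retrievable with [sphere_excess()];
#' * `"scale"`: when the squared sum exceeds 1 the three degrees are rescaled
#'   by \eqn{1/\sqrt{\varrho^2+\varsigma^2+\xi^2}};
#' * `"strict"`: a violation is an error.
#'
#' `clamp_eps` guards divisions: a denominator with absolute value below
#' `clamp_eps` is treated as zero (membership ratios) or replaced by
#' `clamp_eps` (support ratios).
#'
#' @param mode One of `"allow"`, `"scale"`, `"strict"`.
#' @param clamp_eps Positive guard threshold, at most `1e-6`.
#' @return A `membership_policy` object.
#' @export
#' @examples
#' membership_policy("scale")
membership_policy <- function(mode = c("allow", "scale", "strict"),
                              clamp_eps = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(clamp_eps), length(clamp_eps) == 1,
            clamp_eps > 0, clamp_eps <= 1e-6)
  structure(list(mode = mode, clamp_eps = clamp_eps),
            class = "membership_policy")
}

#' @export
print.membership_policy <- function(x, ...) {
  cat("<membership_policy> mode =", x$mode, ", clamp_eps =", x$clamp_eps, "\n")
  invisible(x)
}

default_policy <- function() membership_policy("allow")

clamp01 <- function(x) pmin(1, pmax(0, x))

# guarded ratio used by the subtraction/division membership laws:
# t/0 -> 1 (then clamped), 0/0 -> 0; broadcasts to the common length
guarded_ratio <- function(num, den, eps) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  ifelse(abs(den) < eps,
         ifelse(abs(num) < eps, 0, 1),
         num / den)
}

#' Construct triangular spherical fuzzy numbers
#'
#' A triangular spherical fuzzy number (TSFN) is a triangular support
#' `(a, b, c)` with `a <= b <= c` (left spread, mode, right spread)
#' together with spherical membership degrees `mu` (belonging), `eta`
#' (neutral) and `nu` (non-belonging).  All six arguments are vectorized
#' and recycled to a common length.  Supports are re-sorted so that
#' `a <= b <= c`; membership degrees are clamped to `[0, 1]` and the
#' sphere constraint is enforced according to `policy`.
#'
#' @param a,b,c Numeric vectors, the triangular support.
#' @param mu,eta,nu Numeric vectors, the membership degrees.
#' @param policy A [membership_policy()].
#' @return A vectorized object of class `tsfn`.
#' @export
#' @examples
#' k5 <- tsfn(0.38, 0.45, 0.52, 0.65, 0.40, 0.50)
#' tsfn_score(k5)
tsfn <- function(a, b, c, mu, eta, nu, policy = default_policy()) {
  n <- max(length(a), length(b), length(c), length(mu), length(eta), length(nu))
  a <- rep_len(as.double(a), n); b <- rep_len(as.double(b), n)
  c <- rep_len(as.double(c), n)
  mu <- rep_len(as.double(mu), n); eta <- rep_len(as.double(eta), n)
  nu <- rep_len(as.double(nu), n)
  if (!all(is.finite(c(a, b, c, mu, eta, nu)))) {
    stop("tsfn components must be finite", call. = FALSE)
  }
  new_tsfn(a, b, c, mu, eta, nu, policy)
}

# internal constructor: sorts the support, applies the membership policy
new_tsfn <- function(a, b, c, mu, eta, nu, policy = default_policy()) {
  n <- max(length(a), length(b), length(c), length(mu), length(eta),
           length(nu))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  mu <- rep_len(mu, n); eta <- rep_len(eta, n); nu <- rep_len(nu, n)
  lo <- pmin(a, b, c)
  hi <- pmax(a, b, c)
  mid <- a + b + c - lo - hi
  mu <- clamp01(mu); eta <- clamp01(eta); nu <- clamp01(nu)
  sq <- mu^2 + eta^2 + nu^2
  over <- sq > 1 + 1e-12
  if (any(over)) {
    if (policy$mode == "strict") {
      stop("sphere constraint violated (mu^2 + eta^2 + nu^2 > 1) under strict policy",
           call. = FALSE)
    }
    if (policy$mode == "scale") {
      f <- ifelse(over, 1 / sqrt(sq), 1)
      mu <- mu * f; eta <- eta * f; nu <- nu * f
    }
  }
  structure(list(a = lo, b = mid, c = hi, mu = mu, eta = eta, nu = nu),
            class = "tsfn")
}

#' The zero element
#'
#' `((0, 0, 0); 0, 0, 1)`: the additive identity on supports, used as the
#' diagonal fill of pairwise preference matrices and as the image of
#' minimum cells under min-max normalization.  Its score is 0.
#'
#' @param n Number of copies.
#' @return A `tsfn` of length `n`.
#' @export
tsfn_zero <- function(n = 1L) {
  tsfn(rep(0, n), 0, 0, 0, 0, 1)
}

#' @export
is_tsfn <- function(x) inherits(x, "tsfn")

#' @export
length.tsfn <- function(x) length(x$a)

#' @export
`[.tsfn` <- function(x, i) {
  structure(list(a = x$a[i], b = x$b[i], c = x$c[i],
                 mu = x$mu[i], eta = x$eta[i], nu = x$nu[i]),
            class = "tsfn")
}

#' @export
c.tsfn <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, is_tsfn, logical(1))))
  structure(
    list(a = unlist(lapply(parts, `[[`, "a")),
         b = unlist(lapply(parts, `[[`, "b")),
         c = unlist(lapply(parts, `[[`, "c")),
         mu = unlist(lapply(parts, `[[`, "mu")),
         eta = unlist(lapply(parts, `[[`, "eta")),
         nu = unlist(lapply(parts, `[[`, "nu"))),
    class = "tsfn")
}

#' @export
format.tsfn <- function(x, digits = 4, ...) {
  sprintf("((%.*g, %.*g, %.*g); %.*g, %.*g, %.*g)",
          digits, x$a, digits, x$b, digits, x$c,
          digits, x$mu, digits, x$eta, digits, x$nu)
}

#' @export
print.tsfn <- function(x, ...) {
  cat("<tsfn[", length(x), "]>\n", sep = "")
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.tsfn <- function(x, ...) {
  data.frame(a = x$a, b = x$b, c = x$c, mu = x$mu, eta = x$eta, nu = x$nu)
}

#' Convert a TSFN vector to a tibble
#'
#' @param x A `tsfn`.
#' @param ... Unused.
#' @return A tibble with columns `a`, `b`, `c`, `mu`, `eta`, `nu`.
#' @export
tsfn_tbl <- function(x, ...) {
  stopifnot(is_tsfn(x))
  tibble::tibble(a = x$a, b = x$b, c = x$c, mu = x$mu, eta = x$eta, nu = x$nu)
}

#' Sphere excess and refusal degree
#'
#' `sphere_excess()` returns \eqn{\mu^2+\eta^2+\nu^2 - 1} (positive values
#' indicate a violation stored under the `"allow"` policy);  `refusal()`
#' returns \eqn{\sqrt{\max(0, 1 - (\mu^2+\eta^2+\nu^2))}}, the residual
#' commitment not assigned to the three degrees.
#'
#' @param x A `tsfn`.
#' @return A numeric vector.
#' @export
sphere_excess <- function(x) {
  stopifnot(is_tsfn(x))
  x$mu^2 + x$eta^2 + x$nu^2 - 1
}

#' @rdname sphere_excess
#' @export
refusal <- function(x) {
  stopifnot(is_tsfn(x))
  sqrt(pmax(0, -sphere_excess(x)))
}

#' Serialize TSFNs to and from JSON
#'
#' Round-trips exactly: components are written as decimal strings with full
#' double precision.
#'
#' @param x A `tsfn`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `tsfn_to_json()`: a JSON string (invisibly, when writing to a
#'   file); `tsfn_from_json()`: a `tsfn`.
#' @export
tsfn_to_json <- function(x, path = NULL) {
  stopifnot(is_tsfn(x))
  # 17 significant digits round-trip any double exactly
  recs <- purrr::pmap(unclass(x), function(a, b, c, mu, eta, nu) {
    list(a = sprintf("%.17g", a), b = sprintf("%.17g", b),
         c = sprintf("%.17g", c), mu = sprintf("%.17g", mu),
         eta = sprintf("%.17g", eta), nu = sprintf("%.17g", nu))
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname tsfn_to_json
#' @param json A JSON string or file path produced by `tsfn_to_json()`.
#' @export
tsfn_from_json <- function(json) {
  recs <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  tsfn(as.numeric(recs$a), as.numeric(recs$b), as.numeric(recs$c),
       as.numeric(recs$mu), as.numeric(recs$eta), as.numeric(recs$nu))
}
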