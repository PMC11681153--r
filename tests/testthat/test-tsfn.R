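test_that("constructor sorts supports, clamps degrees and applies the policy", {
  # valid scale term stored unchanged (squared degree sum 0.8325)
  x <- tsfn(0.38, 0.45, 0.52, 0.65, 0.40, 0.50)
  expect_equal(c(x$a, x$b, x$c), c(0.38, 0.45, 0.52))
  expect_equal(c(x$mu, x$eta, x$nu), c(0.65, 0.40, 0.50))
  expect_lt(sphere_excess(x), 0)

  # disordered support is re-sorted
  y <- tsfn(0.23, 0.09, -0.05, 0, 1, 1)
  expect_equal(c(y$a, y$b, y$c), c(-0.05, 0.09, 0.23))

  # scale policy rescales an over-sphere degree triple by 1/sqrt(sum sq)
  sq <- 0.455^2 + 0.61^2 + 0.70^2
  z <- tsfn(0.11, 0.16, 0.22, 0.455, 0.61, 0.70,
            policy = membership_policy("scale"))
  expect_equal(z$mu, 0.455 / sqrt(sq))
  expect_equal(z$eta, 0.61 / sqrt(sq))
  expect_equal(sphere_excess(z), 0, tolerance = 1e-12)

  expect_error(tsfn(0.1, 0.2, 0.3, 0.455, 0.61, 0.70,
                    policy = membership_policy("strict")),
               "sphere")
  expect_error(tsfn(NaN, 0, 0, 0, 0, 0), "finite")

  # refusal complements the sphere
  expect_equal(refusal(tsfn(0, 0, 0, 0.6, 0, 0.8)), 0)
  expect_equal(refusal(tsfn(0, 0, 0, 0, 0, 0)), 1)
})

test_that("addition follows the probabilistic-sum law", {
  s <- tsfn_add(K(4), K(5))
  expect_tsfn_equal(s, tsfn(0.67, 0.81, 0.95, 0.895, 0.14, 0.20))

  # zero element: neutral on the support, annihilates eta, keeps nu
  x <- K(6)
  xz <- tsfn_add(x, Z)
  expect_equal(c(xz$a, xz$b, xz$c), c(x$a, x$b, x$c))
  expect_equal(xz$mu, x$mu)
  expect_equal(xz$eta, 0)
  expect_equal(xz$nu, x$nu)

  # doubling equals the scalar law
  expect_tsfn_equal(tsfn_add(K(4), K(4)),
                    tsfn(0.58, 0.72, 0.86, 0.91, 0.1225, 0.16))
  expect_tsfn_equal(tsfn_add(K(4), K(4)), tsfn_scale(2, K(4)))
})

test_that("multiplication, scalar multiple and power match the laws", {
  p <- tsfn_multiply(K(4), K(5))
  expect_tsfn_equal(p, tsfn(0.1102, 0.162, 0.2236, 0.455, 0.61, 0.70))
  expect_equal(sphere_excess(p), 0.069125, tolerance = 1e-9)

  one <- tsfn(1, 1, 1, 1, 0, 0)
  expect_tsfn_equal(tsfn_multiply(K(7), one), K(7))
  zx <- tsfn_multiply(Z, K(7))
  expect_equal(c(zx$a, zx$b, zx$c), c(0, 0, 0))

  h <- tsfn_scale(0.5, K(4))
  expect_tsfn_equal(h, tsfn(0.145, 0.18, 0.215,
                            1 - sqrt(0.3), sqrt(0.35), sqrt(0.4)))
  expect_tsfn_equal(tsfn_scale(1, K(9)), K(9))

  sq <- tsfn_pow(K(4), 2)
  expect_tsfn_equal(sq, tsfn(0.0841, 0.1296, 0.1849, 0.49, 0.5775, 0.64))
  expect_tsfn_equal(tsfn_pow(K(3), 1), K(3))
  # even powers of sign-mixed supports re-sort ascending
  neg <- tsfn(-0.05, 0.09, 0.23, 0.5, 0.5, 0.5)
  nsq <- tsfn_pow(neg, 2)
  expect_equal(c(nsq$a, nsq$b, nsq$c), c(0.0025, 0.0081, 0.0529))
  expect_error(tsfn_scale(-1, K(4)))
})

test_that("subtraction and division are total with guarded, clamped ratios", {
  d <- tsfn_subtract(K(5), K(4))
  expect_equal(c(d$a, d$b, d$c), c(-0.05, 0.09, 0.23))
  expect_equal(c(d$mu, d$eta, d$nu), c(0, 1, 1))  # -0.1667, 1.143, 1.25 clamp

  # subtracting the zero element: support unchanged, eta ratio guarded to 1
  x <- K(6)
  xz <- tsfn_subtract(x, Z)
  expect_equal(c(xz$a, xz$b, xz$c), c(x$a, x$b, x$c))
  expect_equal(xz$mu, x$mu)
  expect_equal(xz$eta, 1)
  expect_equal(xz$nu, x$nu)

  xx <- tsfn_subtract(x, x)
  expect_equal(c(xx$a, xx$b, xx$c), c(x$a - x$c, 0, x$c - x$a))
  expect_equal(c(xx$mu, xx$eta, xx$nu), c(0, 1, 1))

  q <- tsfn_divide(K(5), K(4))
  expect_equal(c(q$a, q$b, q$c), c(0.38 / 0.43, 0.45 / 0.36, 0.52 / 0.29))
  expect_equal(q$mu, 0.65 / 0.70)
  expect_equal(q$eta, (0.40 - 0.35) / 0.65)
  expect_equal(q$nu, (0.50 - 0.40) / 0.60)

  xq <- tsfn_divide(x, x)
  expect_equal(c(xq$a, xq$b, xq$c), c(x$a / x$c, 1, x$c / x$a))
  expect_equal(c(xq$mu, xq$eta, xq$nu), c(1, 0, 0))

  zq <- tsfn_divide(Z, K(4))
  expect_equal(tsfn_score(zq), 0)
})

test_that("score is the graded-mean integration value", {
  expect_equal(tsfn_score(K(5)), 0.2325)
  expect_equal(tsfn_score(Z), 0)
  expect_equal(tsfn_score(tsfn(1, 1, 1, 0.5, 0.5, 0.5)), 0.5)
  # zero iff the graded mean or the degree sum vanishes
  expect_equal(tsfn_score(tsfn(-0.3, 0.05, 0.1, 0.9, 0.1, 0.1)), 0)
  expect_equal(tsfn_score(tsfn(0.2, 0.3, 0.4, 0, 0, 0)), 0)
})

test_that("comparison orders by score with a deterministic tie-break", {
  expect_equal(tsfn_score(K(6)), 0.308)
  expect_equal(tsfn_score(K(4)), 0.174)
  expect_equal(tsfn_compare(K(6), K(4)), 1L)
  expect_equal(tsfn_compare(K(4), K(4)), 0L)
  expect_equal(tsfn_compare(Z, K(0)), -1L)
  # equal scores, different mode: lexicographic tie-break on b
  lo <- tsfn(0, 0.25, 0.5, 0.4, 0.4, 0.4)
  hi <- tsfn(0.06, 0.26, 0.40, 0.4, 0.4, 0.4)  # same graded mean 0.25
  expect_equal(tsfn_score(lo), tsfn_score(hi))
  expect_equal(tsfn_compare(lo, hi), -1L)
  expect_equal(tsfn_compare(hi, lo), 1L)
})

test_that("weighted aggregation is idempotent and matches the displayed law", {
  ag <- tsfn_aggregate(c(K(4), K(5)), c(0.5, 0.5))
  expect_tsfn_equal(ag, tsfn(0.335, 0.405, 0.475,
                             1 - sqrt(0.3 * 0.35), sqrt(0.35 * 0.4),
                             sqrt(0.4 * 0.5)))
  expect_tsfn_equal(tsfn_aggregate(K(7), 1), K(7))
  x <- K(3)
  expect_tsfn_equal(tsfn_aggregate(c(x, x, x), rep(1 / 3, 3)), x)
  expect_error(tsfn_aggregate(c(K(1), K(2)), c(0.5, 0.6)), "sum to 1")
  expect_error(tsfn_aggregate(c(K(1), K(2)), 1), "equal length")
})

test_that("fuzzy mean recovers constants and the fixture column value", {
  expect_tsfn_equal(tsfn_mean(K(4), 1), K(4))
  expect_tsfn_equal(tsfn_mean(c(K(4), K(4)), 2), K(4))
  # pairwise-preference column C2: terms K4, Z, K5, K4, K4, K4 over 6
  m <- tsfn_mean(c(K(4), Z, K(5), K(4), K(4), K(4)), 6)
  expect_equal(c(m$a, m$b, m$c), c(0.2567, 0.3150, 0.3733), tolerance = 1e-4)
})

test_that("fuzzy standard deviation is symmetric and vanishes for flat data", {
  flat <- tsfn(0.3, 0.3, 0.3, 0.6, 0.3, 0.3)
  s0 <- tsfn_sd(c(flat, flat), flat, 1)
  expect_equal(c(s0$a, s0$b, s0$c), c(0, 0, 0))
  # symmetry of squared deviations under argument order
  center <- tsfn_mean(c(K(2), K(6)), 2)
  s1 <- tsfn_sd(c(K(2), K(6)), center, 1)
  s2 <- tsfn_sd(c(K(6), K(2)), center, 1)
  expect_tsfn_equal(s1, s2)
  # a spread column has strictly positive dispersion at the mode
  col <- c(Z, K(5), K(6), K(6), K(7), K(6))
  s <- tsfn_sd(col, tsfn_mean(col, 6), 5)
  expect_gt(s$b, 0)
})

test_that("algebraic property suite holds on random inputs", {
  withr::with_seed(42, {
    x <- random_tsfn(25); y <- random_tsfn(25); z <- random_tsfn(25)
    # commutativity and associativity of addition
    expect_tsfn_equal(tsfn_add(x, y), tsfn_add(y, x), tol = 1e-12)
    expect_tsfn_equal(tsfn_add(tsfn_add(x, y), z),
                      tsfn_add(x, tsfn_add(y, z)), tol = 1e-12)
    # n-fold addition equals the scalar law for integer n
    for (n in 2:5) {
      acc <- x
      for (k in seq_len(n - 1)) acc <- tsfn_add(acc, x)
      expect_tsfn_equal(acc, tsfn_scale(n, x), tol = 1e-9)
    }
    # totality: subtraction and division never error, degrees stay in [0,1]
    for (op in list(tsfn_subtract, tsfn_divide)) {
      r <- op(x, y)
      expect_true(all(r$mu >= 0 & r$mu <= 1))
      expect_true(all(r$eta >= 0 & r$eta <= 1))
      expect_true(all(r$nu >= 0 & r$nu <= 1))
      expect_true(all(r$a <= r$b & r$b <= r$c))
    }
    # aggregation of m copies with equal weights is the identity
    for (m in c(2L, 4L)) {
      xi <- x[1]
      expect_tsfn_equal(tsfn_aggregate(do.call(c, rep(list(xi), m)),
                                       rep(1 / m, m)), xi, tol = 1e-9)
    }
    # score is linear in the support for fixed degrees
    base <- tsfn(0.2, 0.4, 0.9, 0.5, 0.3, 0.2)
    scaled <- tsfn(3 * 0.2, 3 * 0.4, 3 * 0.9, 0.5, 0.3, 0.2)
    expect_equal(tsfn_score(scaled), 3 * tsfn_score(base))
  })
})

test_that("JSON serialization round-trips bit-exactly", {
  withr::with_seed(7, x <- random_tsfn(5))
  path <- withr::local_tempfile(fileext = ".json")
  tsfn_to_json(x, path)
  y <- tsfn_from_json(path)
  expect_identical(unclass(x), unclass(y))
})

test_that("operator sugar dispatches to the laws", {
  expect_tsfn_equal(K(4) + K(5), tsfn_add(K(4), K(5)))
  expect_tsfn_equal(2 * K(4), tsfn_scale(2, K(4)))
  expect_tsfn_equal(K(4)^2, tsfn_pow(K(4), 2))
  expect_true(K(6) > K(4))
})
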