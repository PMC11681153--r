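# scale terms used throughout the tests
SC <- default_scale()
K <- function(i) scale_value(SC, paste0("K", i))
Z <- tsfn_zero()

# random valid TSFNs for property tests (supports in [-1, 2], degrees on
# the sphere cap)
random_tsfn <- function(n) {
  tri <- matrix(stats::runif(3 * n, -1, 2), ncol = 3)
  ang1 <- stats::runif(n, 0, pi / 2)
  ang2 <- stats::runif(n, 0, pi / 2)
  r <- stats::runif(n)^(1 / 3)
  tsfn(tri[, 1], tri[, 2], tri[, 3],
       r * cos(ang1), r * sin(ang1) * cos(ang2), r * sin(ang1) * sin(ang2))
}

expect_tsfn_equal <- function(x, y, tol = 1e-9) {
  for (f in c("a", "b", "c", "mu", "eta", "nu")) {
    expect_equal(x[[f]], y[[f]], tolerance = tol, ignore_attr = TRUE)
  }
}

# the published converged alternative scores of the case study
printed_x <- c(d1 = 0.500, d2 = 0.532, d3 = 0.562, d4 = 0.593, d5 = 0.605,
               d6 = 0.599, d7 = 0.616, d8 = 0.618, d9 = 0.584, d10 = 0.535,
               d11 = 0.522)
printed_rb <- c(11L, 9L, 7L, 5L, 3L, 4L, 2L, 1L, 6L, 8L, 10L)
printed_w <- c(C1 = 0.149, C2 = 0.142, C3 = 0.189, C4 = 0.193, C5 = 0.168,
               C6 = 0.159)
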