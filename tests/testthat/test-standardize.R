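test_that("column statistics use the explicit divisors", {
  # constant column: mean keeps the support, dispersion has zero mode
  codes <- matrix("K4", 4, 1, dimnames = list(paste0("d", 1:4), "C1"))
  st <- column_stats(fuzzify(codes), mean_divisor = 4, sd_divisor = 3)
  expect_equal(c(st$means$a, st$means$b, st$means$c), c(0.29, 0.36, 0.43))
  # the dispersion of a constant column reflects only the support spread:
  # its left component vanishes and mode equals right spread
  expect_equal(st$sds$a, 0, tolerance = 1e-12)
  expect_equal(st$sds$b, st$sds$c)

  # fixture pairwise column C2 (K4, -, K5, K4, K4, K4) over divisor 6
  plpm <- fuzzify(appss_fixture("covid-india-plpm"))
  st6 <- column_stats(plpm, mean_divisor = 6, sd_divisor = 5)
  m2 <- st6$means[2]
  expect_equal(c(m2$a, m2$b, m2$c), c(0.2567, 0.3150, 0.3733),
               tolerance = 1e-4)
  expect_equal(st6$mean_divisor, 6)
  expect_equal(st6$sd_divisor, 5)
  expect_error(column_stats(plpm, mean_divisor = 0))
})

test_that("fuzzy standardization maps a cell at its column mean to zero score", {
  codes <- matrix(c("K4", "K4", "K4", "K2", "K4", "K6"), 3, 2,
                  dimnames = list(paste0("d", 1:3), c("C1", "C2")))
  fm <- fuzzify(codes)
  std <- standardize(fm)
  # constant column: every standardized cell defuzzifies to 0
  expect_equal(defuzzify(std)[, "C1"], c(d1 = 0, d2 = 0, d3 = 0))
  # spread column: the cell above the mean scores above the cell below
  s2 <- defuzzify(std)[, "C2"]
  expect_gt(s2[["d3"]], s2[["d1"]])
})

test_that("fuzzy min-max sends minimum-intensity cells to the zero element", {
  plpm <- fuzzify(appss_fixture("covid-india-plpm"))
  nm <- minmax_normalize(standardize(plpm))
  o <- defuzzify(nm)
  # the diagonal fill is the weakest cell of each column -> exactly 0
  expect_equal(unname(diag(o)), rep(0, 6))
  # minimum cells become the zero element itself
  expect_tsfn_equal(fm_cell(nm, "C1", "C1"), tsfn_zero())
  # equal codes within a column map to identical values
  expect_equal(o["C4", "C1"], o["C3", "C1"])  # both K6
  # degenerate scope: a constant column collapses to the zero element
  const <- fuzzify(matrix("K5", 3, 1))
  expect_equal(unname(defuzzify(minmax_normalize(standardize(const)))),
               matrix(0, 3, 1))
})

test_that("defuzzification is the cellwise score", {
  plpm <- fuzzify(appss_fixture("covid-india-plpm"))
  o <- defuzzify(plpm)
  expect_equal(o["C1", "C2"], tsfn_score(scale_value(default_scale(), "K4")))
  expect_equal(o["C2", "C1"], 0.2325)  # K5 before any normalization
  expect_equal(unname(diag(o)), rep(0, 6))
})

test_that("expert aggregation averages cellwise and is order-invariant", {
  a <- matrix(0, 2, 2); b <- matrix(1, 2, 2)
  expect_equal(aggregate_experts(list(a)), a)
  expect_equal(aggregate_experts(list(a, b)), matrix(0.5, 2, 2))
  withr::with_seed(5, {
    ms <- replicate(3, matrix(stats::runif(4), 2, 2), simplify = FALSE)
    expect_equal(aggregate_experts(ms), aggregate_experts(rev(ms)))
  })
  expect_error(aggregate_experts(list(a, matrix(0, 3, 2))), "shape")
})

test_that("score-stage pipeline values are monotone in term score within columns", {
  scc <- default_scale(correct_k1 = TRUE)
  codes <- matrix(c("K0", "K2", "K4", "K7",
                    "K1", "K1", "K5", "K3"), 4, 2,
                  dimnames = list(paste0("d", 1:4), c("C1", "C2")))
  o <- decision_matrix(codes, scc, stage = "score")
  term_scores <- tsfn_score(scale_value(scc, codes[, 1]))
  expect_equal(order(o[, 1]), order(term_scores))
  # lowest-scored cell anchors at exactly 0, all values in [0, 1]
  expect_equal(min(o[, 1]), 0)
  expect_true(all(o >= 0 & o <= 1))
  # ties map to identical values
  expect_equal(o["d1", "C2"], o["d2", "C2"])
})

test_that("pipeline output is invariant to row order up to the permutation", {
  scc <- default_scale(correct_k1 = TRUE)
  codes <- matrix(c("K1", "K3", "K6", "K2", "K5", "K0"), 3, 2,
                  dimnames = list(paste0("d", 1:3), c("C1", "C2")))
  o1 <- decision_matrix(codes, scc, stage = "score")
  perm <- c(3, 1, 2)
  o2 <- decision_matrix(codes[perm, ], scc, stage = "score")
  expect_equal(o2, o1[perm, ])
  # the fuzzy stage shares the invariance
  f1 <- decision_matrix(codes, scc, stage = "fuzzy")
  f2 <- decision_matrix(codes[perm, ], scc, stage = "fuzzy")
  expect_equal(f2, f1[perm, ])
})
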