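test_that("bundled fixtures hold the transcribed case-study tables", {
  plpm <- appss_fixture("covid-india-plpm")
  m <- as.matrix(plpm[, -1])
  rownames(m) <- plpm[[1]]
  expect_equal(unname(m["C1", "C5"]), "K8")
  expect_equal(unname(m["C2", ]), c("K5", "-", "K5", "K5", "K6", "K4"))
  expect_equal(unname(diag(m)), rep("-", 6))

  q <- appss_fixture("covid-india-defuzzified")
  expect_equal(unname(q["C3", ]), c(0.742, 0.976, 0.000, 0.881, 0.449, 0.582))

  dat <- appss_fixture("covid-india-data")
  expect_equal(nrow(dat), 11)
  expect_equal(as.numeric(dat[dat$alternative == "d1", "C1"]), 32433)
  counts <- as.matrix(dat[, -1])
  # every count is a non-negative integer and d1 is the column minimum
  expect_true(all(counts >= 0))
  expect_equal(unname(apply(counts, 2, which.min)), rep(1L, 6))

  h <- appss_fixture("covid-india-hierarchy")
  expect_equal(sort(unlist(h, use.names = FALSE)), paste0("C", 1:6))
  expect_error(appss_fixture("no-such-fixture"))
})

test_that("the case-study problem bins the counts onto the scale", {
  prob <- covid_problem()
  expect_equal(unname(prob$performance_codes["d1", ]),
               c("K2", "K2", "K1", "K1", "K0", "K0"))
  expect_equal(unname(prob$performance_codes["d5", "C1"]), "K10")
  expect_equal(unname(prob$performance_codes["d8", ]),
               c("K7", "K6", "K3", "K3", "K2", "K2"))
})

test_that("the full run ranks the 60-69 group first and infants last", {
  rep <- appss_run(covid_problem())
  rk <- stats::setNames(rep$ranking$rank, rep$ranking$alternative)
  expect_equal(rk[["d8"]], 1L)
  expect_equal(rk[["d1"]], 11L)
  # the infant row is the weakest assessment of every column, so its
  # converged state is exactly sigmoid(0)
  expect_identical(unname(rep$bam$x["d1"]), 0.5)
  expect_true(rep$bam$converged)
  expect_true(all(rep$satisfaction$satisfaction == 0L))
})

test_that("stage injection starts the pipeline from a printed crisp matrix", {
  prob <- covid_problem()
  rep <- appss_run(prob,
                   criteria_matrix = appss_fixture("covid-india-defuzzified"))
  w <- stats::setNames(rep$preference$weight, rep$preference$criterion)
  expect_true(all(abs(w - printed_w) <= 0.005))
  # zero performance matrix: every alternative parks at 0.5, all rank 1
  zero <- matrix(0, 11, 6, dimnames = dimnames(rep$performance_matrix))
  rep0 <- appss_run(prob, performance_matrix = zero)
  expect_equal(unname(rep0$bam$x), rep(0.5, 11))
  expect_equal(rep0$ranking$rank, rep(1L, 11))
})

test_that("the alpha sweep preserves the ordering across the unit interval", {
  sw <- alpha_sweep(covid_problem(), alphas = seq(0, 1, by = 0.25))
  expect_equal(nrow(sw), 5)
  expect_true(attr(sw, "stable"))
  # a single-alpha sweep equals a plain run
  one <- alpha_sweep(covid_problem(), alphas = 0.5)
  rep <- appss_run(covid_problem())
  expect_equal(one$ranks[[1]],
               stats::setNames(rep$ranking$rank, rep$ranking$alternative))
})

test_that("the problem generator is seeded and well-formed", {
  p1 <- generate_problem(7, f = 5, g = 4)
  p2 <- generate_problem(7, f = 5, g = 4)
  expect_identical(p1$plpm, p2$plpm)
  expect_identical(p1$performance_counts, p2$performance_counts)
  expect_false(identical(p1$plpm, generate_problem(8, f = 5, g = 4)$plpm))
  # absent diagonal, valid codes elsewhere
  expect_equal(unname(diag(p1$plpm)), rep("-", 4))
  offd <- p1$plpm[upper.tri(p1$plpm) | lower.tri(p1$plpm)]
  expect_true(all(offd %in% default_scale()$code))
  # stratified counts exercise several bins
  codes <- unique(as.vector(generate_problem(3, f = 4, g = 3)$performance_codes))
  expect_gte(length(codes), 3)
  # generated problems run end to end
  rep <- appss_run(p1)
  expect_true(rep$bam$converged)
  expect_equal(sort(unique(rep$satisfaction$alternative)),
               sort(rownames(p1$performance_codes)))
})

test_that("identical configuration and seed reproduce the report exactly", {
  prob <- generate_problem(99, f = 6, g = 4)
  cfg <- appss_config(alpha = 0.3, seed = 99L)
  r1 <- appss_run(prob, cfg)
  r2 <- appss_run(generate_problem(99, f = 6, g = 4), cfg)
  expect_identical(r1$bam$x, r2$bam$x)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$config$seed, 99L)
})

test_that("report tidiers join ranking and satisfaction", {
  rep <- appss_run(covid_problem())
  td <- tidy(rep)
  expect_equal(nrow(td), 11)
  expect_true(all(c("score", "rank", "flow_net", "satisfaction", "class")
                  %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$top, "d8")
  # plots build without error
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep$bam), "ggplot")
  expect_s3_class(autoplot(rep$preference), "ggplot")
})
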