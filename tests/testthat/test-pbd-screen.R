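# Screening statistics against the bundled table and against independent
# oracles (regression slopes, closed-form variance).

test_that("concentration effects reproduce the bundled screening table", {
  d <- cod_fixture("table1")
  eff <- concentration_effect(d)
  printed <- c(yeast_extract = 0.6368, malt_extract = 0.0393,
               dextrose = 0.1918, calcium_carbonate = -0.0377,
               starch = -0.1411, ammonium_carbonate = 0.0539,
               sodium_carbonate = -0.0248)
  # printed effects derive from unrounded activities; 3-decimal inputs
  # reproduce them to 1e-3 (absolute)
  expect_lt(max(abs(eff[names(printed)] - printed)), 1e-3)
  expect_lt(abs(concentration_effect(d, factor = "starch") + 0.1411), 1e-3)
})

test_that("a constant response has zero effect on every factor and dummy", {
  d <- pbd_design(pbd7_factors())
  eff <- concentration_effect(d, response = rep(1.8, 12))
  expect_equal(unname(eff), rep(0, 11))
})

test_that("each effect equals twice the least-squares slope on its coded column", {
  d <- pbd_design(pbd7_factors())
  set.seed(7)
  y <- rnorm(12, mean = 2, sd = 0.3)
  eff <- concentration_effect(d, response = y)
  for (cn in colnames(d$coded)) {
    slope <- unname(stats::coef(stats::lm(y ~ d$coded[, cn]))[2L])
    expect_equal(unname(eff[cn]), 2 * slope, tolerance = 1e-12)
  }
})

test_that("effects are invariant to run reordering and response shifts, and t ranking to scaling", {
  d <- cod_fixture("table1")
  y <- d$response
  eff <- concentration_effect(d)
  perm <- c(5, 3, 12, 1, 8, 2, 11, 4, 10, 7, 9, 6)
  d2 <- d
  d2$coded <- d$coded[perm, ]
  d2$natural <- d$natural[perm, ]
  d2$response <- y[perm]
  expect_equal(concentration_effect(d2), eff)
  expect_equal(concentration_effect(d, response = y + 5), eff)
  r1 <- pbd_screen(d, v_eff = 0.001494)
  r2 <- pbd_screen(d, response = 3 * y, v_eff = 9 * 0.001494)
  expect_identical(r1$factor, r2$factor)
})

test_that("dummy variance: overrides, noiseless zero, and Monte-Carlo closed form", {
  d <- pbd_design(pbd7_factors())
  ov <- dummy_variance(d, v_eff = 0.001494)
  expect_identical(ov$v_eff, 0.001494)
  expect_lt(abs(ov$se - 0.038652), 1e-6)  # sqrt(0.001494) to printed precision

  # dummies carry only error: a purely additive main-effect response has
  # exactly zero dummy effects
  effects <- c(yeast_extract = 0.6, dextrose = 0.2, starch = -0.14)
  y0 <- simulate_pbd_response(d, effects, sd = 0)
  dv0 <- dummy_variance(d, response = y0)
  expect_lt(dv0$v_eff, 1e-20)

  # Monte-Carlo mean of V_eff vs the analytic effect variance 4 sigma^2 / N
  sigma <- 0.05
  set.seed(123)
  noise <- matrix(rnorm(12 * 2000, 0, sigma), nrow = 12)
  dcols <- d$coded[, d$dummies]
  veffs <- colSums((crossprod(dcols, noise) / 6)^2) / ncol(dcols)
  expect_equal(mean(veffs), 4 * sigma^2 / 12, tolerance = 0.1)

  expect_error(dummy_variance(pbd_design(lapply(1:11, function(i)
    factor_spec(paste0("f", i), "screening", low = 0, high = 1))),
    response = rnorm(12)), "no dummy columns")
})

test_that("t statistics and one-tailed p values match the study's convention", {
  # printed p values correspond to the upper tail of |t| with df = N - 2
  tt <- effect_ttest(c(a = 1.3954 * 0.038652, b = 0.6416 * 0.038652),
                     se = 0.038652, df = 10)
  expect_equal(tt["a", "p"], 0.09655, tolerance = 1e-4)
  expect_equal(tt["b", "p"], 0.26777, tolerance = 1e-4)
  # symmetry: t = 0 gives p = 0.5 one-tailed
  expect_equal(effect_ttest(c(x = 0), se = 1, df = 10)$p, 0.5)
  # zero SE sentinel
  expect_warning(t0 <- effect_ttest(c(x = 0.2), se = 0, df = 10), "zero")
  expect_identical(t0$t, Inf)
  expect_identical(t0$p, 0)
})

test_that("screening report ranks the four carried-forward factors on top", {
  d <- cod_fixture("table1")
  scr <- pbd_screen(d, v_eff = attr(d, "v_eff"))
  expect_s3_class(scr, "pbd_screen")
  expect_identical(scr$factor[1L], "yeast_extract")
  expect_setequal(scr$factor[scr$significant],
                  c("yeast_extract", "dextrose", "starch",
                    "ammonium_carbonate"))
  # printed t values within 0.2%
  printed_t <- c(yeast_extract = 16.4770, dextrose = 4.9631,
                 starch = -3.6513, ammonium_carbonate = 1.3954)
  got <- scr$t[match(names(printed_t), scr$factor)]
  expect_equal(got, unname(printed_t), tolerance = 2e-3)
  # constant response: nothing significant
  scr0 <- pbd_screen(d, response = rep(2, 12), v_eff = 0.001)
  expect_false(any(scr0$significant))
})

test_that("a planted dominant effect is ranked first in nearly all replicates", {
  d <- pbd_design(pbd7_factors())
  sigma <- 0.05
  top <- vapply(seq_len(500), function(i) {
    y <- simulate_pbd_response(d, c(dextrose = 10 * sigma), baseline = 2,
                               sd = sigma, seed = 1000 + i)
    scr <- pbd_screen(d, response = y)
    scr$factor[1L]
  }, character(1))
  expect_gte(mean(top == "dextrose"), 0.99)
})
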