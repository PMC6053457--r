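# Second-order model: basis expansion, OLS fit vs a normal-equations
# oracle, ANOVA identities, prediction invariances, surface slices.

test_that("quadratic expansion has the documented columns and arithmetic", {
  mm <- expand_quadratic(c(0.4, 0.4, 0.8, 0.02),
                         names = c("x1", "x2", "x3", "x4"))
  expect_equal(ncol(mm), 15L)
  expect_equal(colnames(mm)[1:2], c("(Intercept)", "x1"))
  expect_equal(unname(mm[1, "x1:x3"]), 0.32)
  expect_equal(unname(mm[1, "x4^2"]), 0.0004)
  z <- expand_quadratic(rep(0, 4))
  expect_equal(unname(z[1, ]), c(1, rep(0, 14)))
})

test_that("OLS coefficients match the normal-equations oracle", {
  d <- cod_fixture("table2")
  fit <- rsm_fit(d)
  X <- expand_quadratic(d$natural)
  beta <- solve(crossprod(X), crossprod(X, d$response))  # independent route
  expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-8)
})

test_that("zero-noise responses from a known model are recovered exactly", {
  model <- cod_fixture("table3-model")
  d <- cod_fixture("table2")
  y <- simulate_ccd_response(d, model, sd = 0)
  fit <- rsm_fit(d, response = y)
  expect_equal(unname(fit$coefficients), unname(model$coefficients),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("fit on the bundled CCD: residuals, ANOVA identity, center behaviour", {
  d <- cod_fixture("table2")
  fit <- rsm_fit(d)
  ctr <- fit$predictions$residual[d$point_type == "center"]
  expect_true(all(abs(ctr) < 0.15))
  expect_equal(sum(fit$predictions$residual), 0, tolerance = 1e-8)
  a <- fit$anova
  expect_equal(a$ss[1] + a$ss[2], a$ss[3],
               tolerance = 1e-8 * a$ss[3])
  expect_equal(fit$r_squared, 1 - a$ss[2] / a$ss[3], tolerance = 1e-12)
  expect_identical(a$df[1:2], c(14L, 12L))
})

test_that("constant responses give a flat model with R-squared 0 by convention", {
  d <- cod_fixture("table2")
  fit <- rsm_fit(d, response = rep(1.8, 27))
  expect_lt(max(abs(fit$coefficients[-1])), 1e-10)
  expect_equal(unname(fit$coefficients[1]), 1.8, tolerance = 1e-10)
  expect_identical(fit$r_squared, 0)
})

test_that("natural- and coded-unit fits of the same data predict identically", {
  d <- cod_fixture("table2")
  fn <- rsm_fit(d, units = "natural")
  fc <- rsm_fit(d, units = "coded")
  set.seed(11)
  pts <- cbind(runif(20, 0, 0.8), runif(20, 0, 0.8),
               runif(20, 0, 1.6), runif(20, 0, 0.04))
  expect_equal(predict(fn, pts),
               predict(fc, code_points(pts, d$factors)),
               tolerance = 1e-8)
  # predict() converts units itself when the fit carries factor specs
  expect_equal(predict(fc, pts, units = "natural"),
               predict(fn, pts), tolerance = 1e-8)
})

test_that("the bundled model evaluates to the printed center prediction", {
  m <- cod_fixture("table3-model")
  expect_equal(unname(predict(m, c(0.4, 0.4, 0.8, 0.02))), 1.698545,
               tolerance = 1e-3)
  zero <- quadratic_model(rep(0, 15), m$factor_names)
  expect_identical(unname(predict(zero, c(0.2, 0.5, 1.0, 0.01))), 0)
})

test_that("rank deficiency is reported with the collinear columns", {
  d <- cod_fixture("table2")
  bad <- d
  bad$natural[, "dextrose"] <- 2 * bad$natural[, "yeast_extract"]
  expect_error(rsm_fit(bad), "singular design")
  expect_error(rsm_fit(d, response = d$response[1:5]), "one value per run")
})

test_that("mismatched unit systems without factor specs error out", {
  m <- quadratic_model(rnorm(15), paste0("x", 1:4), units = "natural")
  expect_error(predict(m, rep(0, 4), units = "coded"), "unit-system mismatch")
})

test_that("ANOVA arithmetic reproduces the printed model adequacy table", {
  a <- anova_from_ss(4.445999, 0.502399, 4, 22)
  expect_equal(a$f, 48.67242, tolerance = 1e-5)
  expect_equal(a$r_squared, 0.89847, tolerance = 1e-5)
  expect_equal(a$r, 0.94, tolerance = 0.01)
  expect_lt(a$p, 1e-4)
  expect_equal(a$table$ss[3], 4.948399, tolerance = 1e-6)
})

test_that("coefficient RMSE shrinks roughly as 1/sqrt(replication)", {
  model <- cod_fixture("table3-model")
  base <- cod_fixture("table2")
  sigma <- 0.05
  rmse_for_m <- function(m, nrep = 30, seed0 = 500) {
    X <- base$natural[rep(seq_len(27), each = m), , drop = FALSE]
    d <- X
    mu <- predict(model, X)
    mean(vapply(seq_len(nrep), function(r) {
      set.seed(seed0 + r)
      y <- mu + rnorm(length(mu), 0, sigma)
      fit <- rsm_fit(d, response = y)
      sqrt(mean((fit$coefficients - model$coefficients)^2))
    }, numeric(1)))
  }
  r1 <- rmse_for_m(1); r4 <- rmse_for_m(4); r16 <- rmse_for_m(16)
  expect_gt(r1, r4)
  expect_gt(r4, r16)
  expect_gt(r1 / r16, 2)   # expected factor 4
  expect_lt(r1 / r16, 8)
})

test_that("surface slices behave like the model they cut through", {
  m <- cod_fixture("table3-model")
  # high yeast extract maximizes the yeast x starch slice within the CCD box
  sl <- surface_slice(m, c("yeast_extract", "starch"), n = 41,
                      ranges = list(c(0, 0.8), c(0, 1.6)))
  top <- sl[which.max(sl$yhat), ]
  expect_equal(top$yeast_extract, 0.8, tolerance = 1e-9)
  # 1x1 grid equals a point prediction
  one <- surface_slice(m, c("dextrose", "starch"), n = 1,
                       ranges = list(c(0.4, 0.4), c(0.8, 0.8)))
  expect_equal(one$yhat,
               unname(predict(m, c(0.4, 0.4, 0.8, 0.02))), tolerance = 1e-12)
  # additive model (no interaction): slice rows differ by a constant
  co <- stats::setNames(rep(0, 15), names(m$coefficients))
  co[c("(Intercept)", "yeast_extract", "starch", "starch^2")] <-
    c(1, 2, -0.5, 0.1)
  add <- quadratic_model(co, cod_fixture("table3-model")$factors)
  sla <- surface_slice(add, c("yeast_extract", "starch"), n = 5,
                       ranges = list(c(0, 1), c(0, 1)))
  wide <- matrix(sla$yhat, 5, 5)   # rows: yeast, cols: starch
  offsets <- sweep(wide, 1L, wide[, 1L], "-")
  expect_equal(offsets, matrix(rep(offsets[1L, ], each = 5), 5, 5),
               tolerance = 1e-12)
  expect_error(surface_slice(m, c("starch", "starch")), "distinct")
})
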