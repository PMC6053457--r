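# GA contracts (elitism, determinism, feasibility) and agreement with
# analytic and grid-search oracles.

test_that("the GA finds the vertex of a 1-D parabola", {
  res <- ga_maximize(function(x) -(x[1] - 0.3)^2, bounds = list(c(0, 1)),
                     config = ga_config(pop_size = 50, crossover_fraction = 0.8,
                                        mutation = "gaussian", seed = 7))
  expect_lt(abs(res$best_point[1] - 0.3), 1e-3)
})

test_that("elitism carries the two best individuals unchanged", {
  set.seed(3)
  pop <- matrix(runif(20), 10, 2)
  fit <- -rowSums((pop - 0.5)^2)
  cfg <- ga_config(pop_size = 10, elite_count = 2)
  nxt <- evolve_generation(pop, fit, cfg, bounds = list(c(0, 1), c(0, 1)))
  best2 <- pop[order(fit, decreasing = TRUE)[1:2], ]
  expect_identical(nxt[1:2, ], best2)
})

test_that("crossover fraction 1 yields only recombined genes; identical parents breed themselves", {
  set.seed(4)
  pop <- matrix(runif(24, 1, 2), 12, 2)
  fit <- rowSums(pop)
  cfg <- ga_config(pop_size = 12, elite_count = 2, crossover_fraction = 1)
  nxt <- evolve_generation(pop, fit, cfg, bounds = list(c(1, 2), c(1, 2)))
  # every child gene value already existed in the parent population
  expect_true(all(nxt %in% pop))
  # degenerate population: scattered crossover reproduces the parent
  same <- matrix(1.5, 12, 2)
  nxt2 <- evolve_generation(same, rep(1, 12), cfg,
                            bounds = list(c(1, 2), c(1, 2)))
  expect_true(all(nxt2 == 1.5))
})

test_that("seeded runs are bit-reproducible with a monotone best trace", {
  obj <- function(x) -sum((x - c(0.2, 0.6))^2) + 1
  cfg <- ga_config(pop_size = 30, max_generations = 40,
                   crossover_fraction = 0.8, mutation = "gaussian", seed = 11)
  b <- list(c(0, 1), c(0, 1))
  r1 <- ga_maximize(obj, b, cfg)
  r2 <- ga_maximize(obj, b, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$trace$best) >= 0))
  expect_equal(r1$best_value, obj(r1$best_point))
})

test_that("every evaluated point stays inside the box", {
  seen <- NULL
  obj <- function(x) { seen <<- rbind(seen, x); -sum(x^2) }
  b <- list(c(-0.5, 2), c(1, 3))
  res <- ga_maximize(obj, b, ga_config(pop_size = 20, max_generations = 15,
                                       crossover_fraction = 0.7, seed = 5))
  expect_true(all(seen[, 1] >= -0.5 & seen[, 1] <= 2))
  expect_true(all(seen[, 2] >= 1 & seen[, 2] <= 3))
  expect_true(all(res$best_point >= c(-0.5, 1) & res$best_point <= c(2, 3)))
})

test_that("non-finite objective values are penalized, not propagated", {
  obj <- function(x) if (x[1] > 0.5) NaN else x[1]
  expect_warning(
    res <- ga_maximize(obj, list(c(0, 1)),
                       ga_config(pop_size = 20, max_generations = 10,
                                 crossover_fraction = 0.8, seed = 2)),
    "non-finite")
  expect_true(is.finite(res$best_value))
  expect_lte(res$best_point[1], 0.5)
})

test_that("stationary-point analysis classifies max, saddle and boundary cases", {
  # separable concave bowl: interior maximum returned exactly
  nm <- c("x1", "x2")
  co <- stats::setNames(numeric(6), c("(Intercept)", nm, paste0(nm, "^2"),
                                      "x1:x2"))
  co[c("x1", "x2")] <- c(2 * 0.3, 2 * 0.7)
  co[paste0(nm, "^2")] <- -1          # y = -(x1-0.3)^2 - (x2-0.7)^2 + const
  m <- quadratic_model(co, nm)
  sp <- quadratic_stationary_point(m, bounds = list(c(0, 1), c(0, 1)))
  expect_equal(unname(sp$point), c(0.3, 0.7), tolerance = 1e-10)
  expect_identical(sp$nature, "max")
  expect_false(sp$boundary_constrained)

  co2 <- co; co2[] <- 0; co2["x1^2"] <- 1; co2["x2^2"] <- -1
  expect_identical(
    quadratic_stationary_point(quadratic_model(co2, nm))$nature, "saddle")

  # bundled model over the axial box: optimum sits on the boundary
  sp3 <- quadratic_stationary_point(cod_fixture("table3-model"),
                                    bounds = ga_bounds_preset("ccd-box"))
  expect_true(sp3$boundary_constrained)
  expect_gte(sp3$value, 2.788)
})

test_that("GA agrees with analytic and grid oracles on random concave quadratics", {
  cfg <- ga_config(pop_size = 60, max_generations = 120,
                   stall_generations = 60, crossover_fraction = 0.8,
                   mutation = "gaussian")
  for (s in 1:20) {
    set.seed(s)
    k <- if (s %% 2 == 0) 2L else 3L
    prob <- random_concave_quadratic(k)
    lb <- prob$xs - runif(k, 0.5, 1.5)
    ub <- prob$xs + runif(k, 0.5, 1.5)
    if (s %% 5 == 0) ub <- prob$xs - 0.1   # push the optimum onto the boundary
    bounds <- rbind(lb, ub)
    cfg$seed <- 100 + s
    res <- ga_maximize(prob$objective, bounds, cfg)
    sp <- quadratic_stationary_point(prob$model, bounds)
    # independent dense grid search
    n_grid <- if (k == 2L) 201L else 41L
    axes <- lapply(seq_len(k), function(j) seq(lb[j], ub[j], length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    gval <- max(predict(prob$model, grid))
    expect_lt(abs(res$best_value - sp$value), 1e-2)
    expect_lt(abs(res$best_value - gval), 1e-2)
    expect_gte(res$best_value, gval - 1e-2)  # grid cannot beat GA by much
  }
})

test_that("GA on the bundled model beats the best observed activity", {
  m <- cod_fixture("table3-model")
  res <- ga_maximize(function(x) predict(m, x), ga_bounds_preset("ccd-box"),
                     ga_config(seed = 1))
  expect_gte(res$best_value, 2.788)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(ga_config(pop_size = 10, elite_count = 10))
  expect_error(ga_config(crossover_fraction = 1.2))
  expect_error(ga_maximize(function(x) 1, bounds = list(c(1, 0))), "lower bound")
})
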