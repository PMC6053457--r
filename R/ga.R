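# Real-coded genetic algorithm for bound-constrained maximization of a
# response surface, configured like the classical toolbox optimizer used in
# medium-optimization studies: rank fitness scaling, stochastic universal
# sampling, scattered (uniform-mask) crossover, elitism, and stall-based
# termination.

#' Genetic-algorithm configuration
#'
#' Defaults mirror the optimizer settings of the bundled study: population
#' 200, elite count 2, crossover fraction 1 (which, by the standard child
#' accounting `n_mutation = (pop - elite) * (1 - crossover_fraction)`,
#' leaves the mutation operator inactive), 100 generations with a 50
#' generation stall limit.
#'
#' @param pop_size Population size.
#' @param elite_count Number of best individuals copied unchanged into the
#'   next generation.
#' @param crossover_fraction Fraction of non-elite children produced by
#'   crossover (the rest are mutation children).
#' @param max_generations Generation cap.
#' @param stall_generations Terminate when the best fitness has not
#'   improved by more than `stall_tol` for this many generations.
#' @param stall_tol Absolute improvement threshold for the stall test.
#' @param mutation `"uniform"` (each gene reset with probability
#'   `mutation_rate` to a uniform draw within its bounds) or `"gaussian"`
#'   (every gene perturbed by Gaussian noise whose scale shrinks linearly
#'   over the run, then clipped to bounds).
#' @param mutation_rate Per-gene reset probability for uniform mutation.
#' @param mutation_scale,mutation_shrink Gaussian mutation: initial sd as a
#'   fraction of each factor's range, and the linear shrink factor (1 drives
#'   the sd to zero at the generation cap).
#' @param seed Optional integer seed making the whole run reproducible.
#'
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 200, elite_count = 2, crossover_fraction = 1,
                      max_generations = 100, stall_generations = 50,
                      stall_tol = 1e-6,
                      mutation = c("uniform", "gaussian"),
                      mutation_rate = 0.01, mutation_scale = 1,
                      mutation_shrink = 1, seed = NULL) {
  mutation <- match.arg(mutation)
  stopifnot(pop_size >= 4, elite_count >= 0, elite_count < pop_size,
            crossover_fraction >= 0, crossover_fraction <= 1,
            max_generations >= 1, stall_generations >= 1, stall_tol >= 0,
            mutation_rate >= 0, mutation_rate <= 1, mutation_scale >= 0,
            mutation_shrink >= 0)
  structure(list(pop_size = as.integer(pop_size),
                 elite_count = as.integer(elite_count),
                 crossover_fraction = crossover_fraction,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 stall_tol = stall_tol, mutation = mutation,
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 mutation_shrink = mutation_shrink, seed = seed),
            class = "ga_config")
}

#' Bound presets for the bundled medium-optimization study
#'
#' `"ccd-box"` spans the axial (coded -2..+2) ranges of the study's central
#' composite design. `"extended-box"` additionally contains the optimum
#' concentrations the study reports, which for yeast extract and ammonium
#' carbonate lie outside the CCD ranges; the study never states the bounds
#' its optimizer actually used.
#'
#' @param name `"ccd-box"` or `"extended-box"`.
#' @return A 2 x 4 matrix (rows `lower`, `upper`) with factor column names,
#'   in g/100 ml.
#' @export
ga_bounds_preset <- function(name = c("ccd-box", "extended-box")) {
  name <- match.arg(name)
  upper <- switch(name,
    "ccd-box" = c(0.8, 0.8, 1.6, 0.04),
    "extended-box" = c(1, 0.8, 1.6, 0.05))
  matrix(c(0, 0, 0, 0, upper), nrow = 2L, byrow = TRUE,
         dimnames = list(c("lower", "upper"),
                         c("yeast_extract", "dextrose", "starch",
                           "ammonium_carbonate")))
}

sus_select <- function(weights, n) {
  total <- sum(weights)
  step <- total / n
  pts <- stats::runif(1L, 0, step) + step * (seq_len(n) - 1L)
  findInterval(pts, cumsum(weights)) + 1L
}

#' Advance a GA population by one generation
#'
#' Produces the next population from the current one: the `elite_count`
#' fittest individuals are copied unchanged; the remaining slots are filled
#' by scattered-crossover children (per-gene random mask between two
#' parents) and, when `crossover_fraction < 1`, mutation children. Parents
#' are drawn by stochastic universal sampling with rank-scaled fitness
#' (expectation proportional to `1/sqrt(rank)`).
#'
#' @param population `n x k` matrix of individuals (rows within bounds).
#' @param fitness Numeric vector of fitness values (larger is better).
#' @param config A [ga_config()].
#' @param bounds Bounds as a 2 x k matrix (rows lower/upper) or list of
#'   `c(lo, hi)`.
#' @param generation Current generation index (drives the Gaussian mutation
#'   shrink schedule).
#'
#' @return The next `n x k` population matrix.
#' @export
evolve_generation <- function(population, fitness, config, bounds,
                              generation = 1L) {
  stopifnot(inherits(config, "ga_config"))
  pop <- as.matrix(population)
  n <- nrow(pop); k <- ncol(pop)
  stopifnot(length(fitness) == n)
  bounds <- as_bounds(bounds, k)
  lb <- bounds[1L, ]; ub <- bounds[2L, ]
  ord <- order(fitness, decreasing = TRUE)
  n_elite <- config$elite_count
  n_kids <- n - n_elite
  n_x <- round(config$crossover_fraction * n_kids)
  n_m <- n_kids - n_x
  scaled <- 1 / sqrt(seq_len(n))           # rank scaling, rank 1 = best
  n_parents <- 2L * n_x + n_m
  parents <- integer(0)
  if (n_parents > 0L) {
    parents <- ord[sus_select(scaled, n_parents)]
    parents <- parents[sample.int(n_parents)]
  }
  kids <- matrix(0, n_kids, k)
  if (n_x > 0L) {
    for (j in seq_len(n_x)) {
      p1 <- pop[parents[2L * j - 1L], ]
      p2 <- pop[parents[2L * j], ]
      mask <- stats::runif(k) < 0.5
      kids[j, ] <- ifelse(mask, p1, p2)
    }
  }
  if (n_m > 0L) {
    for (j in seq_len(n_m)) {
      base <- pop[parents[2L * n_x + j], ]
      child <- switch(config$mutation,
        uniform = {
          hit <- stats::runif(k) < config$mutation_rate
          base[hit] <- lb[hit] + stats::runif(sum(hit)) * (ub - lb)[hit]
          base
        },
        gaussian = {
          frac <- min(1, generation / config$max_generations)
          sd <- config$mutation_scale * (ub - lb) *
            max(0, 1 - config$mutation_shrink * frac)
          base + stats::rnorm(k, 0, sd)
        })
      kids[n_x + j, ] <- pmin(pmax(child, lb), ub)
    }
  }
  out <- rbind(pop[ord[seq_len(n_elite)], , drop = FALSE], kids)
  dimnames(out) <- dimnames(pop)
  out
}

#' Maximize an objective over box bounds with a genetic algorithm
#'
#' Seeded, bound-constrained real-coded GA maximization. The initial
#' population is uniform within the bounds; every generation applies rank
#' scaling, stochastic universal sampling, scattered crossover, optional
#' mutation and elitism (see [evolve_generation()]). Termination is by
#' stall (no improvement greater than `stall_tol` over `stall_generations`
#' generations) or by the generation cap.
#'
#' @param objective Function mapping a length-`k` numeric point to a scalar
#'   value to maximize. Non-finite values at feasible points are penalized
#'   with `-Inf` fitness (with a warning).
#' @param bounds Bounds as a 2 x k matrix (rows lower/upper) or list of
#'   `c(lo, hi)` per factor.
#' @param config A [ga_config()].
#'
#' @return An object of class `ga_result`: `best_point` (named when bounds
#'   carry names), `best_value`, `generations`, `trace` (data frame with
#'   per-generation `best` and `mean` fitness), and `termination`
#'   (`"stall"` or `"generations"`). Elitism guarantees a non-decreasing
#'   best-fitness trace, and `best_value = objective(best_point)`.
#'
#' @examples
#' res <- ga_maximize(function(x) -(x[1] - 0.3)^2, bounds = list(c(0, 1)),
#'                    config = ga_config(pop_size = 50, seed = 1))
#' res$best_point
#' @export
ga_maximize <- function(objective, bounds, config = ga_config()) {
  stopifnot(is.function(objective), inherits(config, "ga_config"))
  bounds <- as_bounds(bounds)
  k <- ncol(bounds)
  lb <- bounds[1L, ]; ub <- bounds[2L, ]
  warned <- FALSE
  evaluate <- function(pop) {
    v <- vapply(seq_len(nrow(pop)), function(i) {
      val <- objective(pop[i, ])
      if (!is.finite(val)) {
        if (!warned) {
          warning("objective returned a non-finite value; penalized with -Inf")
          warned <<- TRUE
        }
        return(-Inf)
      }
      as.numeric(val)
    }, numeric(1))
    v
  }
  with_seed(config$seed, {
    pop <- matrix(stats::runif(config$pop_size * k), config$pop_size, k)
    pop <- sweep(sweep(pop, 2L, ub - lb, "*"), 2L, lb, "+")
    colnames(pop) <- colnames(bounds)
    fit <- evaluate(pop)
    best_val <- -Inf; best_point <- pop[1L, ]
    trace_best <- numeric(0); trace_mean <- numeric(0)
    last_improvement <- 0L
    termination <- "generations"
    gen <- 0L
    for (gen in seq_len(config$max_generations)) {
      i <- which.max(fit)
      if (fit[i] > best_val + config$stall_tol) last_improvement <- gen
      if (fit[i] > best_val) {
        best_val <- fit[i]
        best_point <- pop[i, ]
      }
      trace_best <- c(trace_best, best_val)
      trace_mean <- c(trace_mean, mean(fit[is.finite(fit)]))
      if (gen - last_improvement >= config$stall_generations) {
        termination <- "stall"
        break
      }
      if (gen == config$max_generations) break
      pop <- evolve_generation(pop, fit, config, bounds, generation = gen)
      fit <- evaluate(pop)
    }
    structure(list(best_point = best_point, best_value = best_val,
                   generations = gen,
                   trace = data.frame(generation = seq_along(trace_best),
                                      best = trace_best, mean = trace_mean),
                   termination = termination, config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: best value %.6g after %d generations (%s)\n",
              x$best_value, x$generations, x$termination))
  cat("best point:\n")
  print(round(x$best_point, 6))
  invisible(x)
}

#' Stationary point of a quadratic response surface
#'
#' Solves the stationarity system of a fitted second-order polynomial,
#' classifies the stationary point by the eigenvalue signs of the quadratic
#' form, and -- when the stationary point is infeasible, a saddle, or a
#' minimum while a box is given -- falls back to a dense grid search with
#' local polish inside the bounds. Serves as an analytic oracle for the GA.
#'
#' @param model A `quadratic_model` or `rsm_fit`.
#' @param bounds Optional box bounds (2 x k matrix or list of `c(lo, hi)`).
#' @param n_grid Grid points per dimension for the fallback search
#'   (default scales with dimension).
#'
#' @return A list: `point`, `value`, `nature` (`"max"`, `"min"`,
#'   `"saddle"`, or `"degenerate"` for a singular quadratic form),
#'   `boundary_constrained` (TRUE when the reported optimum sits on the box
#'   boundary), and `stationary_point` (the unconstrained solution, NULL if
#'   degenerate).
#' @export
quadratic_stationary_point <- function(model, bounds = NULL, n_grid = NULL) {
  stopifnot(inherits(model, "quadratic_model"))
  nm <- model$factor_names
  k <- length(nm)
  co <- model$coefficients
  a <- co[nm]
  B <- diag(co[paste0(nm, "^2")], k)
  if (k >= 2L) {
    pr <- utils::combn(k, 2L)
    for (j in seq_len(ncol(pr))) {
      val <- co[paste0(nm[pr[1L, j]], ":", nm[pr[2L, j]])] / 2
      B[pr[1L, j], pr[2L, j]] <- B[pr[2L, j], pr[1L, j]] <- val
    }
  }
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  tol <- 1e-10 * scale
  nature <- if (any(abs(ev) < tol)) "degenerate"
            else if (all(ev < 0)) "max"
            else if (all(ev > 0)) "min"
            else "saddle"
  xs <- if (nature == "degenerate") NULL
        else stats::setNames(drop(solve(B, -a / 2)), nm)
  value_at <- function(x) unname(predict(model, x))
  if (is.null(bounds)) {
    if (is.null(xs)) stop("singular quadratic form and no bounds for a grid fallback")
    return(list(point = xs, value = value_at(xs), nature = nature,
                boundary_constrained = FALSE, stationary_point = xs))
  }
  bounds <- as_bounds(bounds, k)
  lb <- bounds[1L, ]; ub <- bounds[2L, ]
  btol <- 1e-8 * (ub - lb)
  if (nature == "max" && !is.null(xs) &&
      all(xs >= lb - btol & xs <= ub + btol)) {
    pt <- pmin(pmax(xs, lb), ub)
    return(list(point = pt, value = value_at(pt), nature = nature,
                boundary_constrained = FALSE, stationary_point = xs))
  }
  n_grid <- n_grid %||% max(5L, min(51L, ceiling(2e5^(1 / k))))
  axes <- lapply(seq_len(k), function(j) seq(lb[j], ub[j], length.out = n_grid))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- nm
  vals <- predict(model, grid)
  start <- grid[which.max(vals), ]
  opt <- stats::optim(start, fn = function(x) -value_at(x),
                      method = "L-BFGS-B", lower = lb, upper = ub)
  pt <- stats::setNames(opt$par, nm)
  on_boundary <- any(pt <= lb + 1e-6 * (ub - lb) | pt >= ub - 1e-6 * (ub - lb))
  list(point = pt, value = -opt$value, nature = nature,
       boundary_constrained = on_boundary, stationary_point = xs)
}
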