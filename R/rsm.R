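# Second-order response-surface model:
#   Y = b0 + sum_i b_i x_i + sum_i b_ii x_i^2 + sum_{i<j} b_ij x_i x_j
# fit by ordinary least squares on a central composite design.

quad_term_names <- function(nm) {
  k <- length(nm)
  pairs <- if (k >= 2L) utils::combn(nm, 2L) else matrix(character(0), 2L, 0L)
  c("(Intercept)", nm, paste0(nm, "^2"),
    if (ncol(pairs)) paste0(pairs[1L, ], ":", pairs[2L, ]))
}

n_quad_terms <- function(k) 1L + 2L * k + k * (k - 1L) / 2L

#' Expand points into the full second-order model matrix
#'
#' Columns are ordered: intercept, linear terms `x1..xk`, quadratic terms
#' `x1^2..xk^2`, then pairwise interactions `xi:xj` with `i < j` in
#' lexicographic pair order.
#'
#' @param points An `n x k` matrix/data frame of points, or a length-`k`
#'   vector (one point).
#' @param names Optional factor names (defaults to the column names of
#'   `points`, or `x1..xk`).
#'
#' @return An `n x (1 + 2k + k(k-1)/2)` model matrix.
#'
#' @examples
#' expand_quadratic(c(0.4, 0.4, 0.8, 0.02))
#' @export
expand_quadratic <- function(points, names = NULL) {
  x <- if (is.null(dim(points))) matrix(as.numeric(points), nrow = 1L)
       else as.matrix(points)
  storage.mode(x) <- "double"
  k <- ncol(x)
  nm <- names %||% colnames(x) %||% paste0("x", seq_len(k))
  pairs <- if (k >= 2L) utils::combn(k, 2L) else matrix(integer(0), 2L, 0L)
  inter <- matrix(0, nrow(x), ncol(pairs))
  for (j in seq_len(ncol(pairs)))
    inter[, j] <- x[, pairs[1L, j]] * x[, pairs[2L, j]]
  mm <- cbind(1, x, x^2, inter)
  colnames(mm) <- quad_term_names(nm)
  mm
}

#' Assemble a quadratic response-surface model from known coefficients
#'
#' Builds a `quadratic_model` directly from a coefficient vector (in the
#' column order of [expand_quadratic()]), e.g. to evaluate a published
#' regression equation.
#'
#' @param coefficients Numeric vector of length `1 + 2k + k(k-1)/2`,
#'   optionally named.
#' @param factors Either a character vector of `k` factor names or a list
#'   of ccd [factor_spec()] objects (needed for center-based defaults in
#'   [surface_slice()]).
#' @param units `"natural"` (concentrations) or `"coded"`.
#'
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(coefficients, factors, units = c("natural", "coded")) {
  units <- match.arg(units)
  if (is.character(factors)) {
    fnames <- factors
    factors <- NULL
  } else {
    factors <- check_factor_list(factors)
    fnames <- factor_names(factors)
  }
  k <- length(fnames)
  p <- n_quad_terms(k)
  if (length(coefficients) != p)
    stop("expected ", p, " coefficients for ", k, " factors, got ",
         length(coefficients))
  coefficients <- stats::setNames(as.numeric(coefficients),
                                  quad_term_names(fnames))
  structure(list(coefficients = coefficients, factor_names = fnames,
                 factors = factors, units = units),
            class = "quadratic_model")
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least-squares fit of the full quadratic polynomial (linear,
#' quadratic and pairwise-interaction terms) to the responses of a central
#' composite design, with coefficient standard errors, t tests, ANOVA and a
#' per-run prediction table.
#'
#' @param design A `doe_design` (typically a `ccd_design`) or a plain
#'   matrix/data frame of points.
#' @param response Response vector; defaults to the one attached to the
#'   design.
#' @param units Fit in `"natural"` concentration units (default) or
#'   `"coded"` design units. Predictions from either fit of the same data
#'   agree to numerical precision.
#'
#' @return An object of class `c("rsm_fit", "quadratic_model")` with
#'   components `coefficients`, `coef_table` (estimate, se, t, two-sided p),
#'   `anova` (regression / residual / total SS, df, MS, F, p), `r_squared`,
#'   `predictions` (per-run observed, predicted, residual), `sigma2`,
#'   `vcov`, `n`, `p`.
#'
#' @details Degrees of freedom follow the standard convention for a model
#'   with `p` coefficients on `n` runs: `p - 1` for regression and `n - p`
#'   for residual. For printed ANOVA tables built on other conventions see
#'   [anova_from_ss()]. A rank-deficient model matrix (smallest/largest
#'   singular value below 1e-10) is an error naming the collinear columns.
#'
#' @examples
#' d <- cod_fixture("table2")
#' fit <- rsm_fit(d)
#' fit$r_squared
#' @export
rsm_fit <- function(design, response = NULL, units = c("natural", "coded")) {
  units <- match.arg(units)
  if (inherits(design, "doe_design")) {
    response <- response %||% design$response
    pts <- if (units == "natural") design$natural else design$coded
    pts <- pts[, factor_names(design$factors), drop = FALSE]
    factors <- design$factors
  } else {
    pts <- as.matrix(design)
    factors <- NULL
  }
  if (is.null(response)) stop("no response attached to the design")
  y <- as.numeric(response)
  X <- expand_quadratic(pts)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("'response' must have one value per run (", n, ")")
  if (n < p) stop("need at least ", p, " runs to fit ", p, " coefficients; got ", n)
  sv <- svd(scale(X, center = FALSE, scale = sqrt(colSums(X^2))))$d
  if (min(sv) / max(sv) < 1e-10) {
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ X - 1)
  coefs <- stats::setNames(stats::coef(fit), colnames(X))
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- sum((fitted - mean(y))^2)
  df_reg <- p - 1L; df_res <- n - p
  sigma2 <- if (df_res > 0) ss_res / df_res else NA_real_
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tstat <- coefs / se
  coef_table <- data.frame(term = colnames(X), estimate = unname(coefs),
                           se = se, t = tstat,
                           p = 2 * stats::pt(abs(tstat), df_res,
                                             lower.tail = FALSE),
                           row.names = NULL)
  r2 <- if (ss_tot > 1e-12 * max(1, mean(y)^2)) 1 - ss_res / ss_tot else 0
  f <- (ss_reg / df_reg) / (ss_res / df_res)
  anova_tab <- data.frame(
    source = c("regression", "residual", "total"),
    ss = c(ss_reg, ss_res, ss_tot),
    df = c(df_reg, df_res, n - 1L),
    ms = c(ss_reg / df_reg, ss_res / df_res, NA),
    f = c(f, NA, NA),
    p = c(stats::pf(f, df_reg, df_res, lower.tail = FALSE), NA, NA))
  predictions <- data.frame(
    if (inherits(design, "doe_design")) as.data.frame(design$natural)
    else as.data.frame(pts),
    observed = y, predicted = fitted, residual = resid)
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = coefs,
         factor_names = colnames(pts) %||% paste0("x", seq_len(ncol(pts))),
         factors = factors, units = units,
         coef_table = coef_table, anova = anova_tab,
         r_squared = r2, r = sqrt(max(r2, 0)),
         predictions = predictions, sigma2 = sigma2, vcov = vc,
         n = n, p = p),
    class = c("rsm_fit", "quadratic_model"))
}

#' Predict from a quadratic response-surface model
#'
#' @param object A `quadratic_model` or `rsm_fit`.
#' @param newdata A point (length-`k` vector) or `n x k` matrix/data frame.
#' @param units Unit system of `newdata`. Must match the model's unit
#'   system unless the model carries factor specifications, in which case
#'   points are converted.
#' @param ... Unused.
#'
#' @return Numeric vector of predicted responses.
#'
#' @examples
#' m <- cod_fixture("table3-model")
#' predict(m, c(0.4, 0.4, 0.8, 0.02))
#' @export
predict.quadratic_model <- function(object, newdata, units = object$units, ...) {
  x <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1L)
       else as.matrix(newdata)
  if (ncol(x) != length(object$factor_names))
    stop("points have ", ncol(x), " coordinates but the model has ",
         length(object$factor_names), " factors")
  if (units != object$units) {
    if (is.null(object$factors))
      stop("unit-system mismatch: model is in ", object$units,
           " units, points in ", units,
           " units, and no factor specifications are available to convert")
    x <- if (units == "natural") code_points(x, object$factors)
         else decode_points(x, object$factors)
  }
  drop(expand_quadratic(x, names = object$factor_names) %*% object$coefficients)
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Second-order response-surface model (%d factors, %s units)\n",
              length(x$factor_names), x$units))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Second-order RSM fit: %d runs, %d coefficients (%s units)\n",
              x$n, x$p, x$units))
  print(x$coef_table, digits = 5)
  cat(sprintf("R-squared: %.5f (R = %.5f)\n", x$r_squared, x$r))
  invisible(x)
}

#' ANOVA arithmetic from given sums of squares
#'
#' Recomputes the derived ANOVA quantities (mean squares, F, model p value,
#' R-squared and multiple correlation R) from supplied regression and
#' residual sums of squares and degrees of freedom. This reproduces a
#' printed ANOVA table whatever df convention it used.
#'
#' @param ss_regression,ss_residual Sums of squares.
#' @param df_regression,df_residual Degrees of freedom.
#'
#' @return A list with the assembled `table` (data frame) and scalar
#'   `f`, `p`, `r_squared`, `r`.
#'
#' @examples
#' a <- anova_from_ss(4.445999, 0.502399, 4, 22)
#' a$f; a$r_squared
#' @export
anova_from_ss <- function(ss_regression, ss_residual, df_regression,
                          df_residual) {
  stopifnot(ss_regression >= 0, ss_residual >= 0,
            df_regression >= 1, df_residual >= 1)
  ms_reg <- ss_regression / df_regression
  ms_res <- ss_residual / df_residual
  f <- ms_reg / ms_res
  p <- stats::pf(f, df_regression, df_residual, lower.tail = FALSE)
  ss_tot <- ss_regression + ss_residual
  r2 <- ss_regression / ss_tot
  list(table = data.frame(
         source = c("regression", "residual", "total"),
         ss = c(ss_regression, ss_residual, ss_tot),
         df = c(df_regression, df_residual, df_regression + df_residual),
         ms = c(ms_reg, ms_res, NA),
         f = c(f, NA, NA), p = c(p, NA, NA)),
       f = f, p = p, r_squared = r2, r = sqrt(r2))
}

#' Two-factor slice through a response surface
#'
#' Evaluates the model on a dense rectangular grid over two factors while
#' holding the remaining factors at fixed values (their centers by
#' default), yielding the data behind a contour or 3-D surface plot.
#'
#' @param model A `quadratic_model` or `rsm_fit`.
#' @param pair Two distinct factor names (or indices).
#' @param n Grid points per axis.
#' @param ranges Optional list of two `c(lo, hi)` ranges; defaults to
#'   `center +/- 2 * step` when factor specifications are available.
#' @param fixed Named values for the remaining factors; defaults to their
#'   centers.
#'
#' @return A long-format data frame: the two varied factors and `yhat`.
#' @export
surface_slice <- function(model, pair, n = 30, ranges = NULL, fixed = NULL) {
  stopifnot(inherits(model, "quadratic_model"))
  nm <- model$factor_names
  if (is.numeric(pair)) pair <- nm[pair]
  if (length(pair) != 2L || anyDuplicated(pair) || !all(pair %in% nm))
    stop("'pair' must name two distinct model factors")
  others <- setdiff(nm, pair)
  centers <- if (!is.null(model$factors))
    stats::setNames(factor_centers(model$factors), nm)
  fixed_vals <- stats::setNames(numeric(length(others)), others)
  for (f in others) {
    fixed_vals[f] <- if (!is.null(fixed) && f %in% names(fixed)) fixed[[f]]
                     else if (!is.null(centers)) centers[f]
                     else stop("no fixed value for factor '", f,
                               "' and no factor specification to default from")
  }
  if (is.null(ranges)) {
    if (is.null(model$factors))
      stop("'ranges' must be given when the model has no factor specifications")
    steps <- stats::setNames(factor_steps(model$factors), nm)
    ranges <- lapply(pair, function(f) centers[f] + c(-2, 2) * steps[f])
  }
  stopifnot(length(ranges) == 2L, all(vapply(ranges, length, 0L) == 2L))
  g1 <- seq(ranges[[1L]][1L], ranges[[1L]][2L], length.out = n)
  g2 <- seq(ranges[[2L]][1L], ranges[[2L]][2L], length.out = n)
  grid <- expand.grid(g1, g2, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- pair
  pts <- matrix(0, nrow(grid), length(nm), dimnames = list(NULL, nm))
  pts[, pair[1L]] <- grid[[1L]]
  pts[, pair[2L]] <- grid[[2L]]
  for (f in others) pts[, f] <- fixed_vals[f]
  out <- grid
  out$yhat <- predict(model, pts)
  out
}
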