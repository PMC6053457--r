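#' Define a medium-component factor
#'
#' A factor is a named medium component with a concentration scale. Screening
#' factors carry the two levels of a Plackett-Burman design; CCD factors
#' carry a center concentration and the concentration change per coded unit,
#' so that coded level `z` corresponds to `center + z * step`.
#'
#' @param name Component name, e.g. `"yeast_extract"`.
#' @param role `"screening"` for a two-level factor, `"ccd"` for a
#'   five-level central-composite factor.
#' @param low,high Concentrations of the low (-1) and high (+1) screening
#'   levels. Required when `role = "screening"`.
#' @param center,step Center concentration and concentration per coded unit.
#'   Required when `role = "ccd"`.
#' @param units Unit label, `"g/100 ml"` by default.
#'
#' @return An object of class `factor_spec`.
#'
#' @details For screening factors the coded scale is derived from the two
#'   levels (`center = (low + high)/2`, `step = (high - low)/2`) so that
#'   coding maps `low` to -1 and `high` to +1.
#'
#' @examples
#' factor_spec("yeast_extract", "screening", low = 0.1, high = 0.3)
#' factor_spec("starch", "ccd", center = 0.8, step = 0.4)
#' @export
factor_spec <- function(name, role = c("screening", "ccd"),
                        low = NULL, high = NULL,
                        center = NULL, step = NULL,
                        units = "g/100 ml") {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (role == "screening") {
    if (is.null(low) || is.null(high))
      stop("screening factor '", name, "' needs 'low' and 'high' levels")
    if (!(high > low))
      stop("'high' must exceed 'low' for screening factor '", name, "'")
    center <- (low + high) / 2
    step <- (high - low) / 2
  } else {
    if (is.null(center) || is.null(step))
      stop("ccd factor '", name, "' needs 'center' and 'step'")
    if (!(step > 0))
      stop("'step' must be positive for ccd factor '", name, "'")
  }
  structure(
    list(name = name, units = units, role = role,
         low = low, high = high, center = center, step = step),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  if (x$role == "screening")
    cat(sprintf("factor '%s' (screening): %g / %g %s\n",
                x$name, x$low, x$high, x$units))
  else
    cat(sprintf("factor '%s' (ccd): center %g, step %g %s\n",
                x$name, x$center, x$step, x$units))
  invisible(x)
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")
factor_centers <- function(factors) vapply(factors, `[[`, numeric(1), "center")
factor_steps <- function(factors) vapply(factors, `[[`, numeric(1), "step")

check_factor_list <- function(factors, role = NULL) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  if (!length(factors) || !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("'factors' must be a list of factor_spec objects")
  if (!is.null(role)) {
    roles <- vapply(factors, `[[`, character(1), "role")
    if (any(roles != role))
      stop("all factors must have role '", role, "'")
  }
  nm <- factor_names(factors)
  if (anyDuplicated(nm)) stop("duplicated factor names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  factors
}

as_point_matrix <- function(x, factors) {
  nm <- factor_names(factors)
  if (is.data.frame(x)) {
    if (all(nm %in% names(x))) x <- x[, nm, drop = FALSE]
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) {
    if (length(x) != length(factors))
      stop("point length (", length(x), ") does not equal factor count (",
           length(factors), ")")
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != length(factors))
    stop("points have ", ncol(x), " coordinates but ", length(factors),
         " factors were given")
  storage.mode(x) <- "double"
  colnames(x) <- nm
  x
}

#' Convert between natural concentrations and coded design units
#'
#' Coded units place each factor on a symmetric scale around its center:
#' `coded = (natural - center) / step`. For screening factors the two levels
#' map to -1 and +1; for CCD factors the axial distance `alpha` maps to
#' `center + alpha * step`. `decode_points()` is the exact inverse.
#'
#' @param x A point (numeric vector of length `k`) or an `n x k` matrix or
#'   data frame of points, columns in factor order.
#' @param factors List of [factor_spec()] objects.
#'
#' @return A matrix of the same shape as `x` (a single point is returned as
#'   a 1-row matrix) in the other unit system.
#'
#' @examples
#' f <- list(factor_spec("a", "ccd", center = 0.4, step = 0.2),
#'           factor_spec("b", "ccd", center = 0.02, step = 0.01))
#' code_points(c(0.6, 0.01), f)       # +1, -1
#' decode_points(c(-2, 0), f)         # 0, 0.02
#' @export
code_points <- function(x, factors) {
  factors <- check_factor_list(factors)
  x <- as_point_matrix(x, factors)
  steps <- factor_steps(factors)
  if (any(steps == 0)) stop("zero step for factor(s): ",
                            paste(factor_names(factors)[steps == 0], collapse = ", "))
  sweep(sweep(x, 2L, factor_centers(factors), "-"), 2L, steps, "/")
}

#' @rdname code_points
#' @export
decode_points <- function(x, factors) {
  factors <- check_factor_list(factors)
  x <- as_point_matrix(x, factors)
  sweep(sweep(x, 2L, factor_steps(factors), "*"), 2L, factor_centers(factors), "+")
}
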