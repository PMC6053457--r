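# Seeded synthetic-data generators with the statistical structure each
# pipeline stage assumes: additive main effects on a two-level screening
# design, a known quadratic surface on a CCD, and Michaelis-Menten velocity
# curves. All generators are pure functions of their arguments and seed, and
# with zero noise the corresponding estimator recovers the planted
# parameters exactly.

#' Simulate responses on a Plackett-Burman design
#'
#' Generates `y = baseline + sum(effect_f / 2 * coded_f) + e` with iid
#' Gaussian noise, using the DOE effect convention (an effect is the mean
#' response at +1 minus the mean at -1), so [concentration_effect()] on a
#' noiseless simulation returns the planted effects exactly. Dummy columns
#' carry no signal unless explicitly given an effect.
#'
#' @param design A `pbd_design`.
#' @param effects Named numeric vector of planted concentration effects;
#'   names must match factor (or dummy) columns. Unnamed columns get 0.
#' @param baseline Mean response at the design center (U/ml). Default 1.98,
#'   the mean activity of the bundled screening table.
#' @param sd Standard deviation of the additive Gaussian noise (U/ml).
#' @param seed Optional seed.
#'
#' @return Numeric response vector, one value per run.
#' @export
simulate_pbd_response <- function(design, effects, baseline = 1.98,
                                  sd = 0.05, seed = NULL) {
  stopifnot(inherits(design, "doe_design"), sd >= 0)
  cols <- colnames(design$coded)
  effects <- effects[!is.na(names(effects))]
  unknown <- setdiff(names(effects), cols)
  if (length(unknown))
    stop("effects given for unknown column(s): ",
         paste(unknown, collapse = ", "))
  b <- stats::setNames(numeric(length(cols)), cols)
  b[names(effects)] <- effects
  mu <- baseline + drop(design$coded %*% (b / 2))
  with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
}

#' Simulate responses on a central composite design
#'
#' `y = predict(model, point) + e` with iid Gaussian noise; with `sd = 0`
#' refitting via [rsm_fit()] recovers the generating coefficients to
#' numerical precision.
#'
#' @param design A `ccd_design` (or any `doe_design`).
#' @param model A `quadratic_model` for the same factors.
#' @param sd Noise standard deviation (U/ml).
#' @param seed Optional seed.
#'
#' @return Numeric response vector, one value per run.
#' @export
simulate_ccd_response <- function(design, model, sd = 0.05, seed = NULL) {
  stopifnot(inherits(design, "doe_design"),
            inherits(model, "quadratic_model"), sd >= 0)
  pts <- if (model$units == "natural") design$natural else design$coded
  pts <- pts[, model$factor_names, drop = FALSE]
  mu <- predict(model, pts)
  with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
}

#' Simulate Michaelis-Menten kinetics data
#'
#' `v = Vmax * S / (Km + S)`, optionally perturbed by additive Gaussian
#' noise (`sd`, velocity units) or multiplicative noise
#' (`v * (1 + N(0, cv))`).
#'
#' @param km,vmax Michaelis constant (mM) and maximal velocity.
#' @param s Vector of substrate concentrations (mM), positive.
#' @param noise `"none"`, `"additive"` or `"multiplicative"`.
#' @param sd Additive noise standard deviation.
#' @param cv Coefficient of variation of multiplicative noise.
#' @param seed Optional seed.
#'
#' @return Data frame with columns `s` and `v`.
#'
#' @examples
#' simulate_mm_kinetics(0.043, 2.21, s = c(0.02, 0.043, 0.1))
#' @export
simulate_mm_kinetics <- function(km, vmax, s,
                                 noise = c("none", "additive", "multiplicative"),
                                 sd = 0.05, cv = 0.05, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(km > 0, vmax > 0, all(s > 0), sd >= 0, cv >= 0)
  v <- vmax * s / (km + s)
  v <- with_seed(seed, switch(noise,
    none = v,
    additive = v + stats::rnorm(length(v), 0, sd),
    multiplicative = v * (1 + stats::rnorm(length(v), 0, cv))))
  data.frame(s = as.numeric(s), v = v)
}
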