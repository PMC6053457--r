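# Plackett-Burman screening statistics.
#
# The concentration effect of a two-level factor is the difference between
# the mean response at its high level and at its low level,
#   E = (sum of high-level responses - sum of low-level responses) / (N/2),
# the experimental error variance is estimated from the effects of the
# unassigned (dummy) columns, V_eff = sum(E_d^2)/n_dummies, and each factor
# is tested with t = E / sqrt(V_eff).

check_balanced <- function(coded) {
  ok <- apply(coded, 2L, function(z) all(z %in% c(-1, 1)) && sum(z) == 0)
  if (!all(ok))
    stop("unbalanced or non two-level column(s): ",
         paste(colnames(coded)[!ok], collapse = ", "))
  invisible(TRUE)
}

effects_all_columns <- function(design, response) {
  if (is.null(response)) stop("no response attached to the design")
  if (length(response) != nrow(design$coded))
    stop("'response' must have one value per run")
  check_balanced(design$coded)
  drop(crossprod(design$coded, response)) / (nrow(design$coded) / 2)
}

#' Concentration effect of screening factors
#'
#' Computes, for each factor (and dummy column) of a balanced two-level
#' design, the difference between the mean response at the high and at the
#' low level.
#'
#' @param design A `pbd_design` (or any balanced two-level `doe_design`).
#' @param response Response vector; defaults to the one attached to the
#'   design.
#' @param factor Optional single factor (or dummy column) name; if given,
#'   only that effect is returned.
#'
#' @return Named numeric vector of effects in response units.
#' @export
concentration_effect <- function(design, response = design$response,
                                 factor = NULL) {
  stopifnot(inherits(design, "doe_design"))
  eff <- effects_all_columns(design, response)
  if (!is.null(factor)) {
    if (!factor %in% names(eff)) stop("unknown factor '", factor, "'")
    return(eff[factor])
  }
  eff
}

#' Experimental-error variance from dummy columns
#'
#' Estimates the variance of a concentration effect from the effects of the
#' unassigned (dummy) columns of a Plackett-Burman design:
#' `V_eff = sum(E_d^2) / n_dummies`, and the standard error as its square
#' root. A known `v_eff` (e.g. one printed in a report whose dummy
#' assignment is not recoverable) can be supplied and is then used verbatim.
#'
#' @inheritParams concentration_effect
#' @param v_eff Optional override for the variance of an effect.
#'
#' @return A list with `v_eff`, `se`, the per-dummy `dummy_effects` (NULL
#'   when an override is used) and `n_dummies`.
#' @export
dummy_variance <- function(design, response = design$response, v_eff = NULL) {
  stopifnot(inherits(design, "doe_design"))
  if (!is.null(v_eff)) {
    stopifnot(is.numeric(v_eff), length(v_eff) == 1L, v_eff >= 0)
    return(list(v_eff = v_eff, se = sqrt(v_eff), dummy_effects = NULL,
                n_dummies = length(design$dummies)))
  }
  if (!length(design$dummies))
    stop("design has no dummy columns and no 'v_eff' override was supplied; ",
         "the experimental error cannot be estimated")
  eff <- effects_all_columns(design, response)
  ed <- eff[design$dummies]
  v <- sum(ed^2) / length(ed)
  list(v_eff = v, se = sqrt(v), dummy_effects = ed, n_dummies = length(ed))
}

#' t statistics and one- or two-tailed p values for screening effects
#'
#' @param effects Named numeric vector of concentration effects.
#' @param se Standard error of an effect (scalar).
#' @param df Degrees of freedom of the reference t distribution.
#' @param tails 1 for the upper-tail probability of |t| (the convention of
#'   the bundled study), 2 for a two-tailed test.
#'
#' @return A data frame with columns `effect`, `t`, `p`.
#' @export
effect_ttest <- function(effects, se, df, tails = 1) {
  stopifnot(is.numeric(effects), length(se) == 1L, se >= 0, df >= 1,
            tails %in% c(1, 2))
  if (se == 0) {
    warning("standard error is zero; t set to +/-Inf and p to 0")
    t <- ifelse(effects == 0, 0, sign(effects) * Inf)
    p <- ifelse(effects == 0, if (tails == 1) 0.5 else 1, 0)
  } else {
    t <- effects / se
    p <- tails * stats::pt(abs(t), df = df, lower.tail = FALSE)
  }
  data.frame(effect = effects, t = t, p = pmin(p, 1),
             row.names = names(effects))
}

#' Plackett-Burman screening report
#'
#' Runs the full screening analysis: per-factor concentration effects,
#' dummy-column error variance (or a supplied override), t statistics and
#' p values, ranked by |t| with a significance flag at the configured
#' confidence level.
#'
#' @inheritParams dummy_variance
#' @param tails,df Passed to [effect_ttest()]. `df` defaults to
#'   `n_runs - 2`, which reproduces the p values of the bundled study;
#'   `length(design$dummies)` is the conventional dummy-df alternative.
#' @param conf Confidence level; a factor is flagged significant when
#'   `p <= 1 - conf`. The default 0.90 follows the screening rule of the
#'   bundled study.
#'
#' @return A data frame of class `pbd_screen` with columns `factor`,
#'   `effect`, `se`, `t`, `p`, `significant`, ranked by decreasing |t|
#'   (ties broken by input factor order). Attributes `v_eff`, `se`, `df`,
#'   `tails`, `conf` and `dummy_effects` carry the shared quantities.
#'
#' @examples
#' d <- cod_fixture("table1")
#' pbd_screen(d, v_eff = attr(d, "v_eff"))
#' @export
pbd_screen <- function(design, response = design$response, v_eff = NULL,
                       tails = 1, df = NULL, conf = 0.90) {
  stopifnot(inherits(design, "doe_design"), conf > 0, conf < 1)
  eff <- effects_all_columns(design, response)
  dv <- dummy_variance(design, response, v_eff)
  df <- df %||% (nrow(design$coded) - 2L)
  fnames <- factor_names(design$factors)
  tt <- effect_ttest(eff[fnames], dv$se, df = df, tails = tails)
  ord <- order(-abs(tt$t), seq_along(fnames))
  out <- data.frame(factor = fnames, effect = tt$effect, se = dv$se,
                    t = tt$t, p = tt$p,
                    significant = tt$p <= (1 - conf),
                    row.names = NULL)[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("pbd_screen", "data.frame"),
            v_eff = dv$v_eff, se = dv$se, df = df, tails = tails,
            conf = conf, dummy_effects = dv$dummy_effects)
}

#' @export
print.pbd_screen <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Plackett-Burman screening (V_eff = %.6g, S.E. = %.6g, df = %d, %s)\n",
    attr(x, "v_eff"), attr(x, "se"), attr(x, "df"),
    if (attr(x, "tails") == 1) "one-tailed" else "two-tailed"))
  print.data.frame(x, digits = digits, ...)
  cat(sprintf("significance: p <= %.2g\n", 1 - attr(x, "conf")))
  invisible(x)
}
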