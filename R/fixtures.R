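# Bundled fixtures: the printed tables of a published cholesterol oxidase
# medium-optimization study, stored exactly as printed (including their
# internal inconsistencies) under inst/extdata and returned as package
# domain objects.

cod_pbd_factors <- function() {
  list(
    factor_spec("yeast_extract", "screening", low = 0.1, high = 0.3),
    factor_spec("malt_extract", "screening", low = 0.25, high = 0.75),
    factor_spec("dextrose", "screening", low = 0.1, high = 0.3),
    factor_spec("calcium_carbonate", "screening", low = 0.05, high = 0.15),
    factor_spec("starch", "screening", low = 0.25, high = 0.75),
    factor_spec("ammonium_carbonate", "screening", low = 0.0025, high = 0.0075),
    factor_spec("sodium_carbonate", "screening", low = 0.0025, high = 0.0075))
}

cod_ccd_factors <- function() {
  list(
    factor_spec("yeast_extract", "ccd", center = 0.4, step = 0.2),
    factor_spec("dextrose", "ccd", center = 0.4, step = 0.2),
    factor_spec("starch", "ccd", center = 0.8, step = 0.4),
    factor_spec("ammonium_carbonate", "ccd", center = 0.02, step = 0.01))
}

# Ordered columns of the cyclic 12-run construction that reproduce the
# screening table's level combinations as a set of rows.
cod_pbd_assignment <- c(1L, 2L, 3L, 8L, 5L, 11L, 4L)

extdata <- function(file) {
  path <- system.file("extdata", file, package = "rsmga", mustWork = FALSE)
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("fixture file not found: ", file)
  path
}

#' Load a bundled study table as a package object
#'
#' Returns the printed tables of the bundled cholesterol oxidase
#' medium-optimization study as typed objects:
#'
#' * `"table1"` -- the 12-run, 7-factor Plackett-Burman screening design
#'   with measured activities (U/ml) attached, rows in printed order, dummy
#'   columns reconstructed from the standard cyclic construction, and the
#'   study's printed effect variance as attribute `v_eff` (0.001494).
#' * `"table2"` -- the 27-run, 4-factor central composite design with the
#'   observed activities as response; the printed predicted/residual
#'   columns are kept in attribute `printed`.
#' * `"table3-model"` -- the study's second-order polynomial as a
#'   [quadratic_model()] (natural units, intercept -0.1801).
#' * `"table4"` -- the printed ANOVA sums of squares and df as a data
#'   frame (see [anova_from_ss()]).
#' * `"table5"` -- purification steps: raw protein (mg) and total activity
#'   (U) plus the printed derived columns.
#' * `"table8"` -- substrate-specificity relative activities (percent).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3-model"`, `"table4"`,
#'   `"table5"`, `"table8"`.
#'
#' @return The corresponding domain object (see Details).
#'
#' @examples
#' d <- cod_fixture("table1")
#' d$response[10]   # 2.506
#' @export
cod_fixture <- function(name) {
  known <- c("table1", "table2", "table3-model", "table4", "table5", "table8")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  switch(name,
    "table1" = {
      factors <- cod_pbd_factors()
      d <- pbd_design(factors, assignment = cod_pbd_assignment)
      tab <- utils::read.csv(extdata("pbd_table1.csv"))
      k <- length(factors)
      printed_coded <- code_points(tab[, factor_names(factors)], factors)
      key <- function(m) apply(round(m), 1L, paste, collapse = "/")
      perm <- match(key(printed_coded), key(d$coded[, seq_len(k), drop = FALSE]))
      if (anyNA(perm) || anyDuplicated(perm))
        stop("internal error: screening fixture rows do not match the construction")
      d$coded <- d$coded[perm, , drop = FALSE]
      d$natural <- as.matrix(tab[, factor_names(factors)])
      d$response <- tab$response
      attr(d, "v_eff") <- 0.001494
      d
    },
    "table2" = {
      factors <- cod_ccd_factors()
      d <- suppressMessages(
        read_design_csv(extdata("ccd_table2.csv"), factors, alpha = 2))
      tab <- utils::read.csv(extdata("ccd_table2.csv"))
      d$response <- tab$observed
      attr(d, "printed") <- tab
      d
    },
    "table3-model" = {
      spec <- jsonlite::read_json(extdata("rsm_table3_model.json"),
                                  simplifyVector = TRUE)
      co <- unlist(spec$coefficients)
      m <- quadratic_model(co, cod_ccd_factors(), units = spec$units)
      stopifnot(identical(names(m$coefficients), names(co)))
      m
    },
    "table4" = utils::read.csv(extdata("anova_table4.csv")),
    "table5" = utils::read.csv(extdata("purification_table5.csv"),
                               check.names = FALSE),
    "table8" = utils::read.csv(extdata("substrate_table8.csv")))
}
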