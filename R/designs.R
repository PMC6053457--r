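# Construction of two-level Plackett-Burman and central composite designs.
#
# The 12-run Plackett-Burman design is built from the standard generator row
# (+ + - + + + - - - + -): rows 1..11 are its cyclic shifts, row 12 is all
# minus. Any subset of columns of this matrix is balanced and pairwise
# orthogonal.

pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

pb12_matrix <- function() {
  m <- matrix(0, 12L, 11L)
  for (i in 1:11) m[i, ] <- pb12_generator[((seq.int(0, 10) + (i - 1L)) %% 11L) + 1L]
  m[12L, ] <- -1
  m
}

new_doe_design <- function(factors, coded, natural, point_type,
                           response = NULL, dummies = character(0),
                           class = character(0)) {
  stopifnot(nrow(coded) == nrow(natural))
  if (!is.null(response) && length(response) != nrow(coded))
    stop("'response' must have one value per run")
  structure(
    list(factors = factors, coded = coded, natural = natural,
         point_type = point_type, response = response, dummies = dummies),
    class = c(class, "doe_design")
  )
}

#' Build a 12-run Plackett-Burman screening design
#'
#' Constructs the standard 12-run two-level Plackett-Burman design by cyclic
#' rotation of the generator row `+ + - + + + - - - + -` plus a final
#' all-minus row, binds up to 11 screening factors to its columns, and flags
#' the unassigned columns as dummy (error-estimating) columns.
#'
#' @param factors List of up to 11 screening [factor_spec()] objects.
#' @param n_runs Number of runs; only the 12-run construction is supported.
#' @param assignment Integer vector: which construction column (1..11) each
#'   factor occupies. Defaults to the first `k` columns.
#'
#' @return A `pbd_design` (also `doe_design`): a list with the factor list,
#'   the full 12 x 11 `coded` matrix (assigned factor columns first, then
#'   dummy columns `dummy1`, ...), the 12 x k `natural` concentration
#'   matrix, a `point_type` label per run, an optional `response` vector and
#'   the dummy column names.
#'
#' @examples
#' f <- list(factor_spec("yeast_extract", "screening", low = 0.1, high = 0.3),
#'           factor_spec("dextrose", "screening", low = 0.1, high = 0.3))
#' d <- pbd_design(f)
#' colSums(d$coded)  # every column balanced
#' @export
pbd_design <- function(factors, n_runs = 12, assignment = NULL) {
  factors <- check_factor_list(factors, role = "screening")
  k <- length(factors)
  if (k > 11L) stop("the 12-run Plackett-Burman design holds at most 11 factors")
  if (n_runs != 12L) stop("only the 12-run construction is supported")
  assignment <- assignment %||% seq_len(k)
  assignment <- as.integer(assignment)
  if (length(assignment) != k || anyDuplicated(assignment) ||
      any(assignment < 1L | assignment > 11L))
    stop("'assignment' must be ", k, " distinct column indices in 1..11")
  m <- pb12_matrix()
  dummy_cols <- setdiff(1:11, assignment)
  coded <- cbind(m[, assignment, drop = FALSE], m[, dummy_cols, drop = FALSE])
  dummies <- if (length(dummy_cols)) paste0("dummy", seq_along(dummy_cols))
             else character(0)
  colnames(coded) <- c(factor_names(factors), dummies)
  natural <- decode_points(coded[, seq_len(k), drop = FALSE], factors)
  new_doe_design(factors, coded, natural, rep("pbd", 12L),
                 dummies = dummies, class = "pbd_design")
}

# assign coded point types given the axial distance
classify_ccd_points <- function(coded, alpha, tol = 1e-8) {
  apply(coded, 1L, function(z) {
    nz <- abs(z) > tol
    if (!any(nz)) return("center")
    if (sum(nz) == 1L && abs(abs(z[nz]) - alpha) < tol) return("axial")
    if (all(abs(abs(z[nz]) - 1) < tol) && all(nz)) return("factorial")
    "other"
  })
}

#' Build a central composite design
#'
#' Combines two-level factorial points, `2k` axial (star) points at coded
#' distance `alpha`, and replicated center points into a five-level central
#' composite design.
#'
#' @param factors List of `k` ccd [factor_spec()] objects.
#' @param alpha Coded axial distance (> 0); 2 for the bundled study.
#' @param factorial Either `"half"` (regular half fraction with defining
#'   relation `I = x1 x2 ... xk`), `"full"`, or an explicit matrix of coded
#'   factorial points with entries in \{-1, +1\}.
#' @param n_center Number of center replicates.
#'
#' @return A `ccd_design` (also `doe_design`) with coded and natural run
#'   matrices and a `point_type` label (`factorial`, `axial`, `center`) per
#'   run.
#'
#' @details A warning is issued when `center - alpha * step` drops below
#'   zero for some factor, since concentrations cannot be negative.
#'   Duplicated runs are allowed only among center points; other duplicates
#'   trigger a warning.
#'
#' @examples
#' f <- list(factor_spec("yeast_extract", "ccd", center = 0.4, step = 0.2),
#'           factor_spec("dextrose", "ccd", center = 0.4, step = 0.2),
#'           factor_spec("starch", "ccd", center = 0.8, step = 0.4),
#'           factor_spec("ammonium_carbonate", "ccd", center = 0.02, step = 0.01))
#' d <- ccd_design(f, alpha = 2, factorial = "half", n_center = 11)
#' table(d$point_type)
#' @export
ccd_design <- function(factors, alpha = 2, factorial = "half", n_center = 6) {
  factors <- check_factor_list(factors, role = "ccd")
  k <- length(factors)
  if (!(alpha > 0)) stop("'alpha' must be positive")
  if (is.character(factorial)) {
    factorial <- match.arg(factorial, c("half", "full"))
    pts <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    if (factorial == "half") {
      if (k < 2L) stop("a half fraction needs at least 2 factors")
      pts <- pts[apply(pts, 1L, prod) == 1, , drop = FALSE]
    }
    fact <- pts
  } else {
    fact <- as.matrix(factorial)
    if (ncol(fact) != k) stop("factorial points must have ", k, " columns")
    if (!all(fact %in% c(-1, 1)))
      stop("factorial points must have coded entries in {-1, +1}")
  }
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, center)
  dimnames(coded) <- list(NULL, factor_names(factors))
  neg <- factor_centers(factors) - alpha * factor_steps(factors) < -1e-12
  if (any(neg))
    warning("axial point below zero concentration for factor(s): ",
            paste(factor_names(factors)[neg], collapse = ", "))
  point_type <- c(rep("factorial", nrow(fact)), rep("axial", 2L * k),
                  rep("center", n_center))
  key <- apply(coded, 1L, paste, collapse = "/")
  dup <- duplicated(key) & point_type != "center"
  if (any(dup)) warning("duplicated non-center run(s): ",
                        paste(which(dup), collapse = ", "))
  natural <- decode_points(coded, factors)
  new_doe_design(factors, coded, natural, point_type, class = "ccd_design")
}

#' Attach a response vector to a design
#'
#' @param design A `doe_design`.
#' @param response Numeric vector of responses (e.g. enzyme activity in
#'   U/ml), one per run.
#' @return The design with `$response` set.
#' @export
set_response <- function(design, response) {
  stopifnot(inherits(design, "doe_design"))
  if (length(response) != nrow(design$coded))
    stop("'response' must have one value per run (", nrow(design$coded), ")")
  design$response <- as.numeric(response)
  design
}

#' @export
as.data.frame.doe_design <- function(x, ...) {
  out <- as.data.frame(x$natural)
  out$point_type <- x$point_type
  if (!is.null(x$response)) out$response <- x$response
  out
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("%s: %d runs x %d factors (%s)\n",
              if (inherits(x, "pbd_design")) "Plackett-Burman design"
              else if (inherits(x, "ccd_design")) "Central composite design"
              else "Design",
              nrow(x$coded), length(x$factors),
              paste(factor_names(x$factors), collapse = ", ")))
  if (length(x$dummies))
    cat("dummy columns:", paste(x$dummies, collapse = ", "), "\n")
  if (!is.null(x$response)) cat("response attached (", length(x$response),
                                " values)\n", sep = "")
  invisible(x)
}

#' Read and write design tables as CSV
#'
#' Designs are exchanged as delimited text: one row per run, one column per
#' factor in natural concentration units, plus optional `response` and
#' `point_type` columns. Unknown extra columns are ignored with a message
#' (tolerant-reader policy); Unicode minus signs are normalized on ingest.
#'
#' @param path File path.
#' @param factors List of [factor_spec()] objects naming the required
#'   factor columns.
#' @param require_response Error if no `response` column is present.
#' @param alpha Axial distance used to classify point types for ccd factors
#'   when the file carries no `point_type` column.
#'
#' @return `read_design_csv()` returns a `doe_design`; `write_design_csv()`
#'   invisibly returns `path`.
#' @export
read_design_csv <- function(path, factors, require_response = FALSE, alpha = 2) {
  factors <- check_factor_list(factors)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  raw[] <- lapply(raw, function(col) gsub("−", "-", col))
  nm <- factor_names(factors)
  missing <- setdiff(nm, names(raw))
  if (length(missing))
    stop("design file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (require_response && !("response" %in% names(raw)))
    stop("design file '", path, "' is missing required column: response")
  known <- c(nm, "response", "point_type", "run")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    message("ignoring extra column(s) in '", path, "': ",
            paste(extra, collapse = ", "))
  num_cols <- intersect(c(nm, "response"), names(raw))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[cn]])))
    if (any(is.na(v)))
      stop("non-numeric value(s) in column '", cn, "' of '", path,
           "' at data row(s): ",
           paste(if (length(bad)) bad else which(is.na(v)), collapse = ", "))
    raw[[cn]] <- v
  }
  natural <- as.matrix(raw[, nm, drop = FALSE])
  coded <- code_points(natural, factors)
  roles <- vapply(factors, `[[`, character(1), "role")
  point_type <- if ("point_type" %in% names(raw)) raw$point_type
                else if (all(roles == "ccd")) classify_ccd_points(coded, alpha)
                else rep("pbd", nrow(natural))
  cls <- if (all(roles == "ccd")) "ccd_design"
         else if (all(roles == "screening")) "pbd_design" else character(0)
  new_doe_design(factors, coded, natural, point_type,
                 response = if ("response" %in% names(raw)) raw$response,
                 class = cls)
}

#' @rdname read_design_csv
#' @param design A `doe_design` to write.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "doe_design"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}
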