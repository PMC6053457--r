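# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a given RNG seed without disturbing the caller's stream.
# A NULL seed runs the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# coerce bounds given as 2 x k matrix, k x 2 matrix, or list of c(lo, hi)
as_bounds <- function(bounds, k = NULL) {
  if (is.list(bounds)) bounds <- do.call(cbind, bounds)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L && ncol(bounds) == 2L) bounds <- t(bounds)
  if (nrow(bounds) != 2L)
    stop("'bounds' must give a lower and an upper limit per factor",
         call. = FALSE)
  if (!is.null(k) && ncol(bounds) != k)
    stop(sprintf("'bounds' has %d columns but %d factors are expected",
                 ncol(bounds), k), call. = FALSE)
  if (any(!is.finite(bounds))) stop("'bounds' must be finite", call. = FALSE)
  if (any(bounds[1L, ] >= bounds[2L, ]))
    stop("each lower bound must be below its upper bound", call. = FALSE)
  bounds
}
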