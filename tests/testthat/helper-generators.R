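# shared builders for tests

ccd4_factors <- function() {
  list(
    factor_spec("yeast_extract", "ccd", center = 0.4, step = 0.2),
    factor_spec("dextrose", "ccd", center = 0.4, step = 0.2),
    factor_spec("starch", "ccd", center = 0.8, step = 0.4),
    factor_spec("ammonium_carbonate", "ccd", center = 0.02, step = 0.01))
}

pbd7_factors <- function() {
  list(
    factor_spec("yeast_extract", "screening", low = 0.1, high = 0.3),
    factor_spec("malt_extract", "screening", low = 0.25, high = 0.75),
    factor_spec("dextrose", "screening", low = 0.1, high = 0.3),
    factor_spec("calcium_carbonate", "screening", low = 0.05, high = 0.15),
    factor_spec("starch", "screening", low = 0.25, high = 0.75),
    factor_spec("ammonium_carbonate", "screening", low = 0.0025, high = 0.0075),
    factor_spec("sodium_carbonate", "screening", low = 0.0025, high = 0.0075))
}

# random concave quadratic in k dims with stationary point at `xs`;
# returns list(model, objective, xs, value_at_xs)
random_concave_quadratic <- function(k, xs = NULL) {
  m <- matrix(rnorm(k * k), k, k)
  B <- -(crossprod(m) + diag(0.5, k))       # negative definite
  xs <- xs %||% runif(k, -1, 1)
  a <- drop(-2 * B %*% xs)                  # gradient zero at xs
  b0 <- runif(1, -1, 1)
  nm <- paste0("x", seq_len(k))
  coefs <- c(b0, a, diag(B),
             if (k >= 2) apply(utils::combn(k, 2), 2,
                               function(ij) 2 * B[ij[1], ij[2]]))
  model <- quadratic_model(coefs, nm)
  list(model = model,
       objective = function(x) drop(b0 + sum(a * x) + t(x) %*% B %*% x),
       xs = xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
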