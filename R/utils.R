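# Internal helpers: scoped RNG and counter-based child seeds.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = env)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Deterministically folds one or more integer indices into a master seed
#' using a multiplicative-congruential mix modulo the Mersenne prime
#' 2^31 - 1.  Paired channels, subjects and surrogate realizations each get
#' their own stream while the whole study stays reproducible from a single
#' master seed.
#'
#' @param seed master seed (integer).
#' @param ... integer indices identifying the child stream (e.g. subject
#'   number, channel number, realization number).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' child_seed(42, 3, 1) != child_seed(42, 3, 2)
#' @export
child_seed <- function(seed, ...) {
  idx <- as.double(c(...))
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + (k %% 2147483647) * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}

# Least-squares slope of y ~ x with R^2, without lm() overhead.
ls_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(list(slope = NA_real_, intercept = NA_real_,
                                 r2 = NA_real_, n = length(x)))
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  yhat <- my + slope * (x - mx)
  ssr <- sum((y - yhat)^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  list(slope = slope, intercept = my - slope * mx, r2 = r2, n = length(x))
}
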