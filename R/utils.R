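# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every stochastic generator so identical seeds give
# bit-identical output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Adjusted Fisher-Pearson standardized moment coefficient (the usual
# spreadsheet/statistics-package skewness estimator).
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness needs n >= 3")
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - 1))
  if (s == 0) stop("constant input has undefined skewness")
  g1 <- sum((x - m)^3) / n / (sum((x - m)^2) / n)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Trapezoidal integral of y over (possibly decreasing) x, returned on the
# increasing-x orientation.
trapz_int <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
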