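#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stage seed from a base seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 37L + as.integer(offset)) %% 2147483629L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Convert scan age to the internal age axis (days since conception)
#'
#' Charts are parameterised on a single continuous axis, days since
#' conception, so that neonatal (postmenstrual weeks) and later-life (years
#' since birth) observations live on one scale. Years are mapped assuming a
#' 40-week (280-day) term gestation.
#'
#' @param age Numeric vector of ages.
#' @param unit `"years"` (age since birth) or `"pmweeks"` (postmenstrual
#'   weeks, i.e. weeks since conception).
#' @return Numeric vector of days since conception.
#' @export
age_to_days <- function(age, unit = c("years", "pmweeks")) {
  unit <- match.arg(unit)
  switch(unit,
    years   = 280 + age * 365.25,
    pmweeks = age * 7
  )
}

# Percentile bootstrap CI for a statistic over subject resampling.
# f(idx) must return a scalar given an index vector into 1..n.
boot_ci <- function(n, f, B, seed, level = 0.95) {
  if (B <= 0) return(c(NA_real_, NA_real_))
  stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) f(sample.int(n, n, replace = TRUE)),
           numeric(1))
  })
  stats <- stats[is.finite(stats)]
  a <- (1 - level) / 2
  unname(stats::quantile(stats, c(a, 1 - a), names = FALSE, type = 7))
}

# Spearman rho without the cor.test machinery (NA-safe, midrank ties).
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# Two-sided p for a Spearman correlation via the t approximation
# (midrank-tie safe; matches cor.test(..., exact = FALSE)).
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(rho = rho, p = p, n = n)
}
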