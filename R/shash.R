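#' The sinh-arcsinh (SHASH) location-scale-skew distribution
#'
#' Three-parameter family used for the normative charts: if `Z ~ N(0, 1)`,
#' then `X = mu + sigma * sinh(asinh(Z) + nu)` follows a SHASH distribution
#' with location `mu`, scale `sigma > 0` and skewness `nu` (`nu = 0` recovers
#' the Gaussian; positive `nu` skews right). The family has closed-form CDF
#' and quantile function,
#' `F(x) = pnorm(sinh(asinh((x - mu)/sigma) - nu))`, which is what deviation
#' scoring consumes.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param mu Location.
#' @param sigma Scale, `> 0`.
#' @param nu Skewness.
#' @param log Return log density?
#' @return `dshash` the density, `pshash` the CDF, `qshash` the quantile
#'   function, `rshash` random draws.
#' @examples
#' p <- c(0.05, 0.5, 0.95)
#' pshash(qshash(p, 2.5, 0.1, 0.3), 2.5, 0.1, 0.3)
#' @name shash
NULL

#' @rdname shash
#' @export
dshash <- function(x, mu, sigma, nu = 0, log = FALSE) {
  stopifnot(all(sigma > 0))
  r <- (x - mu) / sigma
  u <- asinh(r) - nu
  z <- sinh(u)
  ld <- stats::dnorm(z, log = TRUE) + log(cosh(u)) - log(sigma) -
    0.5 * log1p(r^2)
  if (log) ld else exp(ld)
}

#' @rdname shash
#' @export
pshash <- function(q, mu, sigma, nu = 0) {
  stopifnot(all(sigma > 0))
  stats::pnorm(sinh(asinh((q - mu) / sigma) - nu))
}

#' @rdname shash
#' @export
qshash <- function(p, mu, sigma, nu = 0) {
  stopifnot(all(sigma > 0))
  mu + sigma * sinh(asinh(stats::qnorm(p)) + nu)
}

#' @rdname shash
#' @export
rshash <- function(n, mu, sigma, nu = 0) {
  qshash(stats::runif(n), mu, sigma, nu)
}

# Negative log-likelihood of a SHASH regression:
#   mu  = Xl %*% beta   (low-order polynomial basis in log-age)
#   log sigma = Xs %*% gamma
#   nu  = constant (dropped when fix_nu)
shash_negll <- function(par, y, Xl, Xs, fix_nu = FALSE) {
  kl <- ncol(Xl); ks <- ncol(Xs)
  beta <- par[seq_len(kl)]
  gamma <- par[kl + seq_len(ks)]
  nu <- if (fix_nu) 0 else par[kl + ks + 1L]
  mu <- drop(Xl %*% beta)
  ls <- drop(Xs %*% gamma)
  if (any(!is.finite(mu)) || any(!is.finite(ls)) || any(ls > 50)) {
    return(1e10)
  }
  ll <- dshash(y, mu, exp(ls), nu, log = TRUE)
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}
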