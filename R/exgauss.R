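#' Shifted ex-Gaussian latency distribution
#'
#' Saccadic reaction times are modelled as `shift + N(mu, sigma^2) + Exp(tau)`:
#' a hard non-decision shift, a Gaussian component and an exponential tail.
#' `tau` is the mean of the exponential component, all parameters in
#' milliseconds. This is the latency law used by the two-process race
#' generator ([generate_srt_data()]) and by the bootstrap-coverage
#' simulations.
#'
#' @param x,q vector of latencies (ms).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param shift non-decision shift (ms), must be positive.
#' @param mu,sigma mean and sd of the Gaussian component (ms).
#' @param tau mean of the exponential component (ms).
#' @return `dexgauss`/`pexgauss` return densities/probabilities, `qexgauss`
#'   quantiles (ms), `rexgauss` random latencies (ms).
#' @examples
#' pexgauss(200, shift = 100, mu = 50, sigma = 30, tau = 70)
#' qexgauss(0.5, shift = 100, mu = 50, sigma = 30, tau = 70)
#' @name exgauss
NULL

check_exgauss_params <- function(shift, mu, sigma, tau) {
  if (shift <= 0) stop("`shift` must be positive", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (tau < 0) stop("`tau` must be nonnegative", call. = FALSE)
  invisible(NULL)
}

#' @rdname exgauss
#' @export
dexgauss <- function(x, shift, mu, sigma, tau) {
  check_exgauss_params(shift, mu, sigma, tau)
  z <- x - shift - mu
  if (tau < sigma * 1e-4) return(stats::dnorm(z, 0, sigma))
  # log-scale evaluation: the exp() factor overflows for latencies far into
  # the tail while the product stays finite
  lg <- sigma^2 / (2 * tau^2) - z / tau +
    stats::pnorm(z / sigma - sigma / tau, log.p = TRUE)
  exp(lg - log(tau))
}

#' @rdname exgauss
#' @export
pexgauss <- function(q, shift, mu, sigma, tau) {
  check_exgauss_params(shift, mu, sigma, tau)
  z <- q - shift - mu
  if (tau < sigma * 1e-4) return(stats::pnorm(z, 0, sigma))
  lg <- sigma^2 / (2 * tau^2) - z / tau +
    stats::pnorm(z / sigma - sigma / tau, log.p = TRUE)
  p <- stats::pnorm(z / sigma) - exp(lg)
  pmin(pmax(p, 0), 1)
}

#' @rdname exgauss
#' @export
qexgauss <- function(p, shift, mu, sigma, tau) {
  check_exgauss_params(shift, mu, sigma, tau)
  stopifnot(all(p >= 0 & p <= 1))
  lo <- shift + mu - 10 * sigma
  hi <- shift + mu + 10 * sigma + 20 * max(tau, 1)
  vapply(p, function(pp) {
    if (pp == 0) return(-Inf)
    if (pp == 1) return(Inf)
    stats::uniroot(function(q) pexgauss(q, shift, mu, sigma, tau) - pp,
                   lower = lo, upper = hi, tol = 1e-8, extendInt = "upX")$root
  }, numeric(1))
}

#' @rdname exgauss
#' @export
rexgauss <- function(n, shift, mu, sigma, tau) {
  check_exgauss_params(shift, mu, sigma, tau)
  shift + stats::rnorm(n, mu, sigma) + if (tau > 0) stats::rexp(n, 1 / tau) else 0
}
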