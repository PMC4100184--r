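## Log-densities, normalizers and samplers for the bounded and directional
## distributions used throughout the package: beta and gamma on (0,1)/(0,Inf),
## von Mises-Fisher and Watson on the unit hypersphere. Everything is
## evaluated in log space so that concentrations of several hundred neither
## overflow nor lose the normalizer.

#' Beta log-density
#'
#' Log-density of the beta distribution with shape parameters `u`, `v`,
#' evaluated through log-gamma (never a ratio of raw gamma values). The beta
#' law is the natural model for DNA methylation beta-values, which estimate
#' the methylated fraction of cells at a CpG and live on (0, 1).
#'
#' @param x numeric vector with values strictly inside (0, 1).
#' @param u,v positive shape parameters.
#' @return Numeric vector of log-densities.
#' @examples
#' betaLogPdf(0.3, 1, 1)   # uniform case: 0
#' @export
betaLogPdf <- function(x, u, v) {
  checkPositiveScalar(u, "u"); checkPositiveScalar(v, "v")
  if (any(x <= 0 | x >= 1)) stop("betaLogPdf: x must lie strictly in (0, 1)")
  stats::dbeta(x, u, v, log = TRUE)
}

#' Gamma log-density (shape/rate)
#'
#' @param x positive numeric vector.
#' @param shape,rate positive parameters; the mean is shape/rate.
#' @return Numeric vector of log-densities.
#' @export
gammaLogPdf <- function(x, shape, rate) {
  checkPositiveScalar(shape, "shape"); checkPositiveScalar(rate, "rate")
  if (any(x <= 0)) stop("gammaLogPdf: x must be positive")
  stats::dgamma(x, shape = shape, rate = rate, log = TRUE)
}

#' Log normalizing constant of the von Mises-Fisher distribution
#'
#' Returns \eqn{\ln c_K(\lambda)} where
#' \eqn{c_K(\lambda) = \lambda^{K/2-1} / ((2\pi)^{K/2} I_{K/2-1}(\lambda))},
#' evaluated with the exponentially scaled modified Bessel function so that
#' concentrations of several hundred do not overflow. At \eqn{\lambda = 0}
#' this is the log reciprocal surface area of the unit (K-1)-sphere.
#'
#' @param K integer ambient dimension, at least 2.
#' @param lambda nonnegative concentration.
#' @return Scalar \eqn{\ln c_K(\lambda)}.
#' @export
vmfLogNormalizer <- function(K, lambda) {
  if (K < 2) stop("vmfLogNormalizer: dimension K must be >= 2")
  if (lambda < 0) stop("vmfLogNormalizer: lambda must be nonnegative")
  nu <- K / 2 - 1
  if (lambda < 1e-8) {
    ## uniform limit: c_K(0) = Gamma(K/2) / (2 pi^{K/2})
    return(lgamma(K / 2) - log(2) - (K / 2) * log(pi))
  }
  nu * log(lambda) - (K / 2) * log(2 * pi) -
    (log(besselI(lambda, nu, expon.scaled = TRUE)) + lambda)
}

#' von Mises-Fisher log-density
#'
#' \eqn{\ln F(x | \mu, \lambda) = \ln c_K(\lambda) + \lambda \mu^T x} for
#' unit vectors x on the (K-1)-sphere. Inputs within 1e-8 of unit norm are
#' re-normalized; anything further off is rejected.
#'
#' @param x unit vector, or matrix with one unit vector per row.
#' @param mu unit mean direction.
#' @param lambda nonnegative concentration.
#' @param log logical; return log-density (default TRUE).
#' @return Numeric vector of (log-)densities, one per row of `x`.
#' @export
dvmf <- function(x, mu, lambda, log = TRUE) {
  mu <- drop(assertUnitRows(mu, what = "mu"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- assertUnitRows(x, what = "x")
  if (ncol(x) != length(mu)) stop("dvmf: dimension mismatch between x and mu")
  ld <- vmfLogNormalizer(length(mu), lambda) + lambda * drop(x %*% mu)
  if (log) ld else exp(ld)
}

#' Watson log-density
#'
#' Axially symmetric density on the unit (p-1)-sphere,
#' \deqn{W_p(x | \mu, \kappa) = \frac{\Gamma(p/2)}{2\pi^{p/2}}
#'       \, {}_1F_1(1/2, p/2, \kappa)^{-1} \, e^{\kappa (\mu^T x)^2},}
#' supporting concentrations of either sign: \eqn{\kappa > 0} concentrates
#' mass around the axis \eqn{\pm\mu}, \eqn{\kappa < 0} around the great
#' circle orthogonal to it. Because the exponent depends on x only through
#' \eqn{(\mu^T x)^2}, the axial symmetry f(x) = f(-x) holds bitwise.
#'
#' @param x unit vector, or matrix with one unit vector per row.
#' @param mu unit mean axis.
#' @param kappa real concentration (either sign).
#' @param log logical; return log-density (default TRUE).
#' @return Numeric vector of (log-)densities, one per row of `x`.
#' @export
dwatson <- function(x, mu, kappa, log = TRUE) {
  mu <- drop(assertUnitRows(mu, what = "mu"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- assertUnitRows(x, what = "x")
  p <- length(mu)
  if (ncol(x) != p) stop("dwatson: dimension mismatch between x and mu")
  if (p < 2) stop("dwatson: ambient dimension must be >= 2")
  lc <- lgamma(p / 2) - log(2) - (p / 2) * log(pi) -
    logKummer(0.5, p / 2, kappa)
  ld <- lc + kappa * drop(x %*% mu)^2
  if (log) ld else exp(ld)
}

## Uniform direction in the orthogonal complement of mu (mu unit K-vector).
#' @noRd
orthoUniform <- function(n, mu) {
  K <- length(mu)
  Z <- matrix(stats::rnorm(n * K), n, K)
  Z <- Z - tcrossprod(drop(Z %*% mu), mu)
  Z / sqrt(rowSums(Z^2))
}

#' Sample from the von Mises-Fisher distribution
#'
#' Draws unit vectors by the Wood/Ulrich rejection scheme: the component
#' along the mean direction comes from the 1-D marginal via a beta-based
#' envelope, the orthogonal part is uniform on the tangent sphere.
#'
#' @param n number of samples.
#' @param mu unit mean direction (length K >= 2).
#' @param lambda nonnegative concentration.
#' @param seed optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @return An n x K matrix of unit row vectors.
#' @export
rvmf <- function(n, mu, lambda, seed = NULL) {
  if (n < 1) stop("rvmf: n must be >= 1")
  mu <- drop(assertUnitRows(mu, what = "mu"))
  if (lambda < 0) stop("rvmf: lambda must be nonnegative")
  draw <- function() {
    K <- length(mu)
    if (lambda == 0) {
      Z <- matrix(stats::rnorm(n * K), n, K)
      return(Z / sqrt(rowSums(Z^2)))
    }
    b <- (-2 * lambda + sqrt(4 * lambda^2 + (K - 1)^2)) / (K - 1)
    x0 <- (1 - b) / (1 + b)
    cc <- lambda * x0 + (K - 1) * log(1 - x0^2)
    w <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- n - got
      Zb <- stats::rbeta(m, (K - 1) / 2, (K - 1) / 2)
      W <- (1 - (1 + b) * Zb) / (1 - (1 - b) * Zb)
      U <- stats::runif(m)
      ok <- (lambda * W + (K - 1) * log1p(-x0 * W) - cc) >= log(U)
      k <- sum(ok)
      if (k) {
        w[(got + 1L):(got + k)] <- W[ok]
        got <- got + k
      }
    }
    V <- orthoUniform(n, mu)
    w * matrix(mu, n, K, byrow = TRUE) + sqrt(pmax(0, 1 - w^2)) * V
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

## Inverse-CDF table for the Watson polar angle theta in [0, pi]:
## density proportional to exp(kappa cos^2 theta) sin^{p-2} theta.
#' @noRd
watsonAngleTable <- function(p, kappa, ngrid = 16385L) {
  th <- seq(0, pi, length.out = ngrid)
  lf <- kappa * cos(th)^2 + (p - 2) * log(pmax(sin(th), 1e-300))
  f <- exp(lf - max(lf))
  cdf <- cumsum((f[-1] + f[-ngrid]) / 2 * diff(th))
  cdf <- c(0, cdf / cdf[ngrid - 1L])
  list(theta = th, cdf = cdf)
}

#' Sample from the Watson distribution
#'
#' Draws unit vectors whose angle to the mean axis follows the exact polar
#' marginal (density proportional to \eqn{e^{\kappa\cos^2\theta}
#' \sin^{p-2}\theta}), sampled by inverse-CDF lookup on a dense quadrature
#' grid; the orthogonal part is uniform on the tangent sphere. Valid for
#' concentrations of either sign: positive \eqn{\kappa} concentrates samples
#' near \eqn{\pm\mu}, negative \eqn{\kappa} near the orthogonal great circle.
#'
#' @param n number of samples.
#' @param mu unit mean axis (length p >= 2).
#' @param kappa real concentration.
#' @param seed optional integer seed for reproducible draws.
#' @return An n x p matrix of unit row vectors.
#' @export
rwatson <- function(n, mu, kappa, seed = NULL) {
  if (n < 1) stop("rwatson: n must be >= 1")
  mu <- drop(assertUnitRows(mu, what = "mu"))
  p <- length(mu)
  if (p < 2) stop("rwatson: ambient dimension must be >= 2")
  tab <- watsonAngleTable(p, kappa)
  draw <- function() {
    u <- stats::runif(n)
    th <- stats::approx(tab$cdf, tab$theta, xout = u, ties = "ordered")$y
    t <- cos(th)
    V <- orthoUniform(n, mu)
    t * matrix(mu, n, p, byrow = TRUE) + sqrt(pmax(0, 1 - t^2)) * V
  }
  X <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  X / sqrt(rowSums(X^2))
}
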