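## Independent oracles used across the suite.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## 1-D quadrature of a polar-symmetric density on the (K-1)-sphere:
## integral over the sphere of g(mu' x) equals
## S_{K-2} * int_0^pi g(cos th) sin^{K-2} th dth, with S_{K-2} the surface
## area of the unit (K-2)-sphere.
sphereQuadrature <- function(g, K) {
  Sm2 <- 2 * pi^((K - 1) / 2) / gamma((K - 1) / 2)
  Sm2 * stats::integrate(function(th) g(cos(th)) * sin(th)^(K - 2),
                         0, pi, rel.tol = 1e-10)$value
}

## angle (degrees) between two directions, axially if axial = TRUE
angleDeg <- function(a, b, axial = FALSE) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (axial) ca <- abs(ca)
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

## clip helper mirroring the package-wide constant
clip01 <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)

## assert an ELBO trace never decreases by more than 1e-8 (relative)
expect_monotone_elbo <- function(e) {
  if (length(e) < 2L) return(invisible(TRUE))
  drops <- diff(e) < -1e-8 * (abs(e[-length(e)]) + 1)
  expect_equal(sum(drops), 0L)
}
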