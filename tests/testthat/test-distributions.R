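test_that("beta log-density matches log-gamma evaluation and symmetry", {
  expect_equal(betaLogPdf(0.3, 1, 1), 0)
  ## ln(Gamma(10)/(Gamma(5)^2) * 0.5^8), frozen from an independent
  ## log-gamma evaluation
  expect_equal(betaLogPdf(0.5, 5, 5), 0.9005424, tolerance = 1e-6)
  expect_equal(betaLogPdf(0.2, 2, 5), betaLogPdf(0.8, 5, 2))
  expect_error(betaLogPdf(0, 2, 2), "strictly")
  expect_error(betaLogPdf(0.5, -1, 2), "positive")
})

test_that("gamma log-density is shape/rate and normalized", {
  expect_equal(gammaLogPdf(1, 1, 1), -1)
  expect_equal(gammaLogPdf(2, 3, 1.5), -1.090458, tolerance = 1e-6)
  q <- stats::integrate(function(x) exp(gammaLogPdf(x, 2, 1)), 0, 50,
                        rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(gammaLogPdf(-1, 2, 2), "positive")
})

test_that("log Kummer 1F1 matches limiting cases and its own transform", {
  expect_equal(logKummer(0.5, 1.5, 0), 0)
  expect_equal(logKummer(2, 2, 3), 3)       # a = b collapses to exp(x)
  expect_equal(logKummer(0.5, 1.5, 10), 10 + logKummer(1, 1.5, -10),
               tolerance = 1e-10)
  expect_true(is.finite(logKummer(0.5, 1.5, 500)))
  expect_true(is.finite(logKummer(0.5, 7, -500)))
  expect_error(logKummer(0.5, -1, 2), "positive")
})

test_that("vMF normalizer agrees with closed forms and never overflows", {
  expect_equal(vmfLogNormalizer(3, 0), log(1 / (4 * pi)))
  expect_equal(vmfLogNormalizer(3, 1), log(1 / (4 * pi * sinh(1))))
  ## closed form c_3(lambda) = lambda / (4 pi sinh(lambda))
  for (lam in c(4, 40, 100))
    expect_equal(vmfLogNormalizer(3, lam),
                 log(lam) - log(4 * pi) - (lam - log(2)) -
                   log1p(-exp(-2 * lam)), tolerance = 1e-10)
  expect_true(is.finite(vmfLogNormalizer(3, 400)))
  expect_error(vmfLogNormalizer(1, 5), "K")
})

test_that("vMF log-density has the exponential-family shape", {
  mu <- c(0, 0, 1)
  x <- c(1, 0, 0)
  expect_equal(dvmf(x, mu, 0), log(1 / (4 * pi)))
  expect_equal(dvmf(mu, mu, 7) - dvmf(-mu, mu, 7), 14)
  set.seed(1)
  xs <- rvmf(50, mu, 0)
  expect_true(all(dvmf(xs, mu, 5) <= dvmf(mu, mu, 5)))
  expect_error(dvmf(c(1, 1, 1), mu, 5), "unit")
})

test_that("densities integrate to 1 across the concentration grid", {
  ## beta and gamma by adaptive quadrature
  for (p in list(c(5, 5), c(2, 5), c(0.2, 0.8))) {
    q <- stats::integrate(function(x) exp(betaLogPdf(x, p[1], p[2])),
                          0, 1, rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-3)
  }
  ## vMF and Watson by exact 1-D polar quadrature, for the concentrations
  ## at which directional data are typically visualized {0, 4, 40, 400}
  for (K in c(3, 4)) {
    mu <- c(rep(0, K - 1), 1)
    for (lam in c(0, 4, 40, 400)) {
      I <- sphereQuadrature(function(t)
        exp(vmfLogNormalizer(K, lam) + lam * t), K)
      expect_equal(I, 1, tolerance = 1e-3)
    }
    for (kap in c(-400, -40, -4, 0, 4, 40, 400)) {
      lc <- lgamma(K / 2) - log(2) - (K / 2) * log(pi) -
        logKummer(0.5, K / 2, kap)
      I <- sphereQuadrature(function(t) exp(lc + kap * t^2), K)
      expect_equal(I, 1, tolerance = 1e-3)
    }
  }
  ## Monte-Carlo sphere integral as an independent route (K = 4)
  set.seed(42)
  Z <- matrix(stats::rnorm(1e6 * 4), ncol = 4)
  Z <- Z / sqrt(rowSums(Z^2))
  area4 <- 2 * pi^2
  expect_equal(mean(dvmf(Z, c(1, 0, 0, 0), 5, log = FALSE)) * area4, 1,
               tolerance = 0.01)
})

test_that("Watson density is axially symmetric bitwise and finite", {
  mu <- c(1, 0, 0)
  expect_equal(dwatson(c(0, 0, 1), mu, 0), log(1 / (4 * pi)))
  set.seed(3)
  X <- rvmf(100, mu, 0)
  for (kap in c(-40, 4, 400))
    expect_identical(dwatson(X, mu, kap), dwatson(-X, mu, kap))
  ## no overflow across extreme parameters
  expect_true(all(is.finite(dwatson(X, mu, 500))))
  expect_true(all(is.finite(dvmf(X, mu, 500))))
})

test_that("vMF sampler is unit-norm, seeded, and matches Bessel moments", {
  mu <- c(0, 0, 1)
  X <- rvmf(1e4, mu, 400, seed = 11)
  expect_lt(max(abs(sqrt(rowSums(X^2)) - 1)), 1e-10)
  expect_identical(X, rvmf(1e4, mu, 400, seed = 11))
  mdir <- colMeans(X); mdir <- mdir / sqrt(sum(mdir^2))
  expect_lt(angleDeg(mdir, mu), 1)
  ## E[mu' x] = I_{K/2}(lam) / I_{K/2-1}(lam)
  X40 <- rvmf(1e4, mu, 40, seed = 12)
  ratio <- besselI(40, 1.5, expon.scaled = TRUE) /
    besselI(40, 0.5, expon.scaled = TRUE)
  expect_equal(mean(X40 %*% mu), ratio, tolerance = 0.01)
})

test_that("Watson sampler matches its exact marginal law", {
  mu <- c(0, 1, 0)
  X <- rwatson(5000, mu, 40, seed = 21)
  expect_lt(max(abs(sqrt(rowSums(X^2)) - 1)), 1e-10)
  expect_identical(X, rwatson(5000, mu, 40, seed = 21))
  expect_gt(mean(drop(X %*% mu)^2), 0.9)
  ## negative concentration pushes mass to the orthogonal great circle
  Xn <- rwatson(5000, mu, -40, seed = 22)
  expect_lt(mean(drop(Xn %*% mu)^2), 0.05)
  ## Kolmogorov-Smirnov of s = (mu' x)^2 against the quadrature CDF
  ## (p = 3: t = mu' x has density proportional to exp(kappa t^2))
  kap <- 4
  Xk <- rwatson(1e4, mu, kap, seed = 23)
  s <- drop(Xk %*% mu)^2
  norm <- stats::integrate(function(t) exp(kap * t^2), -1, 1,
                           rel.tol = 1e-10)$value
  cdfS <- function(q) vapply(q, function(qq)
    stats::integrate(function(t) exp(kap * t^2), -sqrt(qq), sqrt(qq),
                     rel.tol = 1e-10)$value / norm, numeric(1))
  ks <- suppressWarnings(stats::ks.test(s, cdfS))
  expect_gt(ks$p.value, 0.01)
})
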