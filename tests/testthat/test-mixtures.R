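## Simulated-data recovery oracles for the five clustering back-ends, plus
## the shared structural invariants (row-stochastic responsibilities,
## monotone ELBO surrogates, pruning monotonicity).

blobs3 <- function(n = 300, sep = 10, seed = 2) withr::with_seed(seed, {
  lab <- sample(1:3, n, TRUE)
  ctr <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  list(X = ctr[lab, ] + matrix(stats::rnorm(2 * n), n, 2), lab = lab)
})

betaMix3 <- function(n = 300, conc = 50, seed = 1) withr::with_seed(seed, {
  lab <- sample(1:3, n, TRUE)
  m <- c(0.1, 0.5, 0.9)[lab]
  X <- cbind(stats::rbeta(n, m * conc, (1 - m) * conc),
             stats::rbeta(n, m * conc, (1 - m) * conc))
  list(X = clip01(X), lab = lab)
})

test_that("VBGMM recovers separated Gaussian blobs and prunes", {
  d <- blobs3()
  fit <- fitVBGMM(t(d$X), Minit = 10, seed = 1)
  expect_equal(nComponents(fit), 3L)
  expect_gte(ari(clusterLabels(fit), d$lab), 0.95)
  expect_monotone_elbo(elboTrace(fit))
  expect_equal(sum(mixtureWeights(fit)), 1, tolerance = 1e-10)
  expect_equal(rowSums(responsibilities(fit)), rep(1, 300),
               tolerance = 1e-10)
  one <- fitVBGMM(t(withr::with_seed(3, matrix(rnorm(600), 300, 2))),
                  Minit = 10, seed = 1)
  expect_equal(nComponents(one), 1L)
  expect_error(fitVBGMM(matrix(rnorm(20), 10, 2), Minit = 2),
               "reduce the dimension")
})

test_that("VBBMM recovers planted beta components at the default settings", {
  d <- betaMix3()
  fit <- fitVBBMM(d$X, Minit = 15, prune = 0.01, seed = 1)
  expect_equal(nComponents(fit), 3L)
  expect_gte(ari(clusterLabels(fit), d$lab), 0.9)
  expect_monotone_elbo(elboTrace(fit))
  ## component means recovered within 0.05
  means <- sort(vapply(fit@params, function(p)
    mean(p$u / (p$u + p$v)), numeric(1)))
  expect_lt(max(abs(means - c(0.1, 0.5, 0.9))), 0.05)
  one <- fitVBBMM(clip01(withr::with_seed(4,
    matrix(stats::rbeta(600, 5, 5), 300, 2))), Minit = 15, seed = 1)
  expect_equal(nComponents(one), 1L)
  expect_error(fitVBBMM(matrix(c(0, 0.5, 0.5, 0.5), 2, 2)), "clip")
})

test_that("pruning threshold is monotone in the surviving count", {
  d <- betaMix3(n = 200, seed = 6)
  Ms <- vapply(c(0.001, 0.01, 0.2),
               function(p) nComponents(fitVBBMM(d$X, Minit = 10,
                                                prune = p, seed = 1)),
               integer(1))
  expect_true(all(diff(Ms) <= 0L))
})

test_that("RPBMM splits iff the weighted BIC improves", {
  Yu <- clip01(withr::with_seed(4, matrix(stats::rbeta(600, 5, 5), 200, 3)))
  expect_equal(nComponents(fitRPBMM(Yu, seed = 1)), 1L)
  d <- withr::with_seed(5, {
    lab <- sample(1:2, 200, TRUE)
    m <- c(0.1, 0.9)[lab]
    list(X = clip01(matrix(stats::rbeta(600, m * 30, (1 - m) * 30),
                           200, 3)), lab = lab)
  })
  fit <- fitRPBMM(d$X, seed = 1)
  expect_equal(nComponents(fit), 2L)
  expect_gte(ari(clusterLabels(fit), d$lab), 0.95)
  expect_identical(fit@extras$pathLabels, c("rL", "rR"))
  refit <- fitRPBMM(d$X, seed = 1)
  expect_identical(clusterLabels(refit), clusterLabels(fit))
})

test_that("VBvMM recovers concentrated directional clusters", {
  sim <- simulateDirectionalMixture("vmf", M = 3, K = 3, kappas = 400,
                                    n = 300, seed = 5)
  fit <- fitVBVMM(sim$X, Minit = 10, seed = 1)
  expect_equal(nComponents(fit), 3L)
  expect_gte(ari(clusterLabels(fit), sim$groupLabels), 0.95)
  expect_monotone_elbo(elboTrace(fit))
  ## recovered directions within 5 degrees of the planted axes
  for (p in fit@params) {
    best <- min(vapply(seq_len(3), function(m)
      angleDeg(p$mu, sim$axes[m, ]), numeric(1)))
    expect_lt(best, 5)
  }
  unif <- fitVBVMM(rvmf(300, c(0, 0, 1), 0, seed = 9), Minit = 10,
                   seed = 1)
  expect_lte(nComponents(unif), 2L)
  expect_gte(min(mixtureWeights(unif)), 0.2)
  expect_error(fitVBVMM(matrix(1, 5, 3)), "unit")
})

test_that("VBWMM is sign-invariant and models axial clusters", {
  Z <- rbind(rwatson(100, c(1, 0, 0), 40, seed = 31),
             rwatson(100, c(0, 1, 0), 40, seed = 32))
  lab <- rep(1:2, each = 100)
  fit <- fitVBWMM(Z, Minit = 10, seed = 1)
  expect_equal(nComponents(fit), 2L)
  expect_gte(ari(clusterLabels(fit), lab), 0.9)
  expect_monotone_elbo(elboTrace(fit))
  for (p in fit@params) {
    best <- min(angleDeg(p$mu, c(1, 0, 0), axial = TRUE),
                angleDeg(p$mu, c(0, 1, 0), axial = TRUE))
    expect_lt(best, 5)
  }
  flip <- withr::with_seed(7, sample(c(1, -1), 200, TRUE))
  fit2 <- fitVBWMM(Z * flip, Minit = 10, seed = 1)
  expect_identical(clusterLabels(fit2), clusterLabels(fit))
})

test_that("antipodal data split under vMF but fuse under Watson", {
  Zap <- rbind(rvmf(50, c(0, 0, 1), 200, seed = 11),
               rvmf(50, c(0, 0, -1), 200, seed = 12))
  expect_equal(nComponents(fitVBVMM(Zap, Minit = 6, seed = 1)), 2L)
  expect_equal(nComponents(fitVBWMM(Zap, Minit = 6, seed = 1)), 1L)
})
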