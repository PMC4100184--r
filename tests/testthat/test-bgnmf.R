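makeFit <- function(Abar, Bbar, Hbar) {
  ## BGNMFFit with rate 1 so posterior means equal the shape matrices
  new("BGNMFFit",
      Ashape = Abar, Arate = matrix(1, nrow(Abar), ncol(Abar)),
      Bshape = Bbar, Brate = matrix(1, nrow(Bbar), ncol(Bbar)),
      Hshape = Hbar, Hrate = matrix(1, nrow(Hbar), ncol(Hbar)),
      elbo = 0, K = ncol(Abar), iterations = 0L, converged = TRUE)
}

test_that("posterior-mean reconstruction matches the element-wise formula", {
  f <- makeFit(matrix(2, 1, 1), matrix(6, 1, 1), matrix(1, 1, 1))
  expect_equal(drop(reconstructMean(f)), 0.25)
  pb <- pseudoBasis(makeFit(matrix(1, 1, 1), matrix(3, 1, 1),
                            matrix(1, 1, 1)))
  expect_equal(drop(pb@W), 0.25)
  ## brute-force triple loop at P=5, T=4, K=3
  set.seed(7)
  A <- matrix(rgamma(15, 2), 5, 3); B <- matrix(rgamma(15, 2), 5, 3)
  H <- matrix(rgamma(12, 2), 3, 4)
  f2 <- makeFit(A, B, H)
  R <- reconstructMean(f2)
  for (p in 1:5) for (t in 1:4) {
    a <- sum(A[p, ] * H[, t]); b <- sum(B[p, ] * H[, t])
    expect_equal(R[p, t], a / (a + b), tolerance = 1e-12)
  }
  expect_true(all(R > 0 & R < 1))
})

test_that("a rank-1 bounded model reproduces a constant matrix", {
  X <- matrix(0.5, 50, 20)
  fit <- fitBGNMF(X, K = 1, maxIter = 150, seed = 1)
  expect_lt(max(abs(reconstructMean(fit) - 0.5)), 0.02)
  expect_monotone_elbo(elboTrace(fit))
})

test_that("fitting the transpose yields a samples-by-K pseudo-basis", {
  sim <- simulateGroupMethylation(P = 80, T = 24,
                                  groupSizes = c(8, 8, 8), seed = 3)
  fit <- fitBGNMF(t(betaValues(sim$X)), K = 4, maxIter = 60, seed = 1)
  pb <- pseudoBasis(fit)
  expect_equal(dim(pb@W), c(24L, 4L))      # samples x K
  expect_equal(dim(pb@H), c(4L, 80L))      # K x CpGs
  expect_true(all(pb@W > 0 & pb@W < 1))
  expect_true(all(pb@H > 0))
})

test_that("the generative-model simulation is recovered", {
  sim <- simulateBGNMFMatrix(P = 200, T = 60, K = 3, seed = 5)
  fit <- fitBGNMF(sim$X, K = 3, seed = 5)
  r <- stats::cor(c(reconstructMean(fit)), c(sim$trueMeanMatrix))
  expect_gte(r, 0.90)
  expect_monotone_elbo(elboTrace(fit))
  ## planted sample groups are recoverable from the pseudo-basis
  simg <- simulateBGNMFMatrix(P = 120, T = 60, K = 3, groupH = 3, seed = 9)
  fitg <- fitBGNMF(t(betaValues(simg$X)), K = 3, seed = 2)
  W <- pseudoBasis(fitg)@W
  km <- withr::with_seed(1, stats::kmeans(W, 3, nstart = 10))
  expect_gte(ari(km$cluster, simg$groupLabels), 0.8)
})

test_that("tightening the tolerance leaves converged quantities stable", {
  sim <- simulateBGNMFMatrix(P = 80, T = 30, K = 2, seed = 4)
  f1 <- fitBGNMF(sim$X, K = 2, tol = 1e-5, seed = 1)
  f2 <- fitBGNMF(sim$X, K = 2, tol = 1e-7, seed = 1)
  expect_lt(max(abs(reconstructMean(f1) - reconstructMean(f2))), 0.05)
})

test_that("input validation guards the bounded support", {
  X <- matrix(0.5, 10, 5); X[1, 1] <- 1
  expect_error(fitBGNMF(X, K = 2), "clip")
  expect_error(fitBGNMF(matrix(0.5, 10, 5), K = 6), "K must lie")
})
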