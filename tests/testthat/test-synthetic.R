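test_that("grouped methylation generator honors bounds, shift and seed", {
  sim <- simulateGroupMethylation(P = 300, T = 200,
                                  groupSizes = c(50, 50, 50, 50),
                                  delta = 0.25, seed = 11)
  X <- betaValues(sim$X)
  expect_true(all(X >= 1e-6 & X <= 1 - 1e-6))
  expect_identical(sampleClasses(sim$X)[1], "normal")
  ## empirical group-mean shift at DM CpGs close to delta
  g2rows <- sim$dmRows[seq_along(sim$dmRows) %% 4 == 1]
  d <- abs(rowMeans(X[g2rows, sim$groupLabels == 2]) -
             rowMeans(X[g2rows, sim$groupLabels == 1]))
  expect_lt(abs(mean(d) - 0.25), 0.03)
  ## bitwise determinism from the parameter record
  sim2 <- do.call(simulateGroupMethylation, sim$params)
  expect_identical(betaValues(sim2$X), X)
  expect_error(simulateGroupMethylation(P = 50, T = 20,
                                        groupSizes = c(10, 10),
                                        delta = 0.9), "delta")
  expect_error(simulateGroupMethylation(P = 50, T = 20,
                                        groupSizes = c(5, 5)), "sum")
})

test_that("the BG-NMF generator matches its own definition", {
  sim <- simulateBGNMFMatrix(P = 100, T = 100, K = 3, seed = 2)
  X <- betaValues(sim$X)
  expect_true(all(X > 0 & X < 1))
  ## symmetric priors: A and B exchangeable, grand mean 1/2
  expect_equal(mean(X), 0.5, tolerance = 0.02)
  a <- sim$A %*% sim$H; b <- sim$B %*% sim$H
  expect_equal(sim$trueMeanMatrix, a / (a + b), tolerance = 1e-12)
  sim2 <- simulateBGNMFMatrix(P = 100, T = 100, K = 3, seed = 2)
  expect_identical(X, betaValues(sim2$X))
})

test_that("directional mixture generator respects weights and geometry", {
  sim <- simulateDirectionalMixture("vmf", M = 3, K = 3, kappas = 40,
                                    weights = c(0.5, 0.3, 0.2),
                                    n = 1e4, seed = 3)
  expect_lt(max(abs(sqrt(rowSums(sim$X^2)) - 1)), 1e-10)
  cnt <- tabulate(sim$groupLabels, 3)
  for (m in 1:3) {
    p <- c(0.5, 0.3, 0.2)[m]
    expect_lt(abs(cnt[m] - 1e4 * p), 3 * sqrt(1e4 * p * (1 - p)))
  }
  ## axes pairwise separated by >= 60 degrees
  ca <- abs(tcrossprod(sim$axes)); diag(ca) <- 0
  expect_lte(max(ca), cos(pi / 3) + 1e-12)
  ## mean resultant length grows with concentration
  rl <- vapply(c(4, 40, 400), function(k) {
    s <- simulateDirectionalMixture("vmf", M = 1, K = 3, kappas = k,
                                    n = 2000, seed = 4)
    sqrt(sum(colMeans(s$X)^2))
  }, numeric(1))
  expect_true(all(diff(rl) > 0))
  expect_error(simulateDirectionalMixture("vmf", M = 9, K = 3), "components")
})

test_that("no planted structure means one recovered component", {
  hits <- vapply(1:20, function(s) {
    sim <- simulateGroupMethylation(P = 8, T = 60, groupSizes = c(20, 40),
                                    dmFraction = 0, seed = 100 + s)
    nComponents(fitVBBMM(t(betaValues(sim$X)), Minit = 8, seed = s))
  }, integer(1))
  expect_gte(mean(hits == 1L), 0.9)
})
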