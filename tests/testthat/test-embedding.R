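test_that("top-variance selection ranks rows and preserves order", {
  m <- rbind(rep(0.5, 3),                       # var 0
             c(0.4, 0.5, 0.6),                  # var 0.01
             c(0.3, 0.5, 0.7),                  # var 0.04
             c(0.45, 0.5, 0.55))                # var 0.0025
  dimnames(m) <- list(paste0("cg", 1:4), paste0("s", 1:3))
  sel <- selectTopVariance(m, 2)
  expect_identical(rownames(sel), c("cg2", "cg3"))  # original order kept
  expect_identical(selectTopVariance(m, 4), m)
  expect_error(selectTopVariance(m, 5), "n must lie")
  ## carries through the S4 container
  b <- BetaValueMatrix(m)
  expect_identical(rownames(selectTopVariance(b, 2)), c("cg2", "cg3"))
})

test_that("random-matrix theory separates noise from planted signal", {
  ksNoise <- vapply(1:20, function(s) withr::with_seed(s,
    estimateDimRMT(matrix(stats::rnorm(1000 * 100), 1000, 100))@K),
    integer(1))
  expect_gte(mean(ksNoise == 0L), 0.9)
  expect_true(all(ksNoise <= 1L))
  ks3 <- vapply(1:5, function(s) withr::with_seed(s, {
    X <- matrix(stats::rnorm(1000 * 100), 1000, 100)
    for (i in 1:3)
      X <- X + 10 * tcrossprod(stats::rnorm(1000), stats::rnorm(100)) /
        sqrt(100)
    estimateDimRMT(X)@K
  }), integer(1))
  expect_true(all(ks3 == 3L))
  est <- withr::with_seed(1,
    estimateDimRMT(matrix(stats::rnorm(50 * 30), 50, 30)))
  expect_lte(est@K, 30L)
  expect_warning(estimateDimRMT(rbind(rep(0.5, 10),
                                      matrix(runif(40), 4, 10))),
                 "constant")
})

test_that("PCA scores capture the top-eigenvalue variance", {
  ## collinear 2-D points: one component explains everything
  pts <- rbind(seq(0, 1, length.out = 20), 2 * seq(0, 1, length.out = 20))
  s1 <- pcaReduce(pts, 1)
  expect_equal(stats::var(drop(s1)) /
                 sum(diag(stats::cov(t(pts)))), 1, tolerance = 1e-10)
  set.seed(8)
  X <- matrix(stats::runif(60 * 25), 60, 25)
  ev <- eigen(stats::cov(t(X)), symmetric = TRUE, only.values = TRUE)$values
  for (K in c(2, 5)) {
    s <- pcaReduce(X, K)
    expect_equal(sum(apply(s, 1, stats::var)), sum(ev[seq_len(K)]),
                 tolerance = 1e-8)
    expect_equal(dim(s), c(K, 25L))
  }
  ## reconstruction error non-increasing in K
  errs <- vapply(1:6, function(K) {
    s <- pcaReduce(X, K)
    sum((X - rowMeans(X))^2) - sum(s^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("spectral embedding yields unit columns and separates blobs", {
  set.seed(5)
  pts <- cbind(matrix(stats::rnorm(40, 0, 0.5), 2, 20),
               matrix(stats::rnorm(40, 10, 0.5), 2, 20))
  colnames(pts) <- sprintf("p%02d", 1:40)
  Z <- spectralEmbed(pts, K = 2)
  expect_lt(max(abs(colSums(Z^2) - 1)), 1e-10)
  km <- withr::with_seed(1, stats::kmeans(t(Z), 2, nstart = 5))
  expect_equal(ari(km$cluster, rep(1:2, each = 20)), 1)
  ## permutation invariance of the induced clustering
  perm <- withr::with_seed(2, sample(40))
  Zp <- spectralEmbed(pts[, perm], K = 2)
  kmp <- withr::with_seed(1, stats::kmeans(t(Zp), 2, nstart = 5))
  expect_equal(ari(kmp$cluster[order(perm)], km$cluster), 1)
  expect_error(spectralEmbed(pts, K = 50), "K must lie")
  ## explicit sigma accepted; far-away sample with a tiny kernel width is
  ## reported as isolated
  expect_silent(spectralEmbed(pts, K = 2, sigma = 5))
  ptsIso <- cbind(pts, far = c(1e6, 1e6))
  expect_error(spectralEmbed(ptsIso, K = 2, sigma = 0.1), "isolated")
})
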