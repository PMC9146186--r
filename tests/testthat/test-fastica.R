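test_that("center_whiten yields identity covariance and flags degeneracy", {
  set.seed(21)
  X <- matrix(rnorm(4 * 5000), 4) * c(3, 0.5, 1, 2) + c(-1, 0, 2, 5)
  cw <- center_whiten(X)
  N <- ncol(X)
  covZ <- tcrossprod(cw$Z - rowMeans(cw$Z)) / (N - 1)
  expect_lt(max(abs(covZ - diag(4))), 1e-8)
  expect_lt(max(abs(rowMeans(cw$Z))), 1e-12)
  # already-white input: whitening is the identity up to sign
  W <- matrix(rnorm(2 * 20000), 2)
  W <- t(scale(t(W)))  # exact zero mean, unit variance rows
  cwW <- center_whiten(W)
  expect_lt(max(abs(abs(cwW$whitening) - diag(2))), 0.05)
  # rank-deficient covariance
  Xd <- rbind(X[1, ], X[1, ] * 2, X[2, ])
  expect_error(center_whiten(Xd), class = "fecg_degenerate_input")
  # 2x2 known mixing, uniform sources: sampling-error bound
  S <- matrix(runif(2 * 10000, -1, 1), 2)
  Z2 <- center_whiten(matrix(c(1, 0.4, 0.3, 1), 2) %*% S)$Z
  expect_lt(max(abs(tcrossprod(Z2) / (10000 - 1) - diag(2))), 0.05)
})

test_that("already-separated sources pass through up to permutation and sign", {
  S <- make_three_sources()[1:2, ]
  Z <- center_whiten(S)$Z
  res <- fastica_overrelaxed(Z, fastica_config(seed = 1))
  corr <- abs(cor(t(res$sources), t(S)))
  expect_true(all(apply(corr, 2, max) > 0.999))
})

test_that("seeded FastICA recovers a random 3-channel mixture", {
  S <- make_three_sources()
  set.seed(42)
  A <- matrix(runif(9, 0.5, 1.5) * sample(c(-1, 1), 9, TRUE), 3)
  cw <- center_whiten(A %*% S)
  res <- fastica_overrelaxed(cw$Z, fastica_config(seed = 7))
  expect_true(all(res$converged))
  corr <- abs(cor(t(res$sources), t(S)))
  expect_true(all(apply(corr, 2, max) >= 0.95))
  # whitened-space orthonormality of the unmixing rows
  expect_lt(max(abs(tcrossprod(res$unmixing) - diag(3))), 1e-6)
  # unit-variance, uncorrelated sources
  covS <- tcrossprod(res$sources - rowMeans(res$sources)) / (ncol(S) - 1)
  expect_lt(max(abs(covS - diag(3))), 1e-6)
  # Amari separation error of the global unmixing
  expect_lt(amari_error(res$unmixing %*% cw$whitening, A), 0.1)
  # deflation route finds the same sources
  defl <- fastica_overrelaxed(cw$Z, fastica_config(seed = 7, method = "deflation"))
  corr_d <- abs(cor(t(defl$sources), t(S)))
  expect_true(all(apply(corr_d, 2, max) >= 0.95))
})

test_that("over-relaxed and plain iterations share the fixed point", {
  S <- make_three_sources()
  A <- matrix(c(1, .5, .3, .4, 1, .6, .2, .7, 1), 3)
  Z <- center_whiten(A %*% S)$Z
  for (seed in c(2, 5, 9, 13, 17)) {
    r1 <- fastica_overrelaxed(Z, fastica_config(seed = seed, overrelax_lambda = 1))
    r15 <- fastica_overrelaxed(Z, fastica_config(seed = seed, overrelax_lambda = 1.5))
    cc <- abs(cor(t(r1$sources), t(r15$sources)))
    expect_true(all(apply(cc, 1, max) >= 0.999),
                label = sprintf("fixed-point match, seed %d", seed))
    expect_true(all(r15$converged))
  }
})

test_that("the separation API is seeded, deterministic and guarded", {
  S <- make_three_sources(8000)
  A <- matrix(c(1, .5, .3, .4, 1, .6, .2, .7, 1), 3)
  X <- A %*% S
  rec <- ecg_record(t(X), fs = 1000)
  r1 <- separate(rec, fastica_config(seed = 3))
  r2 <- separate(rec, fastica_config(seed = 3))
  expect_identical(r1, r2)
  # permutation of input channels yields the same source set
  recP <- ecg_record(t(X[c(2, 3, 1), ]), fs = 1000)
  rP <- separate(recP, fastica_config(seed = 3))
  cc <- abs(cor(t(rP$sources), t(r1$sources)))
  expect_true(all(apply(cc, 1, max) > 0.999))
  # guards
  expect_error(separate(ecg_record(matrix(rnorm(100), ncol = 1), 100)),
               class = "fecg_precondition_error")
  expect_error(fastica_overrelaxed(X, fastica_config(seed = 1)),
               class = "fecg_precondition_error")
})
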