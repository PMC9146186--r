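test_that("beat matrix construction follows the R-synchronized segmentation", {
  # exactly periodic signal: all rows identical, rank 1
  x <- rep(sin(2 * pi * (0:99) / 100), 8)
  peaks <- seq(100, 800, by = 100)
  bm <- build_beat_matrix(x, peaks, fs = 1000)
  expect_true(all(abs(sweep(bm$A, 2, bm$A[1, ])) < 1e-12))
  expect_equal(qr(bm$A)$rank, 1L)
  # hand-traced segmentation: peaks {101, 191, 301} on 400 samples,
  # pre-offset 0.3 * median(RR) = 30 -> segments of 90 and 110, n = 100
  y <- rnorm(400)
  bm2 <- build_beat_matrix(y, c(101L, 191L, 301L), fs = 1000)
  expect_equal(nrow(bm2$A), 2L)
  expect_equal(bm2$n, 100L)
  expect_equal(unname(bm2$seg_bounds[, "end"] - bm2$seg_bounds[, "start"]),
               c(90L, 110L))
  # guards
  expect_error(build_beat_matrix(y, c(10L, 50L)),
               class = "fecg_insufficient_beats")
  expect_error(build_beat_matrix(y, c(50L, 10L, 90L)),
               class = "fecg_ordering_error")
})

test_that("singular spectrum and its difference spectrum behave as defined", {
  s_id <- singular_spectrum(diag(3))
  expect_equal(s_id$values, c(1, 1, 1))
  expect_equal(s_id$diff_spectrum, c(0, 0))
  s_d <- singular_spectrum(diag(c(3, 1)))
  expect_equal(s_d$values, c(3, 1))
  expect_equal(s_d$diff_spectrum, 2)
  # rank-1 + small noise: the spectrum gap sits after the first value
  set.seed(8)
  A <- outer(rnorm(12), rnorm(20)) + matrix(rnorm(240, sd = 0.01), 12)
  expect_equal(which.max(singular_spectrum(A)$diff_spectrum), 1L)
})

test_that("rank truncation is the Eckart-Young optimum", {
  set.seed(99)
  # exact preservation cases
  r1 <- outer(rnorm(6), rnorm(9))
  expect_lt(max(abs(rank_truncate(r1, 1) - r1)), 1e-10)
  A <- matrix(rnorm(48), 6)
  expect_lt(max(abs(rank_truncate(A, 6) - A)), 1e-10)
  expect_error(rank_truncate(A, 0), class = "fecg_value_error")
  expect_error(rank_truncate(A, 7), class = "fecg_value_error")
  # Frobenius identity ||A - A_k||_F^2 = sum_{i>k} d_i^2, and rank(A_k) <= k
  for (rep in 1:10) {
    M <- matrix(rnorm(48), 6)
    d <- svd(M, nu = 0, nv = 0)$d
    for (k in c(1, 2, 4)) {
      Mk <- rank_truncate(M, k)
      expect_lt(abs(sum((M - Mk)^2) - sum(d[(k + 1):6]^2)), 1e-8)
      expect_lte(qr(Mk, tol = 1e-7)$rank, k)
    }
  }
})

test_that("beat inversion restores periodic signals and is local", {
  x <- rep(sin(2 * pi * (0:99) / 100), 8)
  peaks <- seq(100, 800, by = 100)
  bm <- build_beat_matrix(x, peaks, fs = 1000)
  back <- beats_to_signal(bm$A, bm)
  inside <- back != 0
  expect_lt(max(abs(back[inside] - x[inside])), 1e-9)
  # locality: modifying one row only changes its segment
  A2 <- bm$A
  A2[2, ] <- A2[2, ] + 1
  back2 <- beats_to_signal(A2, bm)
  seg2 <- bm$seg_bounds[2, "start"]:(bm$seg_bounds[2, "end"] - 1L)
  expect_true(all(back2[-seg2] == back[-seg2]))
  expect_true(all(back2[seg2] != back[seg2]))
  expect_error(beats_to_signal(bm$A[, -1], bm), class = "fecg_value_error")
})

test_that("the rank-2 estimate denoises a periodic signal", {
  set.seed(4)
  clean <- rep(sin(2 * pi * (0:99) / 100), 20)
  noise <- rnorm(length(clean), sd = 0.2)
  peaks <- seq(100, 1900, by = 100)
  est <- svd_estimate(clean + noise, peaks, k = 2, fs = 1000)
  inside <- est != 0
  rmse <- sqrt(mean((est[inside] - clean[inside])^2))
  expect_lt(rmse, 0.2)              # below the injected noise RMS
  expect_gt(cor(est[inside], clean[inside]), 0.99)
  # zero signal maps to zero
  expect_true(all(svd_estimate(numeric(2000), peaks, fs = 1000) == 0))
})

test_that("the rank-2 estimate of a clean fetal ECG preserves the waveform", {
  se <- synth_ecg(seed = 6, duration_s = 30)
  est <- svd_estimate(se$signal, se$r_peaks, k = 2, fs = 1000)
  inside <- est != 0
  expect_gte(cor(est[inside], se$signal[inside]), 0.99)
})
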