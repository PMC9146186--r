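fs <- 1000

test_that("the quadratic-spline transform matches its derivative semantics", {
  # constant signal: a derivative wavelet yields zero everywhere
  w0 <- swt_quadratic_spline(rep(3.3, 300), fs)
  expect_lt(max(abs(w0$coeffs)), 1e-10)
  # linear ramp: scale-1 coefficients constant (and nonzero) away from edges
  wr <- swt_quadratic_spline(as.numeric(1:2000), fs)
  mid <- wr$coeffs[200:1800, 1]
  expect_lt(max(abs(mid - mid[1])), 1e-9)
  expect_gt(abs(mid[1]), 0)
  # unit step at 500: every scale has its dominant modulus maximum within
  # 2^scale samples of the edge after delay alignment
  ws <- swt_quadratic_spline(c(rep(0, 500), rep(1, 1500)), fs)
  for (s in 1:4) {
    expect_lt(abs(which.max(abs(ws$coeffs[, s])) - 500), 2^s + 1)
  }
  expect_error(swt_quadratic_spline(rnorm(32), fs), class = "fecg_length_error")
})

test_that("an isolated peak produces one aligned negative/positive pole pair", {
  x <- exp(-((1:2000) - 1000)^2 / 50)
  w <- swt_quadratic_spline(x, fs)
  for (s in 1:4) {
    p <- find_mod_max_pairs(w, s, 1e-4, -1e-4, 0.2)
    expect_identical(nrow(p), 1L)
    expect_lt(p$neg_idx[1], p$pos_idx[1])
    expect_lte(abs(p$zero_idx[1] - 1000), 1)
    expect_true(p$neg_idx[1] < p$zero_idx[1] && p$zero_idx[1] < p$pos_idx[1])
  }
})

test_that("pole pairing keeps nearest pairs and deletes orphans", {
  # hand-built coefficient tracks stand in for a transform
  mk <- function(coef) {
    structure(list(coeffs = cbind(coef), delays = 0L, fs = fs),
              class = "wavelet_scales")
  }
  lobe <- function(center, amp, width = 5) {
    function(i) amp * exp(-(i - center)^2 / (2 * width^2))
  }
  i <- 1:400
  w1 <- mk(lobe(100, -1)(i) + lobe(110, 1)(i))
  p1 <- find_mod_max_pairs(w1, 1, 0.2, -0.2, 0.1)
  expect_identical(nrow(p1), 1L)
  expect_true(p1$zero_idx > 100 && p1$zero_idx < 110)
  # two negative lobes before one positive: the nearer negative wins,
  # the orphan is deleted
  w2 <- mk(lobe(80, -1)(i) + lobe(140, -1)(i) + lobe(170, 1)(i))
  p2 <- find_mod_max_pairs(w2, 1, 0.2, -0.2, 0.1)
  expect_identical(nrow(p2), 1L)
  expect_equal(p2$neg_idx, 140, tolerance = 1e-8)
  # all-zero coefficients: empty result
  expect_identical(nrow(find_mod_max_pairs(mk(numeric(400)), 1, 0.1, -0.1)), 0L)
})

test_that("R detection is exact on clean fetal signals across seeds", {
  for (seed in 1:4) {
    se <- synth_ecg(seed = seed)
    r <- detect_r_peaks(se$signal, fs)
    cnt <- match_peaks(as.integer(r), se$r_peaks, tol_s = 0.02, fs = fs)
    expect_identical(cnt$fp, 0L)
    expect_identical(cnt$fn, 0L)
    expect_identical(length(r), length(se$r_peaks))
  }
})

test_that("correction rules recover dropouts and reject spurious spikes", {
  se <- synth_ecg(seed = 11)
  x <- se$signal
  k <- 40L
  rk <- se$r_peaks[k]
  # attenuate one beat to 40%: the missed-detection gap rule must find it
  env <- 1 - 0.6 * exp(-((seq_along(x)) - rk)^2 / (2 * 40^2))
  xd <- x * env
  rd <- detect_r_peaks(xd, fs)
  expect_true(any(abs(as.integer(rd) - rk) <= 20))
  cntd <- match_peaks(as.integer(rd), se$r_peaks, tol_s = 0.02, fs = fs)
  expect_identical(cntd$fn, 0L)
  # a spurious spike 60 ms after a true R violates the 0.4 * mean RR rule
  # and the weaker pair is dropped
  spike <- 0.8 * exp(-((seq_along(x)) - (rk + 60))^2 / (2 * 5^2))
  rs <- detect_r_peaks(x + spike, fs)
  cnts <- match_peaks(as.integer(rs), se$r_peaks, tol_s = 0.02, fs = fs)
  expect_identical(cnts$fp, 0L)
  expect_identical(cnts$fn, 0L)
})

test_that("detection is amplitude-, polarity- and shift-invariant", {
  se <- synth_ecg(seed = 2)
  f1 <- delineate(se$signal, fs)
  expect_identical(delineate(se$signal * 37.3, fs)$beats, f1$beats)
  expect_identical(as.integer(detect_r_peaks(-se$signal, fs)),
                   as.integer(detect_r_peaks(se$signal, fs)))
  d <- 37L
  xs <- c(se$signal[(d + 1):length(se$signal)], rep(0, d))
  f3 <- delineate(xs, fs)
  shifted <- f3$beats$R + d
  expect_gte(length(intersect(f1$beats$R, shifted)) /
               max(length(f1$beats$R), length(shifted)), 0.98)
})

test_that("Q and S are localized on pronounced deflections and amplitude-gated", {
  pq <- data.frame(wave = c("P", "Q", "R", "S", "T"),
                   amp = c(0.12, -0.35, 1, -0.35, 0.25),
                   center_ms = c(-120, -14, 0, 14, 180),
                   sigma_ms = c(18, 6, 5, 6, 28))
  se <- synth_ecg(seed = 1, beat = gaussian_beat(params = pq))
  fid <- delineate(se$signal, fs)
  tr <- merge(fid$beats, se$fiducials, by = "R", suffixes = c(".d", ".t"))
  expect_gt(nrow(tr), 100)
  expect_true(all(abs(tr$Q.d - tr$Q.t) <= 10, na.rm = TRUE))
  expect_true(all(abs(tr$S.d - tr$S.t) <= 10, na.rm = TRUE))
  expect_gt(mean(!is.na(tr$Q.d)), 0.95)
  # Q amplitude at 1% of R fails the 5% validity rule
  pq$amp[2] <- -0.01
  se2 <- synth_ecg(seed = 1, beat = gaussian_beat(params = pq))
  fid2 <- delineate(se2$signal, fs)
  expect_true(all(is.na(fid2$beats$Q)))
})

test_that("QRS bounds land within 10 ms of the analytic truth", {
  for (seed in c(3, 8)) {
    se <- synth_ecg(seed = seed)
    fid <- delineate(se$signal, fs)
    true_dur <- stats::median((se$fiducials$QRS_off - se$fiducials$QRS_on) / fs,
                              na.rm = TRUE)
    expect_true(all(abs(fid$qrs_durations_s - true_dur) <= 0.010))
    # fetal durations stay inside the physiological 20-50 ms band
    expect_true(all(fid$qrs_durations_s >= 0.02 & fid$qrs_durations_s <= 0.05))
  }
})

test_that("P and T waves are found at scale 2 and vanish with the template", {
  se <- synth_ecg(seed = 5)
  fid <- delineate(se$signal, fs)
  tr <- merge(fid$beats, se$fiducials, by = "R", suffixes = c(".d", ".t"))
  expect_gt(mean(!is.na(tr$T_peak.d)), 0.95)
  expect_true(all(abs(tr$T_peak.d - tr$T_peak.t) <= 25, na.rm = TRUE))
  expect_gt(mean(!is.na(tr$P_peak.d)), 0.9)
  expect_true(all(abs(tr$P_peak.d - tr$P_peak.t) <= 25, na.rm = TRUE))
  # remove the T kernel: no T detections anywhere
  se0 <- synth_ecg(seed = 5, beat = gaussian_beat(t_amp = 0))
  fid0 <- delineate(se0$signal, fs)
  expect_true(all(is.na(fid0$beats$T_peak)))
})

test_that("full delineation keeps the fiducial ordering and measures ST shifts", {
  se <- synth_ecg(seed = 4)
  fid <- delineate(se$signal, fs)
  expect_fiducial_ordering(fid)
  expect_equal(60 / fid$rr_mean_s, 130, tolerance = 0.02)
  # +0.1 mV ST elevation is recovered within 0.02 mV
  x <- se$signal
  tq <- se$fiducials
  for (i in seq_len(nrow(tq))) {
    a <- tq$QRS_off[i]; b <- tq$T_on[i]
    if (is.na(a) || is.na(b) || b <= a) next
    idx <- (a - 5):(b + 5)
    env <- c(seq(0, 1, length.out = 5), rep(1, b - a + 1), seq(1, 0, length.out = 5))
    x[idx] <- x[idx] + 0.1 * env
  }
  fid_st <- delineate(x, fs)
  expect_gt(mean(fid_st$st_deviation_mv, na.rm = TRUE), 0.08)
  expect_lt(mean(fid_st$st_deviation_mv, na.rm = TRUE), 0.12)
  # degenerate input
  expect_error(suppressWarnings(delineate(numeric(5000), fs)),
               class = "fecg_insufficient_beats")
})

test_that("non-1000 Hz inputs are delineated via internal resampling", {
  se <- synth_ecg(fs = 500, duration_s = 30, seed = 9,
                  beat = gaussian_beat(fs = 500))
  fid <- delineate(se$signal, 500)
  cnt <- match_peaks(fid$beats$R, se$r_peaks, tol_s = 0.02, fs = 500)
  expect_identical(cnt$fp, 0L)
  expect_identical(cnt$fn, 0L)
  expect_equal(60 / fid$rr_mean_s, 130, tolerance = 0.03)
})
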