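#' Synthetic abdominal recording configuration
#'
#' Conditions emulating a term-pregnancy abdominal recording: four channels,
#' each a linear instantaneous mixture of a maternal ECG near 80 bpm and a
#' fetal ECG near 130 bpm whose R amplitude is a fraction of the maternal
#' one, plus sub-Hz baseline wander, powerline interference and white
#' noise.
#'
#' @param fs sampling rate, Hz (default 1000).
#' @param duration_s record length in seconds (>= 10; default 60).
#' @param maternal_hr_bpm,fetal_hr_bpm mean heart rates (defaults 80 and
#'   130; fetal must exceed maternal).
#' @param hr_jitter_pct uniform per-beat RR jitter in percent (default 3).
#' @param fetal_amp_ratio fetal-to-maternal R amplitude ratio on the
#'   channels, in (0, 1) (default 0.25).
#' @param n_channels abdominal channels (default 4).
#' @param baseline_amp_mv,baseline_hz baseline wander amplitude and
#'   frequency (defaults 0.2 mV at 0.3 Hz; must stay below 0.5 Hz).
#' @param powerline_amp_mv,powerline_hz powerline amplitude and frequency
#'   (defaults 0.05 mV at 50 Hz).
#' @param white_noise_mv white-noise standard deviation (default 0.02 mV).
#' @param seed RNG seed (default 1).
#' @export
synth_config <- function(fs = 1000, duration_s = 60, maternal_hr_bpm = 80,
                         fetal_hr_bpm = 130, hr_jitter_pct = 3,
                         fetal_amp_ratio = 0.25, n_channels = 4L,
                         baseline_amp_mv = 0.2, baseline_hz = 0.3,
                         powerline_amp_mv = 0.05, powerline_hz = 50,
                         white_noise_mv = 0.02, seed = 1L) {
  stopifnot(fs >= 250, duration_s >= 10, fetal_amp_ratio > 0,
            fetal_amp_ratio < 1, maternal_hr_bpm > 0,
            fetal_hr_bpm > maternal_hr_bpm, baseline_hz < 0.5,
            n_channels >= 2)
  structure(as.list(environment()), class = "synth_config")
}

#' Sum-of-Gaussians ECG beat template
#'
#' One-beat waveform built from five Gaussian kernels (P, Q, R, S, T) at
#' fixed phase offsets around the R peak, with analytic fiducial truth: peak
#' locations at the kernel centres, QRS onset/offset at the +/- 2 sigma
#' points of the Q and S kernels, P/T bounds at their +/- 2 sigma points.
#'
#' @param fs sampling rate (Hz).
#' @param qrs_ms target QRS duration in ms, in `[20, 120]`.
#' @param with_q,with_s include the Q / S kernels.
#' @param t_amp T-wave amplitude relative to R (0 removes the T wave).
#' @param params optional full override: data frame with columns `wave`,
#'   `amp`, `center_ms`, `sigma_ms`.
#' @return list with `template` (numeric), `r_idx` (index of the R peak
#'   within the template) and `truth` (named sample offsets relative to R:
#'   P_on, P_peak, P_off, Q, QRS_on, R, S, QRS_off, T_on, T_peak, T_off;
#'   absent waves are dropped).
#' @export
gaussian_beat <- function(fs = 1000, qrs_ms = 40, with_q = TRUE,
                          with_s = TRUE, t_amp = 0.25, params = NULL) {
  if (qrs_ms < 20 || qrs_ms > 120) {
    stop_fecg("fecg_value_error", "qrs_ms must be in [20, 120], got %g", qrs_ms)
  }
  if (is.null(params)) {
    scale <- qrs_ms / 40          # widen P/T offsets with slower QRS
    params <- data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      amp = c(0.12, if (with_q) -0.12 else 0, 1,
              if (with_s) -0.18 else 0, t_amp),
      center_ms = c(-120 * scale, -0.3 * qrs_ms, 0, 0.3 * qrs_ms, 180 * scale),
      sigma_ms = c(18 * scale, 0.1 * qrs_ms, qrs_ms / 8, 0.1 * qrs_ms,
                   28 * scale))
  }
  stopifnot(all(params$sigma_ms > 0))
  span_ms <- max(abs(params$center_ms) + 4 * params$sigma_ms)
  t_ms <- seq(-span_ms, span_ms, by = 1000 / fs)
  template <- numeric(length(t_ms))
  for (i in seq_len(nrow(params))) {
    template <- template + params$amp[i] *
      exp(-(t_ms - params$center_ms[i])^2 / (2 * params$sigma_ms[i]^2))
  }
  r_idx <- which.min(abs(t_ms))
  ms2samp <- function(ms) as.integer(round(ms * fs / 1000))
  g <- function(wave) params[params$wave == wave, , drop = FALSE]
  truth <- c(R = 0L)
  if (g("Q")$amp != 0) {
    truth["Q"] <- ms2samp(g("Q")$center_ms)
    truth["QRS_on"] <- ms2samp(g("Q")$center_ms - 2 * g("Q")$sigma_ms)
  }
  if (g("S")$amp != 0) {
    truth["S"] <- ms2samp(g("S")$center_ms)
    truth["QRS_off"] <- ms2samp(g("S")$center_ms + 2 * g("S")$sigma_ms)
  }
  if (g("P")$amp != 0) {
    truth["P_peak"] <- ms2samp(g("P")$center_ms)
    truth["P_on"] <- ms2samp(g("P")$center_ms - 2 * g("P")$sigma_ms)
    truth["P_off"] <- ms2samp(g("P")$center_ms + 2 * g("P")$sigma_ms)
  }
  if (g("T")$amp != 0) {
    truth["T_peak"] <- ms2samp(g("T")$center_ms)
    truth["T_on"] <- ms2samp(g("T")$center_ms - 2 * g("T")$sigma_ms)
    truth["T_off"] <- ms2samp(g("T")$center_ms + 2 * g("T")$sigma_ms)
  }
  list(template = template, r_idx = r_idx, truth = truth)
}

#' Synthesize a single-lead ECG with ground truth
#'
#' Places beat templates at RR intervals `60/HR * (1 + jitter)`, jitter
#' uniform within +/- `hr_jitter_pct` percent, from a seeded RNG.
#'
#' @param fs sampling rate (Hz).
#' @param duration_s length in seconds.
#' @param hr_bpm mean heart rate.
#' @param hr_jitter_pct uniform RR jitter, percent.
#' @param seed RNG seed (NULL: use the current RNG stream).
#' @param beat a [gaussian_beat] template list.
#' @return list with `signal`, `r_peaks` (1-based indices) and `fiducials`
#'   (per-beat data frame of absolute-truth sample indices).
#' @export
synth_ecg <- function(fs = 1000, duration_s = 60, hr_bpm = 130,
                      hr_jitter_pct = 3, seed = NULL,
                      beat = gaussian_beat(fs = fs)) {
  with_seed(seed, {
    n <- as.integer(round(duration_s * fs))
    rr_base <- 60 / hr_bpm
    t <- 0.1                       # beats at the edges are clipped, not dropped
    r_times <- numeric(0)
    while (t < duration_s - 0.1) {
      r_times <- c(r_times, t)
      jit <- if (hr_jitter_pct > 0) stats::runif(1, -hr_jitter_pct, hr_jitter_pct) / 100 else 0
      t <- t + rr_base * (1 + jit)
    }
    r_peaks <- as.integer(round(r_times * fs)) + 1L
    x <- numeric(n)
    tmpl <- beat$template
    for (r in r_peaks) {
      lo <- r - beat$r_idx + 1L
      hi <- lo + length(tmpl) - 1L
      dst <- max(1L, lo):min(n, hi)
      x[dst] <- x[dst] + tmpl[dst - lo + 1L]
    }
    fid <- as.data.frame(lapply(as.list(beat$truth), function(off) {
      v <- r_peaks + off
      v[v < 1L | v > n] <- NA_integer_
      v
    }))
    fid <- cbind(beat = seq_along(r_peaks), fid)
    list(signal = x, r_peaks = r_peaks, fiducials = fid)
  })
}

#' Synthesize a multichannel abdominal recording
#'
#' Maternal (wide-QRS, default 80 bpm) and fetal (narrow-QRS, default
#' 130 bpm) single-lead ECGs are mixed into `n_channels` abdominal channels
#' through a random instantaneous mixing matrix with entries in
#' `[0.5, 1.5]` (maternal column) and `[0.5, 1.5] * fetal_amp_ratio` (fetal
#' column), resampled until its condition number is below 50 so separation
#' is well posed. Each channel then receives baseline wander (random
#' phase), powerline interference and white noise.
#'
#' @param cfg a [synth_config].
#' @return object of class `synth_record`: `record` (an [ecg_record] with
#'   reference R lists), `sources` (list `maternal`, `fetal`, `noise` = the
#'   N x C additive noise), `mixing` (C x 2), `true_fiducials` (fetal
#'   per-beat truth), `maternal_fiducials`.
#' @export
synth_abdominal <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    maternal <- synth_ecg(cfg$fs, cfg$duration_s, cfg$maternal_hr_bpm,
                          cfg$hr_jitter_pct, seed = NULL,
                          beat = gaussian_beat(fs = cfg$fs, qrs_ms = 90,
                                               t_amp = 0.3))
    fetal <- synth_ecg(cfg$fs, cfg$duration_s, cfg$fetal_hr_bpm,
                       cfg$hr_jitter_pct, seed = NULL,
                       beat = gaussian_beat(fs = cfg$fs, qrs_ms = 40))
    C <- cfg$n_channels
    repeat {
      mixing <- cbind(maternal = stats::runif(C, 0.5, 1.5),
                      fetal = stats::runif(C, 0.5, 1.5) * cfg$fetal_amp_ratio)
      d <- svd(mixing, nu = 0, nv = 0)$d
      if (d[1] / d[2] < 50) break
    }
    S <- cbind(maternal$signal, fetal$signal)
    clean <- S %*% t(mixing)
    N <- nrow(clean)
    tt <- (seq_len(N) - 1) / cfg$fs
    noise <- matrix(0, N, C)
    for (c in seq_len(C)) {
      noise[, c] <-
        cfg$baseline_amp_mv * sin(2 * pi * cfg$baseline_hz * tt + stats::runif(1, 0, 2 * pi)) +
        cfg$powerline_amp_mv * sin(2 * pi * cfg$powerline_hz * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(N, sd = cfg$white_noise_mv)
    }
    rec <- ecg_record(clean + noise, cfg$fs,
                      channel_names = paste0("abd", seq_len(C)),
                      ref_fetal_r = fetal$r_peaks,
                      ref_maternal_r = maternal$r_peaks)
    structure(list(record = rec,
                   sources = list(maternal = maternal$signal,
                                  fetal = fetal$signal, noise = noise),
                   mixing = mixing,
                   true_fiducials = fetal$fiducials,
                   maternal_fiducials = maternal$fiducials,
                   config = cfg),
              class = "synth_record")
  })
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf("<synth_record> %d channels, %.0f s @ %g Hz; maternal %g bpm, fetal %g bpm (amp ratio %g)\n",
              n_channels(x$record), n_samples(x$record) / x$record$fs,
              x$record$fs, x$config$maternal_hr_bpm, x$config$fetal_hr_bpm,
              x$config$fetal_amp_ratio))
  invisible(x)
}
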