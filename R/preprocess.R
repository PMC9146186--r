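#' Preprocessing configuration
#'
#' Parameters of the artifact-suppression chain applied before source
#' separation: dual running-median baseline removal, a zero-phase IIR notch
#' at the powerline frequency, and MAD-based pulse-artifact clipping. This
#' chain is the package's own standard substitute for unpublished clinical
#' preprocessing pipelines; every stage can be disabled.
#'
#' @param powerline_hz powerline frequency, 50 (default) or 60 Hz.
#' @param notch_q notch quality factor (centre frequency / -3 dB bandwidth).
#' @param baseline_win1_s,baseline_win2_s windows (s) of the two cascaded
#'   running-median filters estimating the baseline; win1 < win2.
#' @param artifact_k MAD multiples beyond which a sample is treated as a
#'   pulse artifact and interpolated over.
#' @param do_baseline,do_notch,do_artifacts stage switches.
#' @export
preprocess_config <- function(powerline_hz = 50, notch_q = 30,
                              baseline_win1_s = 0.2, baseline_win2_s = 0.6,
                              artifact_k = 8,
                              do_baseline = TRUE, do_notch = TRUE,
                              do_artifacts = TRUE) {
  stopifnot(powerline_hz %in% c(50, 60), notch_q > 0,
            baseline_win1_s > 0, baseline_win1_s < baseline_win2_s,
            artifact_k > 0)
  structure(list(powerline_hz = powerline_hz, notch_q = notch_q,
                 baseline_win1_s = baseline_win1_s,
                 baseline_win2_s = baseline_win2_s,
                 artifact_k = artifact_k,
                 do_baseline = do_baseline, do_notch = do_notch,
                 do_artifacts = do_artifacts),
            class = "preprocess_config")
}

#' Remove baseline drift
#'
#' Subtracts a baseline estimate formed by two cascaded running-median
#' filters (default windows 0.2 s then 0.6 s, odd sample counts). The short
#' window removes QRS complexes from the estimate, the long one smooths the
#' drift; narrow deflections survive in the residual while sub-Hz wander is
#' suppressed.
#'
#' @param x single-channel signal.
#' @param fs sampling rate (Hz).
#' @param cfg a [preprocess_config].
#' @return signal of the same length.
#' @export
remove_baseline <- function(x, fs, cfg = preprocess_config()) {
  w2 <- odd_window(fs * cfg$baseline_win2_s)
  if (length(x) <= w2) {
    stop_fecg("fecg_length_error",
              "signal (%d samples) shorter than baseline window (%d)",
              length(x), w2)
  }
  w1 <- odd_window(fs * cfg$baseline_win1_s)
  base <- stats::runmed(stats::runmed(x, w1, endrule = "median"),
                        w2, endrule = "median")
  as.numeric(x - base)
}

#' Notch out powerline interference
#'
#' Second-order IIR notch (constrained biquad) at the powerline frequency,
#' applied forward-backward ([signal::filtfilt]) for zero phase distortion.
#'
#' @inheritParams remove_baseline
#' @export
notch_powerline <- function(x, fs, cfg = preprocess_config()) {
  f0 <- cfg$powerline_hz
  if (fs <= 2 * f0) {
    stop_fecg("fecg_value_error", "fs (%g) must exceed twice the notch frequency (%g)", fs, f0)
  }
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * cfg$notch_q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]
  a <- a / a[1]
  # odd-reflection padding suppresses the forward-backward edge transients
  # (the notch ring-down lasts ~Q/f0 seconds)
  pad <- min(length(x) - 1L, as.integer(round(2 * fs * cfg$notch_q / f0)))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[length(x)] - rev(x[(length(x) - pad):(length(x) - 1L)]))
  y <- as.numeric(signal::filtfilt(b, a, xp))
  y[(pad + 1L):(pad + length(x))]
}

#' Suppress pulse artifacts
#'
#' Samples deviating from the signal median by more than `artifact_k` MADs
#' are replaced by linear interpolation between the nearest unflagged
#' neighbours. Pulse artifacts are rare events by definition: when more
#' than `artifact_max_frac` of the samples flag (as happens on a clean
#' low-variance ECG whose every QRS complex exceeds the MAD band), the
#' artifact model does not fit the signal and the stage returns it
#' unchanged; above 50% the signal is reported degenerate.
#'
#' @inheritParams remove_baseline
#' @param artifact_max_frac flagged-sample fraction above which the stage
#'   declines to act (default 0.02).
#' @export
suppress_artifacts <- function(x, fs, cfg = preprocess_config(),
                               artifact_max_frac = 0.02) {
  if (length(x) < fs) {
    stop_fecg("fecg_length_error", "need at least one second of signal")
  }
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv == 0) return(x)
  bad <- abs(x - med) > cfg$artifact_k * madv
  if (!any(bad)) return(x)
  if (mean(bad) > 0.5) {
    stop_fecg("fecg_degenerate_signal",
              "%.0f%% of samples flagged as artifacts; signal is degenerate",
              100 * mean(bad))
  }
  if (mean(bad) > artifact_max_frac) return(x)
  idx <- which(!bad)
  x[bad] <- stats::approx(idx, x[idx], xout = which(bad), rule = 2)$y
  x
}

#' Full preprocessing chain for one channel
#'
#' @inheritParams remove_baseline
#' @export
preprocess_signal <- function(x, fs, cfg = preprocess_config()) {
  if (cfg$do_baseline)  x <- remove_baseline(x, fs, cfg)
  if (cfg$do_notch)     x <- notch_powerline(x, fs, cfg)
  if (cfg$do_artifacts) x <- suppress_artifacts(x, fs, cfg)
  x
}

#' Preprocess every channel of a record
#'
#' @param record an [ecg_record].
#' @param cfg a [preprocess_config].
#' @return an [ecg_record] with filtered channels (annotations preserved).
#' @export
preprocess_record <- function(record, cfg = preprocess_config()) {
  out <- apply(record$data, 2L, preprocess_signal, fs = record$fs, cfg = cfg)
  ecg_record(out, record$fs, channel_names = record$channel_names,
             ref_fetal_r = record$ref_fetal_r,
             ref_maternal_r = record$ref_maternal_r)
}
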