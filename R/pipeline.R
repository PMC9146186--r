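#' Label independent components as maternal, fetal or noise
#'
#' The dominant beat rate of each source is estimated from the
#' autocorrelation of its squared, smoothed amplitude: the fundamental
#' period is the smallest strong autocorrelation peak with lag in the
#' physiological range. Sources with a dominant rate in 55-105 bpm are
#' labelled maternal, 110-180 bpm fetal, anything else (or too weak a
#' periodicity) noise. At most one maternal and one fetal label are
#' assigned; the highest periodicity score wins.
#'
#' @param sources K x N matrix of unit-variance sources (rows).
#' @param fs sampling rate (Hz).
#' @param min_score minimum autocorrelation peak for a source to count as
#'   periodic (default 0.1).
#' @return character vector of labels (`"maternal"`, `"fetal"`, `"noise"`),
#'   with the per-source rates and scores in attributes `rate_bpm` and
#'   `score`.
#' @export
classify_components <- function(sources, fs, min_score = 0.1) {
  sources <- as.matrix(sources)
  K <- nrow(sources)
  if (K < 2L) stop_fecg("fecg_value_error", "need >= 2 sources to classify")
  lag_min <- round(60 / 180 * fs)
  lag_max <- round(60 / 55 * fs)
  smooth_w <- odd_window(0.025 * fs)
  rate <- score <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    e <- sources[k, ]^2
    e <- stats::filter(e, rep(1 / smooth_w, smooth_w), sides = 2)
    e[is.na(e)] <- 0
    a <- stats::acf(as.numeric(e), lag.max = lag_max + 10L, plot = FALSE,
                    demean = TRUE)$acf[-1L]
    pk <- local_maxima(a)
    pk <- pk[pk >= lag_min & pk <= lag_max]
    if (!length(pk)) next
    # fundamental = smallest lag among peaks comparable to the strongest
    strong <- pk[a[pk] >= 0.5 * max(a[pk])]
    lag <- strong[1L]
    score[k] <- a[lag]
    rate[k] <- 60 * fs / lag
  }
  labels <- rep("noise", K)
  periodic <- !is.na(score) & score >= min_score
  labels[periodic & rate >= 55 & rate <= 105] <- "maternal"
  labels[periodic & rate >= 110 & rate <= 180] <- "fetal"
  for (lab in c("maternal", "fetal")) {
    idx <- which(labels == lab)
    if (length(idx) > 1L) {
      keep <- idx[which.max(score[idx])]
      labels[setdiff(idx, keep)] <- "noise"
    }
  }
  structure(labels, rate_bpm = rate, score = score)
}

#' Extract the fetal ECG from an abdominal record
#'
#' The hybrid FastICA + SVD pipeline:
#' \enumerate{
#'   \item preprocess all channels (baseline, notch, artifact clipping);
#'   \item separate the channels with over-relaxed FastICA and label the
#'     components; the maternal component gives the maternal R peaks, and
#'     the maternal + noise components serve as reference signals;
#'   \item per channel, cancel the maternal beats by subtracting the rank-k
#'     reconstruction of the maternal-synchronized beat matrix, then detect
#'     the fetal R peaks on the residue with the wavelet delineator;
#'   \item build the fetal beat matrix on the residue, keep its k largest
#'     singular values and invert it: the preliminary fetal ECG;
#'   \item remove residual interference by least-squares residualization of
#'     the preliminary estimate against the reference sources;
#'   \item report the channel whose final estimate has the highest
#'     cross-correlation SNR.
#' }
#'
#' @param record an [ecg_record] with >= 2 channels and >= 10 s of signal.
#' @param k singular values kept in the beat-matrix estimates (default 2).
#' @param seed RNG seed for the FastICA initialization; the whole pipeline
#'   is deterministic given the seed.
#' @param preprocess_cfg,delin_cfg,ica_cfg stage configurations; `ica_cfg`
#'   defaults to `fastica_config(seed = seed)`.
#' @param use_residue detect fetal beats on the maternal-cancelled residue
#'   (default) rather than on the raw channel.
#' @return object of class `fecg_extraction` with fields `fecg` (final
#'   estimate, mV), `fecg_svd_only` (preliminary rank-k estimate), `mecg`
#'   (maternal reconstruction of the best channel), `references`,
#'   `component_labels`, `fetal_r`, `maternal_r`, `snr_report` (incl. the
#'   preliminary-estimate SNR), `params` (mean RR s and heart rates bpm),
#'   `channel` (best channel index).
#' @export
extract_fecg <- function(record, k = 2L, seed = 1L,
                         preprocess_cfg = preprocess_config(),
                         delin_cfg = delineate_config(),
                         ica_cfg = NULL, use_residue = TRUE) {
  fs <- record$fs
  if (n_channels(record) < 2L) {
    stop_fecg("fecg_precondition_error", "extraction needs >= 2 channels")
  }
  if (n_samples(record) / fs < 10) {
    stop_fecg("fecg_precondition_error",
              "extraction needs >= 10 s of signal, got %.1f s",
              n_samples(record) / fs)
  }
  # tol 1e-4: the residual-noise subspace is close to Gaussian, where the
  # component rotation is degenerate and tighter tolerances never settle;
  # 1e-4 is ample for component identification
  if (is.null(ica_cfg)) ica_cfg <- fastica_config(seed = seed, tol = 1e-4)
  pre <- preprocess_record(record, preprocess_cfg)
  # a rank-deficient channel covariance (e.g. one source, no noise) makes
  # whitening impossible; the pipeline then runs without reference
  # separation rather than failing
  ica <- tryCatch(separate(pre, ica_cfg),
                  fecg_degenerate_input = function(e) NULL)
  labels <- if (is.null(ica)) {
    structure(character(0), rate_bpm = numeric(0), score = numeric(0))
  } else {
    classify_components(ica$sources, fs)
  }
  mat_idx <- which(labels == "maternal")
  # maternal R peaks: the maternal component is the natural candidate, but
  # the maternal ECG also dominates every abdominal channel; take the
  # candidate whose detected rhythm is the most regular one in the maternal
  # band (the cancellation step is only as good as these peaks)
  mat_cands <- c(if (length(mat_idx) == 1L) list(ica$sources[mat_idx, ]),
                 lapply(seq_len(ncol(pre$data)), function(j) pre$data[, j]))
  maternal_r <- integer()
  best_ms <- 0
  for (xm in mat_cands) {
    rm <- tryCatch(suppressWarnings(detect_r_peaks(xm, fs, delin_cfg)),
                   error = function(e) integer())
    if (length(rm) < 5L) next
    rate <- 60 * fs / stats::median(diff(rm))
    if (rate < 55 || rate > 105) next
    sc <- rhythm_score(as.integer(rm), fs)
    if (sc > best_ms) { best_ms <- sc; maternal_r <- as.integer(rm) }
  }
  # reference set for step 5: maternal + noise components, but never a
  # component beating at a fetal rate (a duplicated / split fetal component
  # demoted to "noise" by the uniqueness rule would otherwise subtract
  # fetal energy from the estimate)
  rate <- attr(labels, "rate_bpm")
  score <- attr(labels, "score")
  fetal_like <- !is.na(rate) & rate >= 108 & rate <= 185 & score >= 0.05
  ref_idx <- which(labels != "fetal" & !fetal_like)
  B <- if (!is.null(ica) && length(ref_idx)) {
    t(ica$sources[ref_idx, , drop = FALSE])
  } else NULL
  cand <- vector("list", n_channels(record))
  for (ch in seq_len(n_channels(record))) {
    x <- pre$data[, ch]
    mecg_hat <- NULL
    resid <- x
    if (use_residue && length(maternal_r) >= 3L) {
      ok <- tryCatch({
        bm_m <- build_beat_matrix(x, maternal_r, fs = fs)
        mecg_hat <- beats_to_signal(rank_truncate(bm_m$A, min(k, min(dim(bm_m$A)))), bm_m)
        resid <- x - mecg_hat
        TRUE
      }, error = function(e) FALSE)
      if (!ok) resid <- x
    }
    fet_r <- tryCatch(
      suppressWarnings(detect_r_peaks(resid, fs, delin_cfg)),
      error = function(e) integer())
    if (length(fet_r) < 3L) next
    fet_rate <- 60 * fs / mean(diff(fet_r))
    prelim <- tryCatch(svd_estimate(resid, fet_r, k = k, fs = fs),
                       error = function(e) NULL)
    if (is.null(prelim)) next
    # a reference that is itself locked to the fetal beats carries leaked
    # fetal energy (imperfect separation) and must not be regressed out
    Bk <- B
    if (!is.null(B)) {
      locked <- vapply(seq_len(ncol(B)), function(j) {
        s <- tryCatch(
          snr_rms(build_beat_matrix(B[, j], as.integer(fet_r), fs = fs)$A)$sigma,
          error = function(e) 0)
        isTRUE(s > 0.1)
      }, logical(1))
      Bk <- if (all(locked)) NULL else B[, !locked, drop = FALSE]
    }
    final <- if (is.null(Bk)) prelim else {
      beta <- qr.coef(qr(Bk), prelim)
      beta[is.na(beta)] <- 0
      as.numeric(prelim - Bk %*% beta)
    }
    # SVD-algorithm-alone baseline: rank-k beat estimate on the channel
    # itself, no maternal cancellation, no reference separation
    svd_only <- tryCatch(svd_estimate(x, fet_r, k = k, fs = fs),
                         error = function(e) NULL)
    bm_f <- tryCatch(build_beat_matrix(final, as.integer(fet_r), fs = fs),
                     error = function(e) NULL)
    if (is.null(bm_f) || is.null(svd_only)) next
    bm_s <- build_beat_matrix(svd_only, as.integer(fet_r), fs = fs)
    cand[[ch]] <- list(channel = ch, fecg = final, fecg_svd_only = svd_only,
                       mecg = mecg_hat, fetal_r = as.integer(fet_r),
                       fetal_band = fet_rate >= 110 && fet_rate <= 180,
                       snr_final = snr_rms(bm_f$A),
                       snr_eig_final = snr_eig(bm_f$A),
                       snr_svd_only = snr_rms(bm_s$A))
  }
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (!length(cand)) {
    stop_fecg("fecg_extraction_failed",
              "no channel yielded a fetal component (labels: %s)",
              paste(labels, collapse = ", "))
  }
  # best channel by SNR_RMS, restricted to channels whose detected rhythm
  # is in the fetal band whenever any channel reaches it
  in_band <- vapply(cand, `[[`, logical(1), "fetal_band")
  if (any(in_band)) cand <- cand[in_band]
  best <- cand[[which.max(vapply(cand, function(c) c$snr_final$sigma, numeric(1)))]]
  rr_f <- mean(diff(best$fetal_r)) / fs
  rr_m <- if (length(maternal_r) >= 2L) mean(diff(maternal_r)) / fs else NA_real_
  params <- list(maternal_qrs_count = length(maternal_r),
                 maternal_mean_rr_s = rr_m,
                 maternal_hr_bpm = if (is.na(rr_m)) NA_real_ else 60 / rr_m,
                 fetal_qrs_count = length(best$fetal_r),
                 fetal_mean_rr_s = rr_f,
                 fetal_hr_bpm = 60 / rr_f)
  structure(list(fecg = best$fecg, fecg_svd_only = best$fecg_svd_only,
                 mecg = if (is.null(best$mecg)) numeric(length(best$fecg)) else best$mecg,
                 references = B,
                 component_labels = labels,
                 fetal_r = best$fetal_r, maternal_r = maternal_r,
                 snr_report = list(snr_eig_db = best$snr_eig_final$snr_eig_db,
                                   snr_rms_db = best$snr_final$snr_rms_db,
                                   snr_rms_svd_only_db = best$snr_svd_only$snr_rms_db,
                                   sigma = best$snr_final$sigma,
                                   eigenvalues = best$snr_eig_final$eigenvalues,
                                   n_beats = best$snr_final$n_beats),
                 params = params, channel = best$channel, fs = fs),
            class = "fecg_extraction")
}

#' @export
print.fecg_extraction <- function(x, ...) {
  cat(sprintf("<fecg_extraction> best channel %d; SNR_RMS %.3f dB (rank-k only %.3f dB)\n",
              x$channel, x$snr_report$snr_rms_db, x$snr_report$snr_rms_svd_only_db))
  cat(sprintf("  fetal: %d beats, mean RR %.3f s, HR %.2f bpm\n",
              x$params$fetal_qrs_count, x$params$fetal_mean_rr_s,
              x$params$fetal_hr_bpm))
  if (!is.na(x$params$maternal_mean_rr_s)) {
    cat(sprintf("  maternal: %d beats, mean RR %.3f s, HR %.2f bpm\n",
                x$params$maternal_qrs_count, x$params$maternal_mean_rr_s,
                x$params$maternal_hr_bpm))
  }
  invisible(x)
}

#' Clinical parameter report
#'
#' Maternal and fetal QRS counts, mean RR intervals (s) and heart rates
#' (bpm, `60 / mean RR`, rounded to 2 decimals).
#'
#' @param res an `fecg_extraction`.
#' @return data frame with columns `parameter`, `value`.
#' @export
report_parameters <- function(res) {
  p <- res$params
  data.frame(
    parameter = c("maternal_qrs_count", "maternal_mean_rr_s",
                  "maternal_hr_bpm", "fetal_qrs_count", "fetal_mean_rr_s",
                  "fetal_hr_bpm"),
    value = c(p$maternal_qrs_count, p$maternal_mean_rr_s,
              heart_rate_bpm(p$maternal_mean_rr_s), p$fetal_qrs_count,
              p$fetal_mean_rr_s, heart_rate_bpm(p$fetal_mean_rr_s)))
}

#' Heart rate from a mean RR interval
#'
#' `60 / RR`, rounded to two decimals as printed in clinical reports.
#'
#' @param mean_rr_s mean RR interval in seconds.
#' @export
heart_rate_bpm <- function(mean_rr_s) round(60 / mean_rr_s, 2)
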