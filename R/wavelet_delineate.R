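#' Delineation configuration
#'
#' Tunables of the wavelet modulus-maxima delineator. All window lengths are
#' in seconds at the working rate of 1000 Hz (signals at other rates are
#' resampled before delineation so the windows map to fixed sample counts).
#'
#' @param r_scale wavelet scale used for R/Q/S detection (default 4, where
#'   QRS energy is strongest).
#' @param pt_scale scale used for P/T detection (default 2, where T-wave
#'   energy is strongest).
#' @param thr_mult multiplier of the mean positive/negative modulus-maximum
#'   magnitude used as the R-detection threshold (default 1; thresholds are
#'   data-relative, making detection amplitude-invariant).
#' @param pt_thr_mult threshold multiplier for P/T pole pairs (default
#'   0.25), applied to the mean maxima magnitudes inside each search region.
#' @param pair_window_s maximum separation of a negative/positive
#'   modulus-maximum pair (default 0.1 s).
#' @param rr_short_frac RR intervals below this fraction of the mean RR are
#'   false detections (default 0.4).
#' @param rr_long_frac RR intervals above this fraction of the mean RR are
#'   missed detections (default 1.5).
#' @param max_bisect bisection rounds when relaxing the threshold inside a
#'   missed-detection gap (default 8).
#' @param max_passes outer correction passes (default 5).
#' @param q_win_s,s_win_s zero-crossing search windows left/right of the R
#'   pole pair for Q and S (defaults 20 and 30 ms).
#' @param qrs_on_win_s,qrs_off_win_s pole search windows left of Q / right
#'   of S for the QRS onset and offset (defaults 30 and 40 ms).
#' @param qs_amp_frac minimum |Q| (or |S|) amplitude relative to |R|, both
#'   measured from the local baseline, below which the wave is reported
#'   absent (default 0.05).
#' @param t_on_shift_samples rightward shift (samples) from the leading T/P
#'   pole to the wave onset (default 3).
#' @export
delineate_config <- function(r_scale = 4L, pt_scale = 2L, thr_mult = 1,
                             pt_thr_mult = 0.25, pair_window_s = 0.1,
                             rr_short_frac = 0.4, rr_long_frac = 1.5,
                             max_bisect = 8L, max_passes = 5L,
                             q_win_s = 0.020, s_win_s = 0.030,
                             qrs_on_win_s = 0.030, qrs_off_win_s = 0.040,
                             qs_amp_frac = 0.05, t_on_shift_samples = 3L) {
  stopifnot(r_scale %in% 1:4, pt_scale %in% 1:4, thr_mult > 0,
            pair_window_s > 0, rr_short_frac > 0, rr_long_frac > 1)
  structure(as.list(environment()), class = "delineate_config")
}

# Insert zeros between filter taps: a-trous upsampling by factor `up`.
upsample_filter <- function(f, up) {
  if (up == 1L) return(f)
  out <- numeric((length(f) - 1L) * up + 1L)
  out[seq(1L, length(out), by = up)] <- f
  out
}

#' Undecimated quadratic-spline wavelet transform
#'
#' A-trous filter bank with the Mallat-Zhong quadratic-spline derivative
#' wavelet (lowpass 1/8 {1,3,3,1}, highpass 2 {-1,1}). Scale-j coefficients
#' are proportional to the negated derivative of the signal smoothed at
#' scale 2^j, so a positive peak produces a negative-then-positive
#' modulus-maximum pair whose zero crossing marks the peak. Coefficients are
#' time-aligned: the group delay of each scale's filter cascade is removed,
#' and the removed delays are recorded.
#'
#' @param x signal (>= 64 samples).
#' @param fs sampling rate (Hz).
#' @param n_scales number of dyadic scales (default 4).
#' @return object of class `wavelet_scales`: `coeffs` (N x n_scales, aligned),
#'   `delays` (samples removed per scale), `fs`.
#' @export
swt_quadratic_spline <- function(x, fs = 1000, n_scales = 4L) {
  N <- length(x)
  if (N < 64L) stop_fecg("fecg_length_error", "need >= 64 samples, got %d", N)
  h <- c(0.125, 0.375, 0.375, 0.125)
  g <- c(-2, 2)
  pad <- 64L
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(N - pad):(N - 1L)]))
  coeffs <- matrix(0, N, n_scales)
  delays <- integer(n_scales)
  a <- xp
  hdelay <- 0  # accumulated smoothing delay (samples; half-integer)
  for (j in seq_len(n_scales)) {
    up <- 2L^(j - 1L)
    wj <- stats::filter(a, upsample_filter(g, up), method = "convolution", sides = 1)
    wj[is.na(wj)] <- 0
    d <- floor(hdelay + 0.5 * up)
    delays[j] <- d
    coeffs[, j] <- wj[(pad + 1L + d):(pad + N + d)]
    a <- stats::filter(a, upsample_filter(h, up), method = "convolution", sides = 1)
    a[is.na(a)] <- 0
    hdelay <- hdelay + 1.5 * up
  }
  structure(list(coeffs = coeffs, delays = delays, fs = fs),
            class = "wavelet_scales")
}

#' Find paired modulus maxima at one scale
#'
#' Local coefficient maxima above `thr_pos` and minima below `thr_neg` are
#' paired: each positive maximum takes the nearest preceding unused negative
#' maximum within `pair_window_s`. Unmatched maxima are dropped (an
#' unmatched pole is a spurious detection). The zero crossing between the
#' two poles (leftmost sample of the sign change) locates the underlying
#' peak.
#'
#' @param w a `wavelet_scales` object.
#' @param scale scale index 1..4.
#' @param thr_pos,thr_neg thresholds (thr_pos > 0 > thr_neg).
#' @param pair_window_s maximum pole separation in seconds.
#' @param from,to optional sample range restricting the search.
#' @return data frame with columns `neg_idx`, `pos_idx`, `zero_idx`,
#'   `scale`, `neg_amp`, `pos_amp`, one row per pair, ordered in time.
#' @export
find_mod_max_pairs <- function(w, scale, thr_pos, thr_neg,
                               pair_window_s = 0.1, from = 1L, to = NULL) {
  stopifnot(inherits(w, "wavelet_scales"), scale >= 1L,
            scale <= ncol(w$coeffs), thr_pos > 0, thr_neg < 0)
  cs <- w$coeffs[, scale]
  if (is.null(to)) to <- length(cs)
  pm <- local_maxima(cs)
  nm <- local_minima(cs)
  pm <- pm[cs[pm] > thr_pos & pm >= from & pm <= to]
  nm <- nm[cs[nm] < thr_neg & nm >= from & nm <= to]
  empty <- data.frame(neg_idx = integer(), pos_idx = integer(),
                      zero_idx = integer(), scale = integer(),
                      neg_amp = numeric(), pos_amp = numeric())
  if (!length(pm) || !length(nm)) return(empty)
  win <- round(pair_window_s * w$fs)
  used <- logical(length(nm))
  rows <- vector("list", length(pm))
  cand0 <- findInterval(pm - 1L, nm)   # largest nm < each positive pole
  for (k in seq_along(pm)) {
    p <- pm[k]
    j <- cand0[k]
    while (j >= 1L && used[j] && p - nm[j] <= win) j <- j - 1L
    if (j < 1L || used[j] || p - nm[j] > win) next
    used[j] <- TRUE
    n0 <- nm[j]
    seg <- n0:(p - 1L)
    cross <- seg[cs[seg] <= 0 & cs[seg + 1L] > 0]
    z <- if (length(cross)) cross[1L] else as.integer(round((n0 + p) / 2))
    rows[[k]] <- c(n0, p, z, scale, cs[n0], cs[p])
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) return(empty)
  out <- data.frame(neg_idx = as.integer(rows[, 1]),
                    pos_idx = as.integer(rows[, 2]),
                    zero_idx = as.integer(rows[, 3]),
                    scale = as.integer(rows[, 4]),
                    neg_amp = rows[, 5], pos_amp = rows[, 6])
  out[order(out$zero_idx), , drop = FALSE]
}

# Threshold anchors for R detection: mean magnitudes of the positive /
# negative local extrema at one scale, floored by the coefficient RMS.
# On a clean ECG the extrema mean sits between the QRS poles and the small
# P/T poles and the floor is inactive; on a noisy signal the dense
# noise-floor extrema drag the mean below the noise band, where pairing
# produces unprunable false detections — the RMS, which weighs the strong
# QRS poles quadratically, keeps the anchor between the two populations.
scale_extrema_means <- function(w, scale) {
  cs <- w$coeffs[, scale]
  pm <- local_maxima(cs); pm <- pm[cs[pm] > 0]
  nm <- local_minima(cs); nm <- nm[cs[nm] < 0]
  rms <- sqrt(mean(cs^2))
  list(pos = max(if (length(pm)) mean(cs[pm]) else 0, rms),
       neg = max(if (length(nm)) mean(abs(cs[nm])) else 0, rms),
       pos_idx = pm, neg_idx = nm)
}

# ECG polarity: R spikes dominate the third moment, so negative skewness
# means the lead is inverted relative to the upright-R convention the
# pole-pairing rules assume.
ecg_polarity <- function(x) {
  xc <- x - mean(x)
  s3 <- mean(xc^3)
  if (s3 < 0) -1 else 1
}

#' Detect R peaks by wavelet modulus maxima
#'
#' Scale-4 modulus-maximum pairs above data-relative thresholds give
#' candidate R peaks at their zero crossings. Two correction rules then run
#' until stable: an RR interval shorter than `rr_short_frac` times the mean
#' RR marks a false detection (the pair with the smaller summed pole
#' amplitude is dropped); an RR interval longer than `rr_long_frac` times
#' the mean RR marks a missed detection, and the threshold multiplier is
#' halved by bisection inside that gap until a pair is found.
#'
#' @param x single-channel signal (>= 2 s).
#' @param fs sampling rate (Hz).
#' @param cfg a [delineate_config].
#' @param w optional precomputed [swt_quadratic_spline] of `x`.
#' @return sorted integer R-peak indices, with the matched pole pairs in
#'   `attr(, "pairs")`. Empty (with a warning) if no poles survive even the
#'   fully relaxed threshold.
#' @export
detect_r_peaks <- function(x, fs, cfg = delineate_config(), w = NULL) {
  if (length(x) < 2 * fs) {
    stop_fecg("fecg_length_error", "R detection needs >= 2 s of signal")
  }
  pol <- ecg_polarity(x)
  if (pol < 0) {
    x <- -x
    if (!is.null(w)) w$coeffs <- -w$coeffs
  }
  if (is.null(w)) w <- swt_quadratic_spline(x, fs)
  anchors <- scale_extrema_means(w, cfg$r_scale)
  if (anchors$pos <= 0 || anchors$neg <= 0) {
    warning("no modulus maxima found; returning empty R list")
    return(structure(integer(), pairs = NULL, fs = fs))
  }
  # bisection ladder around the base threshold: run the full
  # detect/prune/repair cycle at each level and keep the detection whose
  # RR series is the most regular physiological rhythm (rhythm-regularity
  # generalizes the single-gap dichotomy adjustment to the whole record)
  cands <- lapply(cfg$thr_mult * c(4, 2, 1, 1 / 2, 1 / 4, 1 / 8),
                  function(m) detect_r_core(w, m, anchors, cfg))
  score <- vapply(cands, function(cc) attr(cc, "rhythm_score"), numeric(1))
  count <- vapply(cands, nrow, integer(1))
  if (max(score) <= 0) {
    warning("no modulus maxima above threshold after full relaxation")
    return(structure(integer(), pairs = NULL, fs = fs))
  }
  near <- which(score >= max(score) - 0.02)
  pairs <- cands[[near[which.max(count[near])]]]
  structure(as.integer(pairs$zero_idx), pairs = pairs, fs = fs)
}

# RR-series regularity of a candidate detection: fraction of intervals
# within [0.75, 4/3] of the median interval, zeroed when the median rate is
# outside the plausible 50-200 bpm band.
rhythm_score <- function(zero_idx, fs) {
  if (length(zero_idx) < 5L) return(0)
  rr <- diff(zero_idx)
  med <- stats::median(rr)
  if (med < 0.3 * fs || med > 1.2 * fs) return(0)
  mean(rr > 0.75 * med & rr < 4 / 3 * med)
}

# One full detection cycle at a fixed threshold multiplier: initial pole
# pairing, then the false-detection and missed-detection corrections.
detect_r_core <- function(w, mult, anchors, cfg) {
  pairs <- find_mod_max_pairs(w, cfg$r_scale, mult * anchors$pos,
                              -mult * anchors$neg, cfg$pair_window_s)
  if (nrow(pairs) == 0L) return(structure(pairs, rhythm_score = 0))
  # more than ~6 pairs per second cannot be a rhythm; skip the corrections
  if (nrow(pairs) > 6 * nrow(w$coeffs) / w$fs) {
    return(structure(pairs, rhythm_score = 0))
  }
  for (pass in seq_len(cfg$max_passes)) {
    fired <- FALSE
    # false detections: drop the weaker pair of any too-short RR interval
    # (non-adjacent violations resolved in one sweep, the rest on the next)
    repeat {
      if (nrow(pairs) < 3L) break
      rr <- diff(pairs$zero_idx)
      bad <- which(rr < cfg$rr_short_frac * mean(rr))
      if (!length(bad)) break
      amp <- abs(pairs$pos_amp) + abs(pairs$neg_amp)
      drop <- logical(nrow(pairs))
      for (i in bad) {
        if (drop[i] || drop[i + 1L]) next
        drop[if (amp[i] < amp[i + 1L]) i else i + 1L] <- TRUE
      }
      pairs <- pairs[!drop, , drop = FALSE]
      fired <- TRUE
    }
    # missed detections: bisect the threshold inside each too-long gap
    # (including the stretches before the first and after the last beat)
    if (nrow(pairs) < 2L) break
    rr <- diff(pairs$zero_idx)
    rbar <- mean(rr)
    refract <- round(cfg$rr_short_frac * rbar)
    n_sig <- nrow(w$coeffs)
    r_now <- pairs$zero_idx
    gap_from <- gap_to <- integer(0)
    gi <- which(rr > cfg$rr_long_frac * rbar)
    gap_from <- c(gap_from, r_now[gi] + refract)
    gap_to <- c(gap_to, r_now[gi + 1L] - refract)
    if (r_now[1L] > cfg$rr_long_frac * rbar) {
      gap_from <- c(gap_from, 1L)
      gap_to <- c(gap_to, r_now[1L] - refract)
    }
    if (n_sig - r_now[length(r_now)] > cfg$rr_long_frac * rbar) {
      gap_from <- c(gap_from, r_now[length(r_now)] + refract)
      gap_to <- c(gap_to, n_sig)
    }
    inserted <- list()
    for (g in seq_along(gap_from)) {
      m <- mult
      for (round_i in seq_len(cfg$max_bisect)) {
        m <- m / 2
        sub <- find_mod_max_pairs(w, cfg$r_scale, m * anchors$pos,
                                  -m * anchors$neg, cfg$pair_window_s,
                                  from = gap_from[g], to = gap_to[g])
        sub <- sub[sub$zero_idx >= gap_from[g] & sub$zero_idx <= gap_to[g], ,
                   drop = FALSE]
        if (nrow(sub)) {
          best <- which.max(abs(sub$pos_amp) + abs(sub$neg_amp))
          inserted[[length(inserted) + 1L]] <- sub[best, , drop = FALSE]
          fired <- TRUE
          break
        }
      }
    }
    if (length(inserted)) {
      pairs <- rbind(pairs, do.call(rbind, inserted))
      pairs <- pairs[order(pairs$zero_idx), , drop = FALSE]
      pairs <- pairs[!duplicated(pairs$zero_idx), , drop = FALSE]
    }
    if (!fired) break
  }
  structure(pairs, rhythm_score = rhythm_score(pairs$zero_idx, w$fs))
}

# Scan for the zero crossing of `cs` nearest to `start`, moving left
# (dir = -1) or right (dir = +1) by at most `win` samples. Returns the
# leftmost sample of the sign change, or NA.
scan_zero_crossing <- function(cs, start, win, dir) {
  n <- length(cs)
  steps <- seq_len(win)
  for (s in steps) {
    i <- if (dir < 0) start - s else start + s - 1L
    if (i < 1L || i + 1L > n) break
    if (cs[i] == 0 || cs[i] * cs[i + 1L] < 0 ||
        (cs[i + 1L] == 0 && cs[i] != 0)) {
      return(i)
    }
  }
  NA_integer_
}

#' Detect Q and S waves
#'
#' Q is the first scale-4 zero crossing within 20 ms left of each R pole
#' pair's leading pole; S the first within 30 ms right of the trailing pole.
#' A wave whose amplitude relative to the local baseline is below
#' `qs_amp_frac` of the R amplitude is reported absent.
#'
#' @param x the delineated signal.
#' @param w its [swt_quadratic_spline].
#' @param r_peaks output of [detect_r_peaks] (pole-pair context attached).
#' @param fs sampling rate.
#' @param cfg a [delineate_config].
#' @return data frame with columns `Q`, `S` (NA = absent), one row per beat.
#' @export
detect_qs <- function(x, w, r_peaks, fs, cfg = delineate_config()) {
  pairs <- attr(r_peaks, "pairs")
  stopifnot(!is.null(pairs))
  cs <- w$coeffs[, cfg$r_scale]
  qwin <- round(cfg$q_win_s * fs)
  swin <- round(cfg$s_win_s * fs)
  bwin <- round(0.15 * fs)
  n <- length(x)
  m <- nrow(pairs)
  Q <- S <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    lead <- min(pairs$neg_idx[i], pairs$pos_idx[i])
    trail <- max(pairs$neg_idx[i], pairs$pos_idx[i])
    r <- pairs$zero_idx[i]
    q <- scan_zero_crossing(cs, lead, qwin, dir = -1L)
    s <- scan_zero_crossing(cs, trail, swin, dir = +1L)
    base <- stats::median(x[max(1L, r - bwin):min(n, r + bwin)])
    r_amp <- abs(x[r] - base)
    if (!is.na(q) && abs(x[q] - base) < cfg$qs_amp_frac * r_amp) q <- NA_integer_
    if (!is.na(s) && abs(x[s] - base) < cfg$qs_amp_frac * r_amp) s <- NA_integer_
    Q[i] <- q
    S[i] <- s
  }
  data.frame(Q = Q, S = S)
}

#' Detect QRS onset and offset
#'
#' The QRS onset is the modulus extremum nearest to the left of Q within a
#' 30 ms window (the leading pole generated by the Q wave); the offset is
#' the last extremum within 40 ms right of S (the trailing pole of the S
#' wave). When Q or S is absent the bounds fall back to R -/+ 25 ms and are
#' flagged.
#'
#' @inheritParams detect_qs
#' @param qs output of [detect_qs].
#' @return data frame with `QRS_on`, `QRS_off`, `fallback` (logical).
#' @export
detect_qrs_bounds <- function(w, qs, r_peaks, fs, cfg = delineate_config()) {
  pairs <- attr(r_peaks, "pairs")
  cs <- w$coeffs[, cfg$r_scale]
  ext <- sort(c(local_maxima(cs), local_minima(cs)))
  onw <- round(cfg$qrs_on_win_s * fs)
  offw <- round(cfg$qrs_off_win_s * fs)
  half_qrs <- round(0.025 * fs)
  m <- nrow(pairs)
  on <- off <- rep(NA_integer_, m)
  fallback <- logical(m)
  for (i in seq_len(m)) {
    q <- qs$Q[i]; s <- qs$S[i]; r <- pairs$zero_idx[i]
    # a QRS-related pole must be salient relative to the beat's own R pair
    floor_i <- 0.05 * max(abs(pairs$neg_amp[i]), abs(pairs$pos_amp[i]))
    ext_i <- ext[abs(cs[ext]) >= floor_i]
    if (!is.na(q)) {
      cand <- ext_i[ext_i >= q - onw & ext_i < q]
      on[i] <- if (length(cand)) max(cand) else NA_integer_
    }
    if (!is.na(s)) {
      cand <- ext_i[ext_i > s & ext_i <= s + offw]
      off[i] <- if (length(cand)) max(cand) else NA_integer_
    }
    if (is.na(on[i])) { on[i] <- max(1L, r - half_qrs); fallback[i] <- TRUE }
    if (is.na(off[i])) { off[i] <- min(length(cs), r + half_qrs); fallback[i] <- TRUE }
  }
  data.frame(QRS_on = on, QRS_off = off, fallback = fallback)
}

#' Detect P and T waves
#'
#' T-wave pole pairs are sought at scale 2 (where T energy is strongest) in
#' the first half of the RR interval right of each R pair's trailing pole;
#' P-wave pairs in the last third of the RR interval left of the leading
#' pole. Thresholds are `pt_thr_mult` times the mean magnitudes of the
#' extrema inside each search region. The wave peak is the pair's zero
#' crossing; the onset is the leading pole shifted three samples right, and
#' the offset mirrors the onset about the peak (approximate waveform
#' symmetry).
#'
#' @inheritParams detect_qs
#' @return data frame with columns `P_on`, `P_peak`, `P_off`, `T_on`,
#'   `T_peak`, `T_off` (NA = absent).
#' @export
detect_p_t <- function(x, w, r_peaks, fs, cfg = delineate_config()) {
  pairs <- attr(r_peaks, "pairs")
  if (nrow(pairs) < 2L) {
    stop_fecg("fecg_insufficient_beats", "P/T search regions need >= 2 R peaks")
  }
  cs <- w$coeffs[, cfg$pt_scale]
  n <- length(cs)
  r <- pairs$zero_idx
  rr <- diff(r)
  rrbar <- mean(rr)
  m <- nrow(pairs)
  out <- data.frame(P_on = rep(NA_integer_, m), P_peak = NA_integer_,
                    P_off = NA_integer_, T_on = NA_integer_,
                    T_peak = NA_integer_, T_off = NA_integer_)
  region_pairs <- function(from, to) {
    from <- max(1L, as.integer(from)); to <- min(n, as.integer(to))
    if (to - from < 4L) return(NULL)
    seg <- cs[from:to]
    pm <- local_maxima(seg); pm <- pm[seg[pm] > 0]
    nm <- local_minima(seg); nm <- nm[seg[nm] < 0]
    if (!length(pm) || !length(nm)) return(NULL)
    thr_pos <- cfg$pt_thr_mult * mean(seg[pm])
    thr_neg <- -cfg$pt_thr_mult * mean(abs(seg[nm]))
    pp <- find_mod_max_pairs(w, cfg$pt_scale, thr_pos, thr_neg,
                             cfg$pair_window_s, from = from, to = to)
    if (nrow(pp) == 0L) NULL else pp
  }
  shift <- cfg$t_on_shift_samples
  for (i in seq_len(m)) {
    lead <- min(pairs$neg_idx[i], pairs$pos_idx[i])
    trail <- max(pairs$neg_idx[i], pairs$pos_idx[i])
    rr_next <- if (i < m) rr[i] else rrbar
    rr_prev <- if (i > 1L) rr[i - 1L] else rrbar
    tp <- region_pairs(trail + 1L, trail + round(rr_next / 2))
    if (!is.null(tp)) {
      best <- tp[which.max(abs(tp$pos_amp) + abs(tp$neg_amp)), ]
      t_on <- min(best$neg_idx, best$pos_idx) + shift
      t_peak <- best$zero_idx
      if (t_on <= t_peak) {
        out$T_on[i] <- t_on
        out$T_peak[i] <- t_peak
        out$T_off[i] <- min(n, t_peak + (t_peak - t_on))
      }
    }
    pp <- region_pairs(lead - round(rr_prev / 3), lead - 1L)
    if (!is.null(pp)) {
      best <- pp[which.max(abs(pp$pos_amp) + abs(pp$neg_amp)), ]
      p_on <- min(best$neg_idx, best$pos_idx) + shift
      p_peak <- best$zero_idx
      if (p_on <= p_peak) {
        out$P_on[i] <- p_on
        out$P_peak[i] <- p_peak
        out$P_off[i] <- min(n, p_peak + (p_peak - p_on))
      }
    }
  }
  out
}

#' Full ECG delineation
#'
#' Runs R, Q/S, QRS-bound and P/T detection on a single-channel ECG and
#' assembles a per-beat fiducial table. The ST segment runs from the QRS
#' offset to the T onset; its deviation is the mean amplitude over that
#' interval minus the isoelectric reference (mean over the 20 ms ending
#' 10 ms before the QRS onset). Fiducials violating the canonical intra-beat
#' ordering are dropped (reported absent) rather than reordered.
#'
#' Signals not sampled at 1000 Hz are resampled to 1000 Hz for detection and
#' the fiducials mapped back to the native rate.
#'
#' @param x single-channel ECG (an extracted fetal ECG or any ECG).
#' @param fs sampling rate (Hz).
#' @param cfg a [delineate_config].
#' @return object of class `fiducial_set`: `beats` (per-beat data frame with
#'   the columns written by [write_fiducials]), `rr_mean_s`,
#'   `qrs_durations_s`, `st_deviation_mv`, `fs`.
#' @export
delineate <- function(x, fs, cfg = delineate_config()) {
  if (fs != 1000) {
    n_out <- round(length(x) * 1000 / fs)
    x1k <- stats::approx(seq_along(x), x, n = n_out)$y
    fid <- delineate(x1k, 1000, cfg)
    map <- function(v) ifelse(is.na(v), NA_integer_,
                              pmin(length(x), pmax(1L, as.integer(round((v - 1) * fs / 1000 + 1)))))
    fid$beats[-1L] <- lapply(fid$beats[-1L], map)
    fid$fs <- fs
    return(fid)
  }
  # normalize to the upright-R convention the pole-pairing rules assume;
  # fiducial indices are unaffected, ST deviation is reported on the
  # upright-R orientation
  x <- ecg_polarity(x) * x
  w <- swt_quadratic_spline(x, fs)
  r <- detect_r_peaks(x, fs, cfg, w = w)
  if (length(r) < 2L) {
    stop_fecg("fecg_insufficient_beats",
              "delineation needs >= 2 detected R peaks, found %d", length(r))
  }
  qs <- detect_qs(x, w, r, fs, cfg)
  bounds <- detect_qrs_bounds(w, qs, r, fs, cfg)
  pt <- detect_p_t(x, w, r, fs, cfg)
  m <- length(r)
  beats <- data.frame(beat = seq_len(m), P_on = pt$P_on, P_peak = pt$P_peak,
                      P_off = pt$P_off, Q = qs$Q, QRS_on = bounds$QRS_on,
                      R = as.integer(r), S = qs$S, QRS_off = bounds$QRS_off,
                      T_on = pt$T_on, T_peak = pt$T_peak, T_off = pt$T_off,
                      ST_start = NA_integer_, ST_end = NA_integer_)
  # enforce the intra-beat ordering: drop waves that contradict the QRS
  drop_p <- with(beats, !is.na(P_off) & P_off > QRS_on)
  beats[drop_p, c("P_on", "P_peak", "P_off")] <- NA_integer_
  drop_t <- with(beats, !is.na(T_on) & T_on < QRS_off)
  beats[drop_t, c("T_on", "T_peak", "T_off")] <- NA_integer_
  beats$ST_start <- beats$QRS_off
  beats$ST_end <- beats$T_on
  iso_w1 <- round(0.030 * fs)
  iso_w0 <- round(0.010 * fs)
  stdev <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    s0 <- beats$ST_start[i]; s1 <- beats$ST_end[i]
    if (is.na(s0) || is.na(s1) || s1 <= s0) next
    iso_lo <- beats$QRS_on[i] - iso_w1
    iso_hi <- beats$QRS_on[i] - iso_w0 - 1L
    if (iso_lo < 1L) next
    stdev[i] <- mean(x[s0:(s1 - 1L)]) - mean(x[iso_lo:iso_hi])
  }
  structure(list(beats = beats,
                 rr_mean_s = mean(diff(r)) / fs,
                 qrs_durations_s = (beats$QRS_off - beats$QRS_on) / fs,
                 st_deviation_mv = stdev,
                 fs = fs),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d beats @ %g Hz; mean RR %.3f s (%.1f bpm); mean QRS %.1f ms\n",
              nrow(x$beats), x$fs, x$rr_mean_s, 60 / x$rr_mean_s,
              1000 * mean(x$qrs_durations_s, na.rm = TRUE)))
  invisible(x)
}
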