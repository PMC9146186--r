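unit_rows <- function(U) {
  U <- as.matrix(U)
  nrm <- sqrt(rowSums(U^2))
  if (any(nrm == 0)) stop_fecg("fecg_value_error", "zero-energy beat row")
  U / nrm
}

#' Eigenvalue signal-to-noise ratio of a beat matrix
#'
#' Rows (beats) are unit-l2-normalized; the eigenvalues gamma of the Gram
#' matrix (the squared singular values) measure how beat energy concentrates
#' on a single shape. The SNR is `gamma_max / (sum(gamma) - gamma_max)`,
#' reported in dB (`10 log10`); identical beats give +Inf.
#'
#' @param beats M x L matrix, one beat per row (M >= 2).
#' @return list with `snr_eig_db`, `ratio`, `eigenvalues`, `n_beats`.
#' @export
snr_eig <- function(beats) {
  U <- unit_rows(beats)
  M <- nrow(U)
  if (M < 2L) stop_fecg("fecg_insufficient_beats", "need >= 2 beats, got %d", M)
  gamma <- svd(U, nu = 0, nv = 0)$d^2
  gmax <- gamma[1L]
  rest <- sum(gamma) - gmax
  ratio <- if (rest <= .Machine$double.eps * sum(gamma)) Inf else gmax / rest
  list(snr_eig_db = 10 * log10(ratio), ratio = ratio,
       eigenvalues = gamma, n_beats = M)
}

#' Cross-correlation signal-to-noise ratio of a beat matrix
#'
#' With unit-normalized beats, `sigma` is the mean pairwise cosine
#' similarity `2/(M(M-1)) sum_{i<k} f(i)' f(k)`; the SNR is
#' `sigma / (1 - sigma)` in dB. `sigma <= 0` reports -Inf, `sigma = 1`
#' (identical beats) +Inf.
#'
#' @inheritParams snr_eig
#' @return list with `snr_rms_db`, `sigma`, `n_beats`.
#' @export
snr_rms <- function(beats) {
  U <- unit_rows(beats)
  M <- nrow(U)
  if (M < 2L) stop_fecg("fecg_insufficient_beats", "need >= 2 beats, got %d", M)
  G <- tcrossprod(U)
  sigma <- (sum(G) - sum(diag(G))) / (M * (M - 1))
  db <- if (sigma <= 0) -Inf
        else if (sigma >= 1 - 1e-9) Inf   # identical beats up to rounding
        else 10 * log10(sigma / (1 - sigma))
  list(snr_rms_db = db, sigma = sigma, n_beats = M)
}

#' Match detected against reference peaks
#'
#' Greedy one-to-one matching in time order: a detected peak within `tol_s`
#' of an unmatched reference peak is a true positive; leftover detected
#' peaks are false positives, leftover reference peaks false negatives.
#'
#' @param detected,reference sorted sample-index vectors.
#' @param tol_s matching tolerance in seconds (default 0.05).
#' @param fs sampling rate (Hz).
#' @return list of counts `tp`, `fp`, `fn`.
#' @export
match_peaks <- function(detected, reference, tol_s = 0.05, fs = 1000) {
  if (is.unsorted(detected) || is.unsorted(reference)) {
    stop_fecg("fecg_value_error", "peak lists must be sorted")
  }
  tol <- tol_s * fs
  i <- 1L; j <- 1L; tp <- 0L
  nd <- length(detected); nr <- length(reference)
  while (i <= nd && j <= nr) {
    d <- detected[i] - reference[j]
    if (abs(d) <= tol) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(tp = tp, fp = nd - tp, fn = nr - tp)
}

#' Detection sensitivity, positive predictive value and F1
#'
#' `Se = 100 TP/(TP+FN)`, `PPV = 100 TP/(TP+FP)`, and
#' `F1 = 100 TP/(TP+FP+FN)`. Note this F1 is a Jaccard-type index (a lower
#' bound of both Se and PPV), not the harmonic-mean F1.
#'
#' @param counts list or vector with elements `tp`, `fp`, `fn`.
#' @return list with `se`, `ppv`, `f1` in percent (unrounded).
#' @export
se_ppv_f1 <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (any(c(tp, fp, fn) < 0)) stop_fecg("fecg_value_error", "negative counts")
  if (tp + fn == 0) stop_fecg("fecg_value_error", "Se undefined: tp + fn = 0")
  if (tp + fp == 0) stop_fecg("fecg_value_error", "PPV undefined: tp + fp = 0")
  list(se = 100 * tp / (tp + fn),
       ppv = 100 * tp / (tp + fp),
       f1 = 100 * tp / (tp + fp + fn))
}
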