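#' Build an R-synchronized beat matrix
#'
#' Cuts a single-channel signal into consecutive R-to-R segments, each
#' starting a fixed fraction of the median RR interval before its R peak so
#' that QRS complexes align columnwise, and linearly resamples every segment
#' to a common period length. Column-coherent QRS energy then concentrates
#' in the leading singular values of the matrix, which is what makes rank
#' truncation act as a beat-synchronous denoiser.
#'
#' @param x single-channel signal.
#' @param r_peaks strictly increasing R-peak sample indices (>= 3).
#' @param n_target equalized period length; default: median segment length.
#' @param pre_frac fraction of the median RR by which each segment starts
#'   before its R peak (default 0.3).
#' @param fs sampling rate, carried for bookkeeping (default 1000).
#' @return an object of class `beat_matrix`: `A` (m x n), `r_peaks` (the m
#'   peaks owning the rows), `seg_bounds` (m x 2 half-open original-sample
#'   intervals), `n`, `fs`, `sig_len`.
#' @export
build_beat_matrix <- function(x, r_peaks, n_target = NULL, pre_frac = 0.3,
                              fs = 1000) {
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 3L) {
    stop_fecg("fecg_insufficient_beats",
              "beat matrix needs >= 3 R peaks, got %d", length(r_peaks))
  }
  if (is.unsorted(r_peaks, strictly = TRUE)) {
    stop_fecg("fecg_ordering_error", "R peaks must be strictly increasing")
  }
  if (r_peaks[1L] < 1L || r_peaks[length(r_peaks)] > length(x)) {
    stop_fecg("fecg_value_error", "R peaks outside the signal")
  }
  rr <- diff(r_peaks)
  offset <- as.integer(round(pre_frac * stats::median(rr)))
  starts <- r_peaks - offset
  # segment i spans [starts[i], starts[i+1]); drop partial first/last
  keep <- which(starts[-length(starts)] >= 1L &
                starts[-1L] <= length(x) + 1L)
  if (length(keep) < 2L) {
    stop_fecg("fecg_insufficient_beats", "fewer than 2 complete beats inside the signal")
  }
  seg_start <- starts[keep]
  seg_end <- starts[keep + 1L]
  lens <- seg_end - seg_start
  n <- if (is.null(n_target)) as.integer(round(stats::median(lens))) else as.integer(n_target)
  m <- length(keep)
  A <- matrix(0, m, n)
  for (i in seq_len(m)) {
    A[i, ] <- resample_linear(x[seg_start[i]:(seg_end[i] - 1L)], n)
  }
  structure(list(A = A, r_peaks = r_peaks[keep],
                 seg_bounds = cbind(start = seg_start, end = seg_end),
                 n = n, fs = fs, sig_len = length(x)),
            class = "beat_matrix")
}

#' Singular spectrum and difference spectrum of a beat matrix
#'
#' The difference spectrum (consecutive differences of the descending
#' singular values) peaks at the boundary between signal-carrying and
#' noise-carrying singular values; its argmax is the data-driven rank
#' choice.
#'
#' @param A a `beat_matrix` or a plain matrix.
#' @return list with `values` (descending singular values) and
#'   `diff_spectrum` (their consecutive differences, nonnegative).
#' @export
singular_spectrum <- function(A) {
  if (inherits(A, "beat_matrix")) A <- A$A
  d <- svd(A, nu = 0, nv = 0)$d
  structure(list(values = d, diff_spectrum = -diff(d)),
            class = "singular_spectrum")
}

#' Truncate a matrix to its best rank-k approximation
#'
#' Keeps the k largest singular values and zeroes the rest; by the
#' Eckart-Young theorem the result is the closest rank-k matrix in Frobenius
#' norm, with squared error equal to the sum of the discarded squared
#' singular values.
#'
#' @param A m x n matrix (or `beat_matrix`).
#' @param k rank to keep, in `[1, min(m, n)]` (default 2, the rank at which
#'   fetal beat-matrix extraction performs best).
#' @export
rank_truncate <- function(A, k = 2L) {
  if (inherits(A, "beat_matrix")) A <- A$A
  p <- min(dim(A))
  if (k < 1L || k > p) {
    stop_fecg("fecg_value_error", "k must be in [1, %d], got %s", p, k)
  }
  s <- svd(A)
  s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k) %*%
    t(s$v[, seq_len(k), drop = FALSE])
}

#' Invert a beat matrix back to a signal
#'
#' Resamples each (possibly modified) row back to its original segment
#' length and writes it into the segment's sample interval; samples outside
#' all segments are zero.
#'
#' @param A_prime matrix of the same shape as `bm$A`.
#' @param bm the `beat_matrix` the rows came from.
#' @return signal of the original length.
#' @export
beats_to_signal <- function(A_prime, bm) {
  stopifnot(inherits(bm, "beat_matrix"))
  if (!all(dim(A_prime) == dim(bm$A))) {
    stop_fecg("fecg_value_error", "matrix shape %s does not match beat matrix %s",
              paste(dim(A_prime), collapse = "x"),
              paste(dim(bm$A), collapse = "x"))
  }
  out <- numeric(bm$sig_len)
  for (i in seq_len(nrow(A_prime))) {
    s <- bm$seg_bounds[i, "start"]
    e <- bm$seg_bounds[i, "end"]
    out[s:(e - 1L)] <- resample_linear(A_prime[i, ], e - s)
  }
  out
}

#' Beat-synchronous SVD signal estimate
#'
#' Composition of [build_beat_matrix], [rank_truncate] and
#' [beats_to_signal]: the rank-k reconstruction of the R-synchronized beat
#' matrix, mapped back to the time axis.
#'
#' @inheritParams build_beat_matrix
#' @param k rank to keep (default 2).
#' @export
svd_estimate <- function(x, r_peaks, k = 2L, n_target = NULL, pre_frac = 0.3,
                         fs = 1000) {
  bm <- build_beat_matrix(x, r_peaks, n_target = n_target,
                          pre_frac = pre_frac, fs = fs)
  beats_to_signal(rank_truncate(bm$A, k), bm)
}
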