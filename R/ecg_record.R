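#' Multichannel ECG record
#'
#' Container for a sampled multichannel ECG: an amplitude matrix (one column
#' per channel, in mV), the sampling rate, and optional reference R-peak
#' annotations for the fetal and maternal beats. All sample indices in this
#' package are 1-based, R's native convention.
#'
#' @param data numeric matrix, N samples x C channels (a vector is treated as
#'   one channel).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names optional character vector of C channel labels.
#' @param ref_fetal_r,ref_maternal_r optional strictly increasing integer
#'   vectors of reference R-peak sample indices in `[1, N]`.
#' @return an object of class `ecg_record` with fields `data`, `fs`,
#'   `channel_names`, `ref_fetal_r`, `ref_maternal_r`.
#' @examples
#' rec <- ecg_record(matrix(rnorm(2000), ncol = 2), fs = 1000)
#' n_channels(rec)
#' @export
ecg_record <- function(data, fs, channel_names = NULL,
                       ref_fetal_r = NULL, ref_maternal_r = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 1L || nrow(data) < 2L) {
    stop_fecg("fecg_format_error", "record needs >= 1 channel and >= 2 samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_fecg("fecg_value_error", "fs must be a positive scalar (Hz)")
  }
  if (is.null(channel_names)) {
    channel_names <- colnames(data)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(data)))
    }
  }
  stopifnot(length(channel_names) == ncol(data))
  colnames(data) <- channel_names
  check_ref <- function(r, what) {
    if (is.null(r) || length(r) == 0L) return(NULL)
    r <- as.integer(r)
    if (any(r < 1L) || any(r > nrow(data))) {
      stop_fecg("fecg_value_error", "%s indices out of range [1, %d]", what, nrow(data))
    }
    if (is.unsorted(r, strictly = TRUE)) {
      stop_fecg("fecg_value_error", "%s indices must be strictly increasing", what)
    }
    r
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 ref_fetal_r = check_ref(ref_fetal_r, "ref_fetal_r"),
                 ref_maternal_r = check_ref(ref_maternal_r, "ref_maternal_r")),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$ref_fetal_r)) {
    cat(sprintf("  fetal reference R peaks: %d\n", length(x$ref_fetal_r)))
  }
  if (!is.null(x$ref_maternal_r)) {
    cat(sprintf("  maternal reference R peaks: %d\n", length(x$ref_maternal_r)))
  }
  invisible(x)
}

#' @rdname ecg_record
#' @param x an `ecg_record`.
#' @export
n_channels <- function(x) ncol(x$data)

#' @rdname ecg_record
#' @export
n_samples <- function(x) nrow(x$data)
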