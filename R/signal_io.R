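#' Read a WFDB record
#'
#' Reads a single-segment WFDB record (header `.hea` plus signal file) in
#' storage format 16 (16-bit two's complement, little-endian) or 212 (packed
#' 12-bit pairs) — the formats used by the public abdominal fetal-ECG
#' databases. Amplitudes are converted to physical units via each signal's
#' gain and baseline. If a companion MIT-format beat annotation file exists
#' next to the header (`<record>.fqrs` or `<record>.qrs` for fetal R peaks,
#' `<record>.mqrs` for maternal) its sample indices populate the reference
#' fields.
#'
#' @param path path to the `.hea` header, or the record name without
#'   extension.
#' @return an [ecg_record].
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop_fecg("fecg_format_error", "WFDB header not found: %s", hea)
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop_fecg("fecg_format_error", "corrupt WFDB header (too few lines): %s", hea)
  }
  top <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(top) < 4L) {
    stop_fecg("fecg_format_error", "corrupt WFDB header record line: %s", hea)
  }
  if (grepl("/", top[[1L]])) {
    stop_fecg("fecg_unsupported_format", "multi-segment WFDB records are not supported: %s", hea)
  }
  nsig <- as.integer(top[[2L]])
  fs <- as.numeric(sub("/.*$", "", top[[3L]]))   # strip counter frequency
  nsamp <- as.integer(top[[4L]])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp)) {
    stop_fecg("fecg_format_error", "corrupt WFDB header fields: %s", hea)
  }
  sig <- lines[2:(1L + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt_tok <- f[[2L]]
    if (grepl("[x:+]", fmt_tok)) {
      stop_fecg("fecg_unsupported_format",
                "WFDB frame/skew/offset specs not supported: %s", fmt_tok)
    }
    gain_tok <- if (length(f) >= 3L) f[[3L]] else "200"
    baseline <- 0
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    }
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_tok)))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[[5L]])) else NA
    if (!grepl("\\(", gain_tok) && !is.na(adc_zero)) baseline <- adc_zero
    list(file = f[[1L]], fmt = as.integer(fmt_tok), gain = gain,
         baseline = baseline,
         name = if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else NA)
  }
  specs <- lapply(sig, parse_sig)
  fmts <- vapply(specs, `[[`, integer(1), "fmt")
  if (!all(fmts %in% c(16L, 212L))) {
    stop_fecg("fecg_unsupported_format",
              "unsupported WFDB storage format(s): %s (only 16 and 212)",
              paste(unique(fmts[!fmts %in% c(16L, 212L)]), collapse = ", "))
  }
  files <- vapply(specs, `[[`, character(1), "file")
  if (length(unique(files)) != 1L || length(unique(fmts)) != 1L) {
    stop_fecg("fecg_unsupported_format", "multi-file WFDB records are not supported")
  }
  dat_path <- file.path(dirname(hea), files[[1L]])
  if (!file.exists(dat_path)) {
    stop_fecg("fecg_format_error", "WFDB signal file not found: %s", dat_path)
  }
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  digital <- if (fmts[[1L]] == 16L) {
    matrix(readBin(raw, "integer", n = nsig * nsamp, size = 2L,
                   signed = TRUE, endian = "little"),
           nrow = nsig)
  } else {
    unpack_212(raw, nsig * nsamp, nsig)
  }
  if (ncol(digital) < nsamp) {
    stop_fecg("fecg_format_error", "WFDB signal file shorter than header claims: %s", dat_path)
  }
  phys <- matrix(0, nrow = nsamp, ncol = nsig)
  for (i in seq_len(nsig)) {
    phys[, i] <- (digital[i, seq_len(nsamp)] - specs[[i]]$baseline) / specs[[i]]$gain
  }
  nm <- vapply(specs, function(s) if (is.na(s$name)) "" else s$name, character(1))
  if (any(!nzchar(nm))) nm <- paste0("ch", seq_len(nsig))
  base <- sub("\\.hea$", "", hea)
  ann_of <- function(ext) {
    p <- paste0(base, ".", ext)
    if (file.exists(p)) read_wfdb_ann(p) else NULL
  }
  fet <- ann_of("fqrs")
  if (is.null(fet)) fet <- ann_of("qrs")
  ecg_record(phys, fs, channel_names = nm,
             ref_fetal_r = fet, ref_maternal_r = ann_of("mqrs"))
}

# Unpack WFDB format 212: two 12-bit samples per 3 bytes.
unpack_212 <- function(raw, n_total, nsig) {
  n_pairs <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n_pairs)]), nrow = 3L)
  s1 <- b[1L, ] + 256L * (b[2L, ] %% 16L)
  s2 <- b[3L, ] + 256L * (b[2L, ] %/% 16L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))[seq_len(n_total)]
  matrix(v, nrow = nsig)
}

# Minimal WFDB writer (format 16), used for fixtures and round trips.
#' Write a WFDB record (format 16)
#'
#' @param record an [ecg_record].
#' @param path record name without extension; writes `<path>.hea` and
#'   `<path>.dat`, plus `.fqrs`/`.mqrs` annotation files when the record has
#'   reference R peaks.
#' @param gain ADC gain (units per mV) used for quantization.
#' @export
write_wfdb <- function(record, path, gain = 1000) {
  nsig <- n_channels(record)
  nsamp <- n_samples(record)
  rec_name <- basename(path)
  dat_name <- paste0(rec_name, ".dat")
  digital <- round(t(record$data) * gain)  # nsig x nsamp
  digital <- pmin(pmax(digital, -32768), 32767)
  hdr <- c(sprintf("%s %d %g %d", rec_name, nsig, record$fs, nsamp),
           sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s",
                   dat_name, gain, record$channel_names))
  writeLines(hdr, paste0(path, ".hea"))
  writeBin(as.integer(digital), paste0(path, ".dat"),
           size = 2L, endian = "little")
  if (!is.null(record$ref_fetal_r)) {
    write_wfdb_ann(record$ref_fetal_r, paste0(path, ".fqrs"))
  }
  if (!is.null(record$ref_maternal_r)) {
    write_wfdb_ann(record$ref_maternal_r, paste0(path, ".mqrs"))
  }
  invisible(path)
}

#' Read an MIT-format beat annotation file
#'
#' Returns the 1-based sample indices of all beat annotations. Handles the
#' SKIP (59), NUM/SUB/CHAN (60-62) and AUX (63) pseudo-annotations.
#'
#' @param path annotation file path.
#' @export
read_wfdb_ann <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw)
  i <- 1L
  t <- 0
  out <- numeric(0)
  while (i + 1L <= n) {
    w <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
    i <- i + 2L
    code <- w %/% 1024L
    delta <- w %% 1024L
    if (code == 0L && delta == 0L) break
    if (code == 59L) {            # SKIP: 4-byte interval, high word first
      if (i + 3L > n) break
      hi <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
      lo <- as.integer(raw[i + 2L]) + 256L * as.integer(raw[i + 3L])
      i <- i + 4L
      t <- t + hi * 65536 + lo
    } else if (code == 63L) {     # AUX: skip payload (padded to even length)
      i <- i + delta + (delta %% 2L)
    } else if (code >= 60L) {
      # NUM/SUB/CHAN carry no time
    } else {
      t <- t + delta
      out <- c(out, t)
    }
  }
  as.integer(out) + 1L  # WFDB annotation times are 0-based sample numbers
}

# MIT annotation writer (NORMAL beats), inverse of read_wfdb_ann.
write_wfdb_ann <- function(samples, path) {
  t0 <- as.integer(samples) - 1L
  deltas <- diff(c(0L, t0))
  words <- integer(0)
  for (d in deltas) {
    while (d > 1023L) {
      hi <- d %/% 65536L
      lo <- d %% 65536L
      words <- c(words, 59L * 1024L, hi, lo)  # SKIP + 4-byte interval
      d <- 0L
    }
    words <- c(words, 1L * 1024L + d)          # NORMAL beat
  }
  words <- c(words, 0L)                        # terminator
  bytes <- as.raw(rbind(words %% 256L, words %/% 256L))
  writeBin(bytes, path)
  invisible(path)
}

#' Read a multichannel record from CSV
#'
#' One column per channel, header row with channel names. If the first
#' column is named `time` (case-insensitive) it is interpreted as seconds and
#' the sampling rate is inferred from its step; otherwise `fs` must be given.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz; may be omitted when a time column exists.
#' @return an [ecg_record].
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L) stop_fecg("fecg_format_error", "empty CSV: %s", path)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop_fecg("fecg_parse_error",
                "non-numeric cell at row %d, column %d (%s) of %s",
                if (is.na(bad)) 1L else bad, j, names(df)[j], path)
    }
  }
  first_is_time <- tolower(names(df)[1L]) %in% c("time", "t", "time_s")
  if (first_is_time) {
    tcol <- df[[1L]]
    step <- stats::median(diff(tcol))
    if (!is.finite(step) || step <= 0) {
      stop_fecg("fecg_format_error", "time column is not increasing in %s", path)
    }
    if (is.null(fs)) fs <- 1 / step
    df <- df[, -1L, drop = FALSE]
  }
  if (is.null(fs)) {
    stop_fecg("fecg_value_error", "fs not given and no time column in %s", path)
  }
  ecg_record(as.matrix(df), fs, channel_names = names(df))
}

#' Write a record to CSV
#'
#' @param record an [ecg_record].
#' @param path output path.
#' @param time_column prepend a `time` column in seconds.
#' @export
write_ecg_csv <- function(record, path, time_column = FALSE) {
  df <- as.data.frame(record$data)
  names(df) <- record$channel_names
  if (time_column) {
    df <- cbind(time = (seq_len(nrow(df)) - 1) / record$fs, df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

fiducial_columns <- c("beat", "P_on", "P_peak", "P_off", "Q", "QRS_on", "R",
                      "S", "QRS_off", "T_on", "T_peak", "T_off",
                      "ST_start", "ST_end")

#' Write delineation fiducials to CSV
#'
#' One row per beat; columns beat, P_on, P_peak, P_off, Q, QRS_on, R, S,
#' QRS_off, T_on, T_peak, T_off, ST_start, ST_end (1-based sample indices;
#' empty cell = undetected).
#'
#' @param fid a [fiducial_set] (or its `beats` data frame).
#' @param path output path.
#' @export
write_fiducials <- function(fid, path) {
  df <- if (inherits(fid, "fiducial_set")) fid$beats else fid
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(integer(0)), length(fiducial_columns)),
                                 fiducial_columns))
  }
  missing_cols <- setdiff(fiducial_columns, names(df))
  for (mc in missing_cols) df[[mc]] <- NA_integer_
  utils::write.csv(df[fiducial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a fiducial CSV written by [write_fiducials()]
#'
#' @param path CSV path.
#' @return the beats data frame.
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path)
  for (j in seq_along(df)) df[[j]] <- as.integer(df[[j]])
  df
}
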