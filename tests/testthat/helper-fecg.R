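# Shared fixtures, generated in code at test time.

# Three strongly non-Gaussian, zero-mean, unit-variance sources.
make_three_sources <- function(n = 20000, fs = 1000) {
  t <- (1:n) / fs
  S <- rbind(sin(2 * pi * 7 * t),
             2 * (5 * t - floor(5 * t)) - 1,     # 5 Hz sawtooth
             stats::runif(n, -1, 1))
  S <- S - rowMeans(S)
  S / apply(S, 1, stats::sd)
}

# Unit-norm beat matrix with all pairwise inner products equal to `rho`.
make_equicorrelated_beats <- function(m, rho, len = 32) {
  stopifnot(len >= m + 1)
  a <- sqrt(rho)
  b <- sqrt(1 - rho)
  U <- matrix(0, m, len)
  for (i in seq_len(m)) {
    U[i, 1] <- a
    U[i, i + 1] <- b
  }
  U
}

# Assert the canonical intra-beat fiducial ordering (NAs allowed).
expect_fiducial_ordering <- function(fid) {
  b <- fid$beats
  ord_cols <- c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S",
                "QRS_off", "T_on", "T_peak", "T_off")
  for (i in seq_len(nrow(b))) {
    v <- unlist(b[i, ord_cols])
    v <- v[!is.na(v)]
    expect_false(is.unsorted(v),
                 label = sprintf("fiducial ordering in beat %d", i))
  }
  expect_false(is.unsorted(b$R, strictly = TRUE))
  st <- b[!is.na(b$ST_start) & !is.na(b$ST_end), ]
  if (nrow(st)) {
    expect_true(all(st$ST_start == st$QRS_off))
    expect_true(all(st$ST_end == st$T_on))
  }
  invisible(fid)
}

# A mixed abdominal record plus a run of the full pipeline, cached per seed
# so several tests can share one extraction.
extraction_cache <- new.env(parent = emptyenv())
cached_extraction <- function(seed, duration_s = 60) {
  key <- sprintf("s%d_d%d", seed, duration_s)
  if (is.null(extraction_cache[[key]])) {
    sr <- synth_abdominal(synth_config(seed = seed, duration_s = duration_s))
    res <- suppressWarnings(extract_fecg(sr$record, seed = seed))
    extraction_cache[[key]] <- list(sr = sr, res = res)
  }
  extraction_cache[[key]]
}
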