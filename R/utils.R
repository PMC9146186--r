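# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so package functions never leak global randomness.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Next odd integer >= n (running-median windows must be odd).
odd_window <- function(n) {
  n <- max(1L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

# Local maxima of a numeric vector: strictly greater than the left neighbour,
# at least as great as the right one (dedupes 2-sample plateaus).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  1L + which(v[i] > v[i - 1L] & v[i] >= v[i + 1L])
}

local_minima <- function(v) local_maxima(-v)

# Linear resampling of a vector to a given length (endpoints preserved).
resample_linear <- function(v, n_out) {
  n_in <- length(v)
  if (n_in == n_out) return(v)
  if (n_in == 1L) return(rep(v, n_out))
  stats::approx(seq_len(n_in), v, xout = seq(1, n_in, length.out = n_out))$y
}

stop_fecg <- function(class, msg, ...) {
  stop(structure(class = c(class, "fecg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
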