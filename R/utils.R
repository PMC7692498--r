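# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

#' Window arithmetic between milliseconds and samples
#'
#' The validator operates on fixed-duration windows (833 ms by default), which
#' corresponds to a sampling-rate-dependent number of samples: 300 samples at
#' 360 Hz, 833 samples at 1000 Hz.
#'
#' @param ms window duration in milliseconds.
#' @param n window length in samples.
#' @param fs sampling frequency in Hz.
#' @return `window_samples()` gives the number of samples spanning `ms`
#'   milliseconds; `window_duration_ms()` the duration in milliseconds of an
#'   `n`-sample window. Both round to the nearest integer.
#' @examples
#' window_samples(833, 360)      # 300
#' window_duration_ms(300, 360)  # 833
#' @export
window_samples <- function(ms, fs) {
  stopifnot(ms > 0, fs > 0)
  as.integer(round(ms * fs / 1000))
}

#' @rdname window_samples
#' @export
window_duration_ms <- function(n, fs) {
  stopifnot(n > 0, fs > 0)
  as.integer(round(n / fs * 1000))
}
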