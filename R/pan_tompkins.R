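# Pan-Tompkins QRS detection cascade: band-pass -> five-point derivative ->
# squaring -> moving-window integration -> dual adaptive thresholds with
# 200-ms refractory, T-wave slope discrimination and 166%-RR searchback.

#' QRS band-pass filter (~5-15 Hz)
#'
#' Zero-phase Butterworth band-pass (order 3, applied forward and backward
#' with `signal::filtfilt`), so the filtered signal stays aligned with the
#' input and the cascade's reported group delay for this stage is zero. The
#' passband emphasises QRS energy while suppressing baseline wander and
#' T/P-wave frequencies.
#'
#' @param values amplitude series.
#' @param fs sampling rate in Hz, >= 100 (the design degenerates below that).
#' @param low,high band edges in Hz.
#' @return Filtered series, same length as the input.
#' @export
pt_bandpass <- function(values, fs, low = 5, high = 15) {
  if (fs < 100) stop("`fs` must be >= 100 Hz for the band-pass design")
  bf <- signal::butter(3, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(values)))
}

#' Five-point derivative
#'
#' `y[n] = (fs/8) * (2 x[n] + x[n-1] - x[n-3] - 2 x[n-4])`, the classic slope
#' estimator of the cascade; the first four samples (edge region) are zero.
#'
#' @param values amplitude series, length >= 5.
#' @param fs sampling rate in Hz.
#' @return Derivative series, same length as the input.
#' @export
pt_derivative <- function(values, fs) {
  if (length(values) < 5L) stop("input must have at least 5 samples")
  y <- stats::filter(as.numeric(values), c(2, 1, 0, -1, -2), method = "convolution",
                     sides = 1)
  y <- as.numeric(y) * fs / 8
  y[1:4] <- 0
  y
}

#' Squaring step
#'
#' Elementwise square, making all energy positive and intensifying the slope
#' signal relative to T waves.
#'
#' @param values amplitude series.
#' @return `values^2`.
#' @export
pt_square <- function(values) as.numeric(values)^2

#' Moving-window integration
#'
#' Causal moving average over `round(width_ms * fs / 1000)` samples (150 ms by
#' default, the original window width), with zero-padding before the first
#' sample so the output length equals the input length.
#'
#' @param values amplitude series.
#' @param fs sampling rate in Hz.
#' @param width_ms window width in milliseconds, > 0.
#' @return Integrated series, same length as the input.
#' @export
pt_mwi <- function(values, fs, width_ms = 150) {
  if (width_ms <= 0) stop("`width_ms` must be > 0")
  n <- length(values)
  N <- as.integer(round(width_ms * fs / 1000))
  if (N < 1L) stop("integration window shorter than one sample")
  if (N > n) stop("integration window longer than the signal")
  cs <- cumsum(as.numeric(values))
  (cs - c(rep(0, N), cs[seq_len(n - N)])) / N
}

#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' Runs the full cascade, then scans the local maxima of the integrated
#' signal with the dual adaptive thresholds: candidates above THR1 are
#' accepted directly; when no beat has been found within 166% of the running
#' mean RR interval, the interval is re-examined and the largest skipped
#' candidate above THR2 (= THR1/2) is accepted via searchback with halved
#' update weight. Candidates within 200 ms of the previous beat are vetoed
#' (physiological refractory period), and candidates 200-360 ms after a beat
#' whose maximal slope is less than half the previous beat's are discarded as
#' T waves. Each accepted beat is localised as the argmax of the band-passed
#' signal magnitude in the window preceding the integrated-signal peak; since
#' the band-pass is zero-phase, peaks are reported directly in original-signal
#' coordinates (`delay = 0`).
#'
#' Thresholds are learned from the first 2 s of the integrated signal and
#' adapt continuously (signal/noise running estimates with 0.125 update
#' weight; THR1 = noise + 0.25 * (signal - noise)). All thresholds scale with
#' the signal, so detection indices are invariant to positive rescaling.
#'
#' @param record an [ecg_record()] at least 2 s long.
#' @param refractory_s minimum inter-beat interval, seconds.
#' @param twave_window_s upper edge of the T-wave discrimination zone, seconds.
#' @param searchback_factor RR multiple that triggers searchback.
#' @return A [detection_result()] with 0-based, delay-corrected peak indices.
#' @export
pt_detect <- function(record, refractory_s = 0.2, twave_window_s = 0.36,
                      searchback_factor = 1.66) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < 2 * fs) stop("record must be at least 2 s long")
  bp <- pt_bandpass(x, fs)
  der <- pt_derivative(bp, fs)
  sq <- pt_square(der)
  mwi <- pt_mwi(sq, fs, 150)
  N <- as.integer(round(0.150 * fs))
  refr <- as.integer(round(refractory_s * fs))

  pk <- pracma::findpeaks(mwi, minpeakdistance = refr)
  if (is.null(pk) || nrow(pk) == 0L) {
    return(detection_result(integer(0), delay = 0L))
  }
  ord <- order(pk[, 2])
  cand_i <- pk[ord, 2]   # 1-based indices into mwi
  cand_v <- pk[ord, 1]

  learn <- mwi[seq_len(min(length(mwi), as.integer(2 * fs)))]
  spki <- max(learn) / 3
  npki <- mean(learn) / 2
  thr1 <- npki + 0.25 * (spki - npki)
  thr2 <- thr1 / 2

  qrs_mwi <- integer(0)    # accepted candidate positions in mwi coordinates
  r_idx <- integer(0)      # localised R indices (1-based into x)
  rr_hist <- numeric(0)    # last RR intervals (samples)
  rr_avg <- NA_real_
  noise_pool_i <- integer(0)  # rejected candidates eligible for searchback
  noise_pool_v <- numeric(0)

  slope_at <- function(i) {
    lo <- max(1L, i - as.integer(round(0.075 * fs)))
    max(abs(der[lo:i]))
  }
  localize <- function(i) {
    lo <- max(1L, i - N - 4L)
    lo - 1L + which.max(abs(bp[lo:i]))
  }
  accept <- function(i, searchback = FALSE) {
    w <- if (searchback) 0.25 else 0.125
    spki <<- w * mwi[i] + (1 - w) * spki
    if (length(qrs_mwi)) {
      rr <- i - qrs_mwi[length(qrs_mwi)]
      rr_hist <<- c(rr_hist, rr)
      if (length(rr_hist) > 8L) rr_hist <<- rr_hist[-1L]
      rr_avg <<- mean(rr_hist)
    }
    qrs_mwi <<- c(qrs_mwi, i)
    r_idx <<- c(r_idx, localize(i))
  }

  for (k in seq_along(cand_i)) {
    i <- cand_i[k]
    v <- cand_v[k]
    # Searchback: if this candidate arrives far beyond the expected RR, look
    # for a skipped candidate above THR2 in the gap.
    if (length(qrs_mwi) && is.finite(rr_avg) &&
        (i - qrs_mwi[length(qrs_mwi)]) > searchback_factor * rr_avg &&
        length(noise_pool_i)) {
      gapmask <- noise_pool_i > qrs_mwi[length(qrs_mwi)] & noise_pool_i < i &
        noise_pool_v > thr2 &
        (noise_pool_i - qrs_mwi[length(qrs_mwi)]) >= refr
      if (any(gapmask)) {
        j <- noise_pool_i[gapmask][which.max(noise_pool_v[gapmask])]
        accept(j, searchback = TRUE)
        thr1 <- npki + 0.25 * (spki - npki)
        thr2 <- thr1 / 2
      }
    }
    if (length(qrs_mwi) && (i - qrs_mwi[length(qrs_mwi)]) < refr) next
    is_twave <- FALSE
    if (length(qrs_mwi) && (i - qrs_mwi[length(qrs_mwi)]) < round(twave_window_s * fs)) {
      if (slope_at(i) <= 0.5 * slope_at(qrs_mwi[length(qrs_mwi)])) is_twave <- TRUE
    }
    if (v > thr1 && !is_twave) {
      accept(i)
    } else {
      npki <- 0.125 * v + 0.875 * npki
      noise_pool_i <- c(noise_pool_i, i)
      noise_pool_v <- c(noise_pool_v, v)
    }
    thr1 <- npki + 0.25 * (spki - npki)
    thr2 <- thr1 / 2
  }
  # Trailing searchback: a missed final beat leaves a long tail gap.
  if (length(qrs_mwi) && is.finite(rr_avg) &&
      (length(mwi) - qrs_mwi[length(qrs_mwi)]) > searchback_factor * rr_avg &&
      length(noise_pool_i)) {
    gapmask <- noise_pool_i > qrs_mwi[length(qrs_mwi)] & noise_pool_v > thr2 &
      (noise_pool_i - qrs_mwi[length(qrs_mwi)]) >= refr
    if (any(gapmask)) {
      accept(noise_pool_i[gapmask][which.max(noise_pool_v[gapmask])],
             searchback = TRUE)
    }
  }

  if (!length(r_idx)) return(detection_result(integer(0), delay = 0L))
  # Enforce the refractory invariant on the final localised peaks: keep the
  # larger band-passed magnitude when two localisations collide.
  ord <- order(r_idx)
  r_idx <- r_idx[ord]
  keep <- rep(TRUE, length(r_idx))
  last <- 1L
  for (k in seq_along(r_idx)[-1L]) {
    if (r_idx[k] - r_idx[last] < refr) {
      if (abs(bp[r_idx[k]]) > abs(bp[r_idx[last]])) {
        keep[last] <- FALSE; last <- k
      } else {
        keep[k] <- FALSE
      }
    } else {
      last <- k
    }
  }
  detection_result(unique(r_idx[keep]) - 1L, delay = 0L)  # back to 0-based
}
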