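#' Beat morphology template: five Gaussian fiducial waves
#'
#' One cardiac cycle is modelled as a sum of five Gaussians, one per fiducial
#' wave (P, Q, R, S, T), each parameterised by an amplitude relative to the
#' R wave, a centre offset from the R peak in seconds (negative before, positive
#' after), and a Gaussian width in seconds. Defaults follow textbook
#' proportions: a small rounded P wave ~220 ms before R, sharp narrow Q/S
#' deflections flanking R, and a broad T wave ~300 ms after R.
#'
#' @param amplitude named numeric vector of wave amplitudes (R positive and
#'   strictly largest in magnitude).
#' @param offset named numeric vector of wave centre offsets from the R peak,
#'   seconds. Must satisfy P < Q < 0 < S < T; R is fixed at 0.
#' @param width named numeric vector of Gaussian widths, seconds, all > 0.
#' @return A `data.frame` with columns `wave`, `amplitude`, `offset`, `width`,
#'   of class `beat_template`.
#' @export
beat_template <- function(amplitude = c(P = 0.15, Q = -0.10, R = 1.0, S = -0.20, T = 0.30),
                          offset    = c(P = -0.22, Q = -0.04, R = 0, S = 0.04, T = 0.30),
                          width     = c(P = 0.05, Q = 0.01, R = 0.015, S = 0.01, T = 0.08)) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(amplitude, offset, width)) {
    if (!all(waves %in% names(v))) stop("amplitude/offset/width must be named with P,Q,R,S,T")
  }
  amplitude <- amplitude[waves]; offset <- offset[waves]; width <- width[waves]
  if (any(width <= 0)) stop("all wave widths must be > 0")
  if (amplitude[["R"]] <= 0) stop("R amplitude must be positive")
  if (any(abs(amplitude[c("P", "Q", "S", "T")]) >= amplitude[["R"]])) {
    stop("R amplitude must strictly exceed |amplitude| of every other wave")
  }
  if (!(offset[["P"]] < offset[["Q"]] && offset[["Q"]] < 0 &&
        0 < offset[["S"]] && offset[["S"]] < offset[["T"]])) {
    stop("wave offsets must satisfy P < Q < 0 < S < T")
  }
  structure(data.frame(wave = waves, amplitude = as.numeric(amplitude),
                       offset = as.numeric(offset), width = as.numeric(width),
                       stringsAsFactors = FALSE),
            class = c("beat_template", "data.frame"))
}

# Half-width of a template's footprint in seconds: the farthest wave centre
# plus three of its widths. Used to size the record's lead-in/out padding.
template_footprint <- function(template) {
  max(abs(template$offset) + 3 * template$width)
}

# Half-width of the QRS core (Q, R, S extent). Beats whose cores would
# overlap at the requested RR are rejected: P/T waves of adjacent beats may
# overlap at short RR (physiological), but merged QRS complexes would break
# the ground-truth annotation.
qrs_footprint <- function(template) {
  qrs <- template$wave %in% c("Q", "R", "S")
  max(abs(template$offset[qrs]) + 3 * template$width[qrs])
}

#' Noise component specification
#'
#' Standard ECG noise taxonomy: `baseline_wander` (low-frequency sinusoid,
#' default 0.3 Hz, emulating respiration/electrode drift), `powerline`
#' (mains sinusoid, default 50 Hz) and `highfreq` (band-limited white noise
#' above a cutoff, default 25 Hz — the component that distorts P/T morphology
#' and degrades morphology-based validators).
#'
#' @param kind one of `"baseline_wander"`, `"highfreq"`, `"powerline"`.
#' @param amplitude noise amplitude as a fraction of the template R amplitude
#'   (sinusoid amplitude, or standard deviation for `highfreq`). Must be >= 0.
#' @param freq characteristic frequency in Hz (sinusoid frequency, or the
#'   high-pass cutoff for `highfreq`). Must be positive and below Nyquist of
#'   the record it is applied to.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("baseline_wander", "highfreq", "powerline"),
                       amplitude = 0.1, freq = NULL) {
  kind <- match.arg(kind)
  if (is.null(freq)) {
    freq <- switch(kind, baseline_wander = 0.3, highfreq = 25, powerline = 50)
  }
  if (!is.numeric(amplitude) || amplitude < 0) stop("noise amplitude must be >= 0")
  if (!is.numeric(freq) || freq <= 0) stop("noise frequency must be > 0")
  structure(list(kind = kind, amplitude = as.numeric(amplitude),
                 freq = as.numeric(freq)),
            class = "noise_spec")
}

# Render one noise component for a record of n samples at fs Hz. Assumes the
# RNG is already seeded by the caller.
render_noise <- function(spec, n, fs, r_amp) {
  if (spec$freq >= fs / 2) {
    stop(sprintf("noise frequency %g Hz is not below Nyquist (%g Hz)",
                 spec$freq, fs / 2))
  }
  if (spec$amplitude == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  a <- spec$amplitude * r_amp
  switch(spec$kind,
    baseline_wander = ,
    powerline = a * sin(2 * pi * spec$freq * t + stats::runif(1, 0, 2 * pi)),
    highfreq = {
      w <- stats::rnorm(n)
      bf <- signal::butter(4, spec$freq / (fs / 2), type = "high")
      hf <- signal::filtfilt(bf, w)
      a * hf / stats::sd(hf)
    })
}

#' Generate an annotated synthetic ECG record
#'
#' Places `n_beats` copies of a five-Gaussian beat template at quasi-periodic
#' positions (RR intervals jittered i.i.d. uniformly in
#' `[-rr_jitter, +rr_jitter]` around `mean_rr`), superimposes the requested
#' noise components, and returns the record with the exact template centres as
#' ground-truth R-peak annotations. Identical arguments and seed reproduce the
#' record bit-for-bit.
#'
#' @param n_beats number of beats, >= 1.
#' @param fs sampling frequency in Hz, >= 100.
#' @param mean_rr mean RR interval in seconds; must exceed twice the template
#'   footprint so consecutive beats do not overlap.
#' @param rr_jitter half-width of the uniform RR jitter, seconds, >= 0.
#' @param template a [beat_template()].
#' @param noise list of [noise_spec()] objects (empty for a noise-free record).
#' @param seed integer seed controlling jitter and noise.
#' @param record_id,subject_id identity strings for the returned record.
#' @return An [ecg_record()] with exactly `n_beats` annotated R-peaks.
#' @examples
#' rec <- generate_record(20, fs = 360, mean_rr = 0.8, seed = 1)
#' diff(rec$r_peaks)  # all 288 samples when rr_jitter = 0
#' @export
generate_record <- function(n_beats, fs = 360, mean_rr = 0.8, rr_jitter = 0,
                            template = beat_template(), noise = list(),
                            seed = 1, record_id = "synth", subject_id = record_id) {
  if (!is_count(n_beats) || n_beats < 1) stop("`n_beats` must be a count >= 1")
  if (fs < 100) stop("`fs` must be >= 100 Hz")
  if (rr_jitter < 0) stop("`rr_jitter` must be >= 0")
  fp <- template_footprint(template)
  core <- qrs_footprint(template)
  if (mean_rr - rr_jitter <= 2 * core) {
    stop(sprintf(paste("`mean_rr` (%g s, jitter %g s) too short for the template's",
                       "QRS footprint: complexes would merge; need mean_rr - rr_jitter > %g s"),
         mean_rr, rr_jitter, 2 * core))
  }
  if (inherits(noise, "noise_spec")) noise <- list(noise)
  with_seed(seed, {
    rr <- if (n_beats > 1) {
      mean_rr + stats::runif(n_beats - 1, -rr_jitter, rr_jitter)
    } else {
      numeric(0)
    }
    rr_samp <- round(rr * fs)
    # Lead-in/out long enough for the template tails and for centred
    # validation windows around the first/last beats.
    pad <- max(ceiling(fp * fs) + 1L, ceiling(0.5 * fs))
    r_idx <- pad + c(0, cumsum(rr_samp))          # 0-based annotation indices
    n <- as.integer(r_idx[n_beats] + pad + 1L)
    x <- numeric(n)
    for (b in seq_len(n_beats)) {
      for (w in seq_len(nrow(template))) {
        amp <- template$amplitude[w]
        ctr <- r_idx[b] + template$offset[w] * fs   # samples, 0-based, real
        sd_s <- template$width[w] * fs
        lo <- max(0L, floor(ctr - 4.5 * sd_s))
        hi <- min(n - 1L, ceiling(ctr + 4.5 * sd_s))
        k <- lo:hi
        x[k + 1L] <- x[k + 1L] + amp * exp(-((k - ctr)^2) / (2 * sd_s^2))
      }
    }
    r_amp <- template$amplitude[template$wave == "R"]
    for (ns in noise) x <- x + render_noise(ns, n, fs, r_amp)
    ecg_record(x, fs, r_idx, record_id = record_id, subject_id = subject_id)
  })
}

#' Corrupt a set of true R-peak indices to emulate a faulty detector
#'
#' Drops `round(fn_rate * N)` true peaks, jitters the survivors by an integer
#' offset drawn uniformly from `[-jitter, +jitter]`, and injects
#' `round(fp_rate * N)` spurious peaks placed at least `0.2 * fs` samples from
#' every true peak (outside both the physiological refractory period and the
#' evaluation matching tolerance), so the validator's false-positive
#' suppression can be measured against known contamination.
#'
#' @param truth integer vector of true R-peak indices (0-based, sorted).
#' @param fp_rate,fn_rate fractions in `[0, 1]`.
#' @param jitter maximum absolute displacement of surviving peaks, samples.
#' @param record_len record length in samples; all output indices lie in
#'   `[0, record_len)`.
#' @param seed integer seed.
#' @param fs sampling rate used only to compute the `0.2 * fs` exclusion gap
#'   around true peaks for injected false positives.
#' @return A [detection_result()] with sorted unique indices.
#' @export
corrupt_detections <- function(truth, fp_rate = 0, fn_rate = 0, jitter = 0,
                               record_len, seed = 1, fs = 360) {
  if (fp_rate < 0 || fp_rate > 1) stop("`fp_rate` must be in [0, 1]")
  if (fn_rate < 0 || fn_rate > 1) stop("`fn_rate` must be in [0, 1]")
  if (!is_count(record_len) || record_len < 1) stop("`record_len` must be a positive count")
  truth <- as.integer(truth)
  n <- length(truth)
  with_seed(seed, {
    keep <- truth
    n_fn <- round(fn_rate * n)
    if (n_fn > 0) keep <- truth[-sample.int(n, n_fn)]
    if (jitter > 0 && length(keep)) {
      keep <- keep + sample.int(2L * as.integer(jitter) + 1L, length(keep),
                                replace = TRUE) - as.integer(jitter) - 1L
      keep <- pmin(pmax(keep, 0L), as.integer(record_len) - 1L)
    }
    n_fp <- round(fp_rate * n)
    fp <- integer(0)
    if (n_fp > 0) {
      gap <- ceiling(0.2 * fs)
      cand <- sample.int(record_len, min(record_len, 50L * n_fp + 200L)) - 1L
      if (n) {
        near <- vapply(cand, function(p) min(abs(p - truth)), numeric(1))
        cand <- cand[near >= gap]
      }
      if (length(cand) < n_fp) {
        stop("could not place the requested number of false positives away from true peaks")
      }
      fp <- cand[seq_len(n_fp)]
    }
    detection_result(sort(unique(c(keep, fp))), delay = 0L)
  })
}
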