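#' Augmentation configuration
#'
#' Parameters of the sample-construction scheme: each eligible annotated beat
#' yields eleven positive (beat-labelled) windows — the centred window, six
#' time-shifted copies (±5, ±10, ±15 samples), P-wave and T-wave attenuated
#' variants (30% over 375 ms), and two globally attenuated copies (20% and
#' 40%) — while the stretches between consecutive beats yield negative
#' windows slid with a 5-sample stride, keeping a 50-sample margin after the
#' first beat and before the second.
#'
#' @param shifts positive shift magnitudes in samples; both signs are used.
#' @param wave_atten_frac attenuation fraction for the P/T-wave variants.
#' @param wave_extent_ms extent of the attenuated region before/after the R
#'   peak, milliseconds.
#' @param global_atten_fracs attenuation fractions applied to whole segments.
#' @param neg_margin margin (samples) kept clear after/before the flanking
#'   R-peaks when harvesting negative windows.
#' @param neg_stride stride (samples) of the negative sliding window.
#' @param window_ms segment duration, milliseconds.
#' @return An object of class `aug_config`.
#' @export
aug_config <- function(shifts = c(5L, 10L, 15L), wave_atten_frac = 0.30,
                       wave_extent_ms = 375, global_atten_fracs = c(0.20, 0.40),
                       neg_margin = 50L, neg_stride = 5L, window_ms = 833) {
  if (any(shifts <= 0)) stop("`shifts` must be positive magnitudes")
  if (wave_atten_frac < 0 || wave_atten_frac >= 1) stop("`wave_atten_frac` must be in [0, 1)")
  if (any(global_atten_fracs < 0 | global_atten_fracs >= 1)) {
    stop("`global_atten_fracs` must be in [0, 1)")
  }
  if (neg_margin <= 0 || neg_stride <= 0) stop("margins and strides must be positive")
  if (window_ms <= 0) stop("`window_ms` must be positive")
  structure(list(shifts = as.integer(shifts), wave_atten_frac = wave_atten_frac,
                 wave_extent_ms = wave_extent_ms,
                 global_atten_fracs = global_atten_fracs,
                 neg_margin = as.integer(neg_margin),
                 neg_stride = as.integer(neg_stride), window_ms = window_ms),
            class = "aug_config")
}

#' Number of positive variants produced per eligible beat
#'
#' Centred window + two signs per shift magnitude + P/T wave attenuations +
#' one variant per global attenuation fraction: 11 with the defaults, so a
#' training partition of B eligible beats yields exactly `11 * B` positives.
#'
#' @param cfg an [aug_config()].
#' @return Integer count.
#' @export
n_positive_variants <- function(cfg = aug_config()) {
  1L + 2L * length(cfg$shifts) +
    (if (cfg$wave_atten_frac > 0) 2L else 0L) +
    length(cfg$global_atten_fracs)
}

new_segment <- function(values, label, record_id, center, variant) {
  structure(list(values = as.numeric(values), label = label,
                 record_id = record_id, center = as.integer(center),
                 variant = variant),
            class = "ecg_segment")
}

#' Extract a fixed-length window centred on a sample
#'
#' Half-open window of `length` samples with `center` landing at index
#' `floor(length/2)` (0-based). Windows that would cross the record boundary
#' return `NULL` — a distinguishable out-of-bounds signal that callers use to
#' skip edge beats rather than padding them with fabricated samples.
#'
#' @param record an [ecg_record()].
#' @param center 0-based sample index.
#' @param length window length in samples.
#' @return Numeric vector of `length` samples, or `NULL` if out of bounds.
#' @export
extract_window <- function(record, center, length) {
  stopifnot(inherits(record, "ecg_record"), is_count(length), length >= 1)
  start <- center - length %/% 2L                 # 0-based
  if (start < 0L || start + length > base::length(record$samples)) return(NULL)
  record$samples[(start + 1L):(start + length)]
}

#' Attenuate the P- or T-wave region of a centred segment
#'
#' Multiplies the `round(extent_ms * fs / 1000)` samples strictly before
#' (`p_wave`) or strictly after (`t_wave`) the segment centre by
#' `1 - frac`, clipped to the segment bounds; all other samples are
#' unchanged. Used to teach the validator to tolerate noise-degraded P/T
#' morphology while relying on the QRS.
#'
#' @param values segment samples, centred on the R peak.
#' @param side `"p_wave"` or `"t_wave"`.
#' @param frac attenuation fraction in `[0, 1)`.
#' @param extent_ms extent of the affected region, milliseconds.
#' @param fs sampling rate in Hz.
#' @return The modified segment.
#' @export
attenuate_wave <- function(values, side = c("p_wave", "t_wave"), frac = 0.30,
                           extent_ms = 375, fs = 360) {
  side <- match.arg(side)
  if (frac < 0 || frac >= 1) stop("`frac` must be in [0, 1)")
  n <- length(values)
  ctr <- n %/% 2L                                  # 0-based centre index
  ext <- as.integer(round(extent_ms * fs / 1000))
  idx0 <- if (side == "p_wave") {
    seq.int(max(0L, ctr - ext), ctr - 1L)
  } else {
    seq.int(ctr + 1L, min(n - 1L, ctr + ext))
  }
  idx0 <- idx0[idx0 >= 0L & idx0 < n]
  out <- as.numeric(values)
  out[idx0 + 1L] <- out[idx0 + 1L] * (1 - frac)
  out
}

#' Attenuate an entire segment
#'
#' @param values segment samples.
#' @param frac attenuation fraction in `[0, 1)`; every sample is multiplied
#'   by `1 - frac`.
#' @return The scaled segment.
#' @export
global_attenuate <- function(values, frac) {
  if (frac < 0 || frac >= 1) stop("`frac` must be in [0, 1)")
  as.numeric(values) * (1 - frac)
}

#' Build the positive (beat-labelled) variants of one annotated beat
#'
#' Returns the full variant set for the beat at `r_index`: the centred
#' window; windows shifted so the R-peak sits ±5, ±10 and ±15 samples from
#' the centre (positive shift = R-peak right of centre); P- and T-attenuated
#' copies of the centred window; and 20%/40% globally attenuated copies — 11
#' segments with the default configuration. If any of the seven window
#' positions does not fit inside the record the beat is skipped entirely
#' (empty list), never padded.
#'
#' @param record an [ecg_record()].
#' @param r_index 0-based annotated R-peak index.
#' @param cfg an [aug_config()].
#' @return List of `ecg_segment` objects (length `n_positive_variants(cfg)`
#'   or 0).
#' @export
positive_variants <- function(record, r_index, cfg = aug_config()) {
  fs <- record$fs
  L <- window_samples(cfg$window_ms, fs)
  shifts <- c(0L, as.vector(rbind(-cfg$shifts, cfg$shifts)))
  # Shift +k puts the R-peak k samples right of centre => window centre r - k.
  centers <- r_index - shifts
  windows <- lapply(centers, function(ctr) extract_window(record, ctr, L))
  if (any(vapply(windows, is.null, logical(1)))) return(list())
  tag <- c("centered",
           if (length(cfg$shifts)) as.vector(rbind(paste0("shift-", cfg$shifts),
                                                   paste0("shift+", cfg$shifts))))
  segs <- mapply(function(w, ctr, tg) {
    new_segment(w, "beat", record$record_id, ctr, tg)
  }, windows, centers, tag, SIMPLIFY = FALSE)
  centered <- windows[[1L]]
  if (cfg$wave_atten_frac > 0) {
    segs <- c(segs, list(
      new_segment(attenuate_wave(centered, "p_wave", cfg$wave_atten_frac,
                                 cfg$wave_extent_ms, fs),
                  "beat", record$record_id, r_index, "p_atten"),
      new_segment(attenuate_wave(centered, "t_wave", cfg$wave_atten_frac,
                                 cfg$wave_extent_ms, fs),
                  "beat", record$record_id, r_index, "t_atten")))
  }
  for (g in cfg$global_atten_fracs) {
    segs <- c(segs, list(
      new_segment(global_attenuate(centered, g), "beat", record$record_id,
                  r_index, sprintf("global%d", round(100 * g)))))
  }
  segs
}

#' Harvest negative (non-beat) windows between consecutive beats
#'
#' For each consecutive annotated pair `(r1, r2)`, windows of `window_len`
#' samples start at `r1 + neg_margin` and advance by `neg_stride` while the
#' window still ends at or before `r2 - neg_margin` (windows overlap). Pairs
#' too close together for any feasible window contribute nothing.
#'
#' @param record an [ecg_record()] with >= 2 annotated beats.
#' @param cfg an [aug_config()].
#' @param window_len window length in samples (defaults to
#'   `window_samples(cfg$window_ms, record$fs)`).
#' @return List of non-beat `ecg_segment` objects.
#' @export
negative_windows <- function(record, cfg = aug_config(), window_len = NULL) {
  if (length(record$r_peaks) < 2L) stop("record must have at least 2 annotated beats")
  if (is.null(window_len)) window_len <- window_samples(cfg$window_ms, record$fs)
  segs <- list()
  rp <- record$r_peaks
  for (k in seq_len(length(rp) - 1L)) {
    first_start <- rp[k] + cfg$neg_margin
    last_start <- rp[k + 1L] - cfg$neg_margin - window_len
    if (last_start < first_start) next
    starts <- seq.int(first_start, last_start, by = cfg$neg_stride)
    for (s in starts) {
      w <- extract_window(record, s + window_len %/% 2L, window_len)
      if (is.null(w)) next
      segs[[length(segs) + 1L]] <- new_segment(
        w, "non_beat", record$record_id, s + window_len %/% 2L, "negative")
    }
  }
  segs
}

#' Assemble a labelled training matrix from annotated records
#'
#' Applies [positive_variants()] to every annotated beat and
#' [negative_windows()] to every between-beat stretch of each record
#' (training partitions only — test data is never augmented), then resamples
#' each native-rate segment to the model input length.
#'
#' @param records list of [ecg_record()] objects.
#' @param cfg an [aug_config()].
#' @param model_len model input length in samples (300 by default).
#' @return A list with `x` (matrix, one segment per row, `model_len`
#'   columns), `label` (character, `"beat"`/`"non_beat"`), and `meta`
#'   (data.frame of record id, centre index and variant tag).
#' @export
build_training_set <- function(records, cfg = aug_config(), model_len = 300L) {
  if (inherits(records, "ecg_record")) records <- list(records)
  segs <- list()
  for (rec in records) {
    for (r in rec$r_peaks) segs <- c(segs, positive_variants(rec, r, cfg))
    if (length(rec$r_peaks) >= 2L) segs <- c(segs, negative_windows(rec, cfg))
  }
  if (!length(segs)) stop("no segments could be extracted from the records")
  x <- t(vapply(segs, function(s) {
    if (length(s$values) == model_len) s$values
    else resample_to_length(s$values, model_len)
  }, numeric(model_len)))
  list(
    x = x,
    label = vapply(segs, function(s) s$label, character(1)),
    meta = data.frame(
      record_id = vapply(segs, function(s) s$record_id, character(1)),
      center = vapply(segs, function(s) s$center, integer(1)),
      variant = vapply(segs, function(s) s$variant, character(1)),
      stringsAsFactors = FALSE)
  )
}
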