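#' Single-lead ECG record
#'
#' The basic container moved through the pipeline: a sampled amplitude series,
#' its sampling rate, the annotated R-peak positions (ground truth), and the
#' record/subject identity used to build subject-disjoint splits. All sample
#' indices in this package are 0-based, and windows are half-open
#' `[start, start + length)`.
#'
#' @param samples numeric amplitude series (arbitrary units).
#' @param fs sampling frequency in Hz, positive.
#' @param r_peaks integer vector of annotated R-peak sample indices (0-based),
#'   strictly increasing, each in `[0, length(samples))`.
#' @param record_id,subject_id identity strings; several records may share one
#'   `subject_id`, and train/test splits never separate a subject's records.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, r_peaks = integer(),
                       record_id = "rec", subject_id = record_id) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  r_peaks <- as.integer(round(r_peaks))
  if (length(r_peaks)) {
    if (any(r_peaks < 0L) || any(r_peaks >= length(samples))) {
      bad <- r_peaks[r_peaks < 0L | r_peaks >= length(samples)][1L]
      stop(sprintf("annotation index %d outside signal bounds [0, %d)",
                   bad, length(samples)))
    }
    if (any(diff(r_peaks) <= 0L)) {
      stop("`r_peaks` must be strictly increasing")
    }
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         r_peaks = r_peaks,
         record_id = as.character(record_id),
         subject_id = as.character(subject_id)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s (subject %s): %d samples @ %g Hz (%.1f s), %d annotated beats>\n",
              x$record_id, x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, length(x$r_peaks)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Detector output: candidate R-peak indices plus cascade delay
#'
#' @param peaks integer vector of detected R-peak sample indices (0-based),
#'   strictly increasing.
#' @param delay group delay, in samples, of the filter cascade used by the
#'   detector. Peaks returned by [pt_detect()] are already delay-corrected
#'   into original-signal coordinates, so its `delay` is 0.
#' @return An object of class `detection_result`.
#' @export
detection_result <- function(peaks, delay = 0L) {
  peaks <- as.integer(round(peaks))
  if (length(peaks) && any(diff(peaks) <= 0L)) {
    stop("`peaks` must be strictly increasing")
  }
  structure(list(peaks = peaks, delay = as.integer(delay)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result: %d peaks, delay %d samples>\n",
              length(x$peaks), x$delay))
  invisible(x)
}
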