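#' Validate detected R-peaks with a trained model
#'
#' Feeds the fixed-duration window centred on each detected peak through the
#' validator and keeps only the detections the model agrees are beats. A
#' detection whose window does not fit inside the record cannot be assessed
#' and is rejected. Windows extracted at the native sampling rate are
#' resampled to the model input length first.
#'
#' @param record an [ecg_record()].
#' @param detections a [detection_result()] (or integer vector of 0-based
#'   peak indices).
#' @param model a trained [cnn_build()] model.
#' @param window_ms validation window duration, milliseconds.
#' @param threshold decision threshold on the beat probability.
#' @return Integer vector of accepted peak indices (a subset of the input).
#' @export
validate_detections <- function(record, detections, model, window_ms = 833,
                                threshold = 0.5) {
  peaks <- if (inherits(detections, "detection_result")) detections$peaks
           else as.integer(detections)
  if (!length(peaks)) return(integer(0))
  L <- window_samples(window_ms, record$fs)
  windows <- lapply(peaks, function(p) extract_window(record, p, L))
  fits <- !vapply(windows, is.null, logical(1))
  if (!any(fits)) return(integer(0))
  x <- t(vapply(windows[fits], function(w) {
    if (length(w) == model$spec$input_len) w
    else resample_to_length(w, model$spec$input_len)
  }, numeric(model$spec$input_len)))
  pr <- cnn_predict(model, x)
  peaks[fits][pr >= threshold]
}

#' Match detections against ground truth with a tolerance
#'
#' Greedy one-to-one matching in order of increasing distance: every
#' (detection, truth) pair within `tol` samples is considered, closest pairs
#' first (ties broken by earlier detection index, then earlier truth index);
#' each detection and each truth peak may be used once. Matched detections
#' are true positives, unmatched detections false positives, unmatched truth
#' peaks false negatives, so `TP + FP = |detected|` and `TP + FN = |truth|`.
#'
#' @param detected,truth sorted integer vectors of 0-based peak indices.
#' @param tol matching tolerance in samples (the largest augmentation shift,
#'   15 samples at 360 Hz, by default).
#' @return Named integer vector `c(TP, FP, FN)`.
#' @export
match_detections <- function(detected, truth, tol = 15) {
  detected <- as.numeric(detected); truth <- as.numeric(truth)
  if (is.unsorted(detected, strictly = FALSE) || is.unsorted(truth, strictly = FALSE)) {
    stop("`detected` and `truth` must be sorted")
  }
  if (!length(detected) || !length(truth)) {
    return(c(TP = 0L, FP = length(detected), FN = length(truth)))
  }
  pairs_d <- integer(0); pairs_t <- integer(0); pairs_dist <- numeric(0)
  for (di in seq_along(detected)) {
    lo <- findInterval(detected[di] - tol, truth) # truths >= d - tol start after lo
    ti <- seq.int(lo, min(lo + 2L + 2L * tol, length(truth)))
    ti <- ti[ti >= 1L & ti <= length(truth)]
    ti <- ti[abs(truth[ti] - detected[di]) <= tol]
    pairs_d <- c(pairs_d, rep(di, length(ti)))
    pairs_t <- c(pairs_t, ti)
    pairs_dist <- c(pairs_dist, abs(truth[ti] - detected[di]))
  }
  ord <- order(pairs_dist, pairs_d, pairs_t)
  used_d <- logical(length(detected)); used_t <- logical(length(truth))
  tp <- 0L
  for (k in ord) {
    if (!used_d[pairs_d[k]] && !used_t[pairs_t[k]]) {
      used_d[pairs_d[k]] <- TRUE
      used_t[pairs_t[k]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(TP = tp, FP = length(detected) - tp, FN = length(truth) - tp)
}

#' Segmentation metrics: sensitivity, positive predictivity, F-score
#'
#' `Se = 100 * TP / (TP + FN)`, `+P = 100 * TP / (TP + FP)` (both
#' percentages) and `F = 2 * (+P * Se) / (+P + Se) / 100` (unitless in
#' `[0, 1]`). A zero denominator yields `NA` rather than an error.
#'
#' @param TP,FP,FN non-negative counts.
#' @return An object of class `eval_metrics` with fields `TP`, `FP`, `FN`,
#'   `Se`, `PP`, `F`.
#' @export
compute_metrics <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative")
  se <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  pp <- if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  structure(list(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
                 Se = se, PP = pp, F = f_score(se, pp)),
            class = "eval_metrics")
}

#' F-score from sensitivity / positive-predictivity percentages
#'
#' @param se,pp percentages in `[0, 100]`.
#' @return `2 * se * pp / (se + pp) / 100`, or `NA` when undefined.
#' @examples
#' round(f_score(95.79, 97.84), 2)  # 0.97
#' @export
f_score <- function(se, pp) {
  if (is.na(se) || is.na(pp) || se + pp == 0) return(NA_real_)
  2 * se * pp / (se + pp) / 100
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | Se %.2f%%  +P %.2f%%  F %.2f\n",
              x$TP, x$FP, x$FN, x$Se, x$PP, x$F))
  invisible(x)
}
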