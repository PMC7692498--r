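#' Run a full detect-validate-evaluate experiment
#'
#' The end-to-end pipeline: check that train and test records share no
#' subject; build the augmented training set from the training records only;
#' train the validator; then, per test record, run the Pan-Tompkins detector,
#' optionally corrupt its detections (to emulate a faultier third-party
#' detector), score the raw detections against ground truth, validate them
#' with the model, and score again. Counts are pooled (micro-averaged) over
#' all test records. The subset relations `validated TP <= raw TP`,
#' `validated FP <= raw FP` and `validated Se <= raw Se` are asserted on
#' every run.
#'
#' @param train_records,test_records lists of [ecg_record()] objects with
#'   disjoint subject sets.
#' @param cfg an [aug_config()].
#' @param spec a [cnn_spec()].
#' @param train_cfg a [cnn_train_config()].
#' @param corrupt optional list with elements `fp_rate`, `fn_rate`, `jitter`
#'   passed to [corrupt_detections()] on each test record's detections.
#' @param tol matching tolerance in samples at 360 Hz; rescaled as
#'   `round(tol / 360 * fs)` for records at other rates.
#' @param threshold validator decision threshold.
#' @param seed integer seed for detection corruption.
#' @param verbose print training progress.
#' @return A list with `raw` and `validated` pooled [compute_metrics()]
#'   objects, a `per_record` data.frame, the trained `model`, its training
#'   `history`, and per-record `peaks` (detected/accepted/truth).
#' @export
run_experiment <- function(train_records, test_records, cfg = aug_config(),
                           spec = cnn_spec(), train_cfg = cnn_train_config(),
                           corrupt = NULL, tol = 15, threshold = 0.5,
                           seed = 0, verbose = FALSE) {
  tr_subj <- unique(vapply(train_records, function(r) r$subject_id, character(1)))
  te_subj <- unique(vapply(test_records, function(r) r$subject_id, character(1)))
  overlap <- intersect(tr_subj, te_subj)
  if (length(overlap)) {
    stop(sprintf("subject(s) %s appear in both train and test sets",
                 paste(overlap, collapse = ", ")))
  }
  train_set <- build_training_set(train_records, cfg, model_len = spec$input_len)
  model <- cnn_build(spec, seed = train_cfg$seed)
  model <- cnn_train(model, train_set$x, train_set$label, train_cfg,
                     strata = train_set$meta$record_id, verbose = verbose)

  pooled_raw <- c(TP = 0L, FP = 0L, FN = 0L)
  pooled_val <- c(TP = 0L, FP = 0L, FN = 0L)
  per_record <- list()
  peaks <- list()
  for (i in seq_along(test_records)) {
    rec <- test_records[[i]]
    tol_rec <- round(tol / 360 * rec$fs)
    det <- pt_detect(rec)
    if (!is.null(corrupt)) {
      det <- corrupt_detections(det$peaks,
                                fp_rate = corrupt$fp_rate %||% 0,
                                fn_rate = corrupt$fn_rate %||% 0,
                                jitter = corrupt$jitter %||% 0,
                                record_len = length(rec$samples),
                                seed = derive_seed(seed, i), fs = rec$fs)
    }
    raw <- match_detections(det$peaks, rec$r_peaks, tol_rec)
    accepted <- validate_detections(rec, det, model,
                                    window_ms = cfg$window_ms,
                                    threshold = threshold)
    val <- match_detections(accepted, rec$r_peaks, tol_rec)
    stopifnot(val["TP"] <= raw["TP"], val["FP"] <= raw["FP"])
    pooled_raw <- pooled_raw + raw
    pooled_val <- pooled_val + val
    per_record[[i]] <- data.frame(
      record_id = rec$record_id, n_truth = length(rec$r_peaks),
      n_detected = length(det$peaks), n_accepted = length(accepted),
      raw_TP = raw["TP"], raw_FP = raw["FP"], raw_FN = raw["FN"],
      val_TP = val["TP"], val_FP = val["FP"], val_FN = val["FN"],
      row.names = NULL)
    peaks[[rec$record_id]] <- list(truth = rec$r_peaks, detected = det$peaks,
                                   accepted = accepted,
                                   rejected = setdiff(det$peaks, accepted))
  }
  raw_m <- compute_metrics(pooled_raw["TP"], pooled_raw["FP"], pooled_raw["FN"])
  val_m <- compute_metrics(pooled_val["TP"], pooled_val["FP"], pooled_val["FN"])
  if (!is.na(raw_m$Se) && !is.na(val_m$Se)) stopifnot(val_m$Se <= raw_m$Se)
  list(raw = raw_m, validated = val_m,
       per_record = do.call(rbind, per_record),
       model = model, history = model$history, peaks = peaks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
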