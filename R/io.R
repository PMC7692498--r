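#' Read an ECG record with beat annotations
#'
#' Two on-disk dialects are supported. `format = "csv"` expects a pair of
#' plain-text files: `<id>.csv` holding one amplitude per line and `<id>.ann`
#' holding one 0-based R-peak sample index per line (the annotation file may
#' be empty but must exist — without ground truth the pipeline cannot label
#' samples). `format = "wfdb"` reads a WFDB header/signal/annotation triple
#' (`.hea`/`.dat`/`.atr`), mapping beat annotations to R-peak indices; see
#' [read_wfdb()].
#'
#' @param path for `"csv"`, the path of the `.csv` file (or its basename
#'   without extension); for `"wfdb"`, the path of the `.hea` file or record
#'   basename.
#' @param format `"csv"` or `"wfdb"`.
#' @param fs sampling rate in Hz for CSV records (the dialect does not encode
#'   it); ignored for WFDB, whose header states it.
#' @param subject_id optional subject identity; defaults to the record id.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = 360,
                        subject_id = NULL) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_wfdb(path, subject_id = subject_id))
  base <- sub("\\.csv$", "", path)
  csv <- paste0(base, ".csv")
  ann <- paste0(base, ".ann")
  if (!file.exists(csv)) stop(sprintf("signal file not found: %s", csv))
  if (!file.exists(ann)) {
    stop(sprintf("annotation file not found: %s (R-peak ground truth is required)", ann))
  }
  samples <- scan(csv, what = numeric(), quiet = TRUE)
  r_peaks <- scan(ann, what = integer(), quiet = TRUE)
  id <- basename(base)
  ecg_record(samples, fs = fs, r_peaks = r_peaks, record_id = id,
             subject_id = if (is.null(subject_id)) id else subject_id)
}

#' Write an ECG record in the CSV/ANN dialect
#'
#' Writes `<dir>/<record_id>.csv` (one amplitude per line) and
#' `<dir>/<record_id>.ann` (one 0-based R-peak index per line).
#'
#' @param record an [ecg_record()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the basename path written (without extension).
#' @export
write_record <- function(record, dir = ".") {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  writeLines(formatC(record$samples, format = "g", digits = 17),
             paste0(base, ".csv"))
  writeLines(as.character(record$r_peaks), paste0(base, ".ann"))
  invisible(base)
}

#' Resample an amplitude series to a fixed length
#'
#' Piecewise-cubic (spline) interpolation on the uniform grid, used to map
#' native-rate validation windows (e.g. 833 samples at 1000 Hz) onto the
#' model's fixed input length (300 samples). The output spans the same time
#' extent and preserves the endpoint values; constant and linear inputs are
#' reproduced exactly.
#'
#' @param values numeric series, length >= 2.
#' @param n_out requested output length, >= 2.
#' @return Numeric vector of length `n_out`.
#' @export
resample_to_length <- function(values, n_out) {
  if (length(values) < 2L) stop("input must have at least 2 samples")
  if (!is_count(n_out) || n_out < 2L) stop("`n_out` must be a count >= 2")
  n <- length(values)
  if (n_out == n) return(as.numeric(values))
  xin <- seq(0, 1, length.out = n)
  xout <- seq(0, 1, length.out = n_out)
  stats::spline(xin, values, xout = xout, method = "fmm")$y
}

#' Build a subject-disjoint train/test split
#'
#' `scheme = "odd_even"` assigns records whose trailing record-id digits are
#' odd to training and even to testing (the conventional split for the
#' MIT-BIH healthy-record list). `scheme = "random_half"` splits *subjects*
#' (not records) into random halves under `seed`. Either way the result is
#' checked to be subject-disjoint: a subject whose records would straddle the
#' split raises an error rather than being silently reassigned.
#'
#' @param records list of [ecg_record()] objects, length >= 2.
#' @param scheme `"odd_even"` or `"random_half"`.
#' @param seed integer seed (used by `"random_half"` only).
#' @return A list with `train` and `test` character vectors of record ids
#'   (disjoint, covering all records).
#' @export
make_subject_split <- function(records, scheme = c("odd_even", "random_half"),
                               seed = 0) {
  scheme <- match.arg(scheme)
  if (length(records) < 2L) stop("need at least 2 records to split")
  ids <- vapply(records, function(r) r$record_id, character(1))
  subj <- vapply(records, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids)) stop("record ids must be unique")
  if (scheme == "odd_even") {
    digits <- regmatches(ids, regexpr("[0-9]+$", ids))
    if (length(digits) != length(ids)) {
      stop("odd_even scheme requires every record id to end in digits")
    }
    odd <- as.numeric(digits) %% 2 == 1
    train <- ids[odd]; test <- ids[!odd]
  } else {
    subjects <- unique(subj)
    if (length(subjects) < 2L) {
      stop("cannot build a subject-disjoint split: fewer than 2 subjects")
    }
    train_subj <- with_seed(seed, sample(subjects, floor(length(subjects) / 2)))
    train <- ids[subj %in% train_subj]
    test <- ids[!subj %in% train_subj]
  }
  if (length(train) == 0L || length(test) == 0L) {
    stop("split left one side empty")
  }
  straddle <- intersect(subj[ids %in% train], subj[ids %in% test])
  if (length(straddle)) {
    stop(sprintf("subject(s) %s have records on both sides of the split",
                 paste(straddle, collapse = ", ")))
  }
  list(train = train, test = test)
}
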