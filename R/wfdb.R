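# Minimal WFDB reader: header (.hea), signal formats 212 and 16, and MIT
# annotation files (.atr). Reading only — enough to load MIT-BIH-style
# records with beat annotations; writing is out of scope.

# MIT annotation codes that denote beats (NORMAL, bundle-branch blocks,
# ectopics, escapes, paced, fusion, unknown). Non-beat codes (rhythm changes,
# artifacts, comments) are ignored when mapping annotations to R-peaks.
WFDB_BEAT_CODES <- c(1:13, 25L, 34L, 35L, 38L)

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty WFDB header: %s", hea_path))
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 2L) stop("malformed WFDB header record line")
  name <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.numeric(top[4]) else NA_real_
  if (nsig < 1L) stop("WFDB header declares no signals")
  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(f) < 2L) stop(sprintf("malformed signal line %d in %s", i, hea_path))
    fmt <- as.integer(sub("[x:+].*$", "", f[2]))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5) {
      as.numeric(f[5])  # adc_zero
    } else 0
    if (is.na(gain) || gain == 0) gain <- 200
    sig[[i]] <- list(file = f[1], format = fmt, gain = gain, baseline = baseline)
  }
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_212 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(raw)
  n3 <- (length(b) %/% 3) * 3
  b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
  s1 <- b1 + bitwAnd(b2, 0x0FL) * 256L
  s2 <- b3 + bitwAnd(b2, 0xF0L) %/% 16L * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)  # 12-bit two's complement
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  total <- if (is.finite(nsamp)) nsig * nsamp else length(flat)
  flat[seq_len(min(total, length(flat)))]
}

read_dat_16 <- function(path, nsig, nsamp) {
  n <- file.size(path) %/% 2
  v <- readBin(path, "integer", n = n, size = 2, signed = TRUE, endian = "little")
  total <- if (is.finite(nsamp)) nsig * nsamp else length(v)
  v[seq_len(min(total, length(v)))]
}

#' Read a WFDB record (.hea/.dat) with beat annotations (.atr)
#'
#' Supports single- and multi-signal records in formats 212 and 16; the first
#' signal is taken as the analysis lead (the method is single-lead). ADC
#' values are converted to physical units via the header gain/baseline. Beat
#' annotations (MIT codes for normal, ectopic, escape, paced, fusion and
#' unknown beats) become 0-based `r_peaks`; non-beat annotations are ignored.
#'
#' @param path path to the `.hea` file or the record basename.
#' @param subject_id optional subject identity; defaults to the record name.
#' @param require_annotations error if no `.atr` file is present (default):
#'   without ground truth the downstream labelling steps cannot run.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(path, subject_id = NULL, require_annotations = TRUE) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop(sprintf("WFDB header not found: %s", hea))
  h <- parse_hea(hea)
  dir <- dirname(hea)
  s1 <- h$signals[[1]]
  dat <- file.path(dir, s1$file)
  if (!file.exists(dat)) stop(sprintf("WFDB signal file not found: %s", dat))
  flat <- switch(as.character(s1$format),
    "212" = read_dat_212(dat, h$nsig, h$nsamp),
    "16"  = read_dat_16(dat, h$nsig, h$nsamp),
    stop(sprintf("unsupported WFDB signal format %d (only 212 and 16)", s1$format)))
  adc <- flat[seq(1, length(flat), by = h$nsig)]
  samples <- (adc - s1$baseline) / s1$gain
  atr <- paste0(base, ".atr")
  r_peaks <- integer(0)
  if (file.exists(atr)) {
    ann <- read_atr(atr)
    r_peaks <- ann$sample[ann$code %in% WFDB_BEAT_CODES]
  } else if (require_annotations) {
    stop(sprintf("annotation file not found: %s (R-peak ground truth is required)", atr))
  }
  if (length(r_peaks) && any(r_peaks >= length(samples))) {
    bad <- r_peaks[r_peaks >= length(samples)][1L]
    stop(sprintf("annotation index %d outside signal bounds [0, %d)",
                 bad, length(samples)))
  }
  ecg_record(samples, fs = h$fs, r_peaks = r_peaks, record_id = h$name,
             subject_id = if (is.null(subject_id)) h$name else subject_id)
}

#' Read a MIT-format annotation file
#'
#' Decodes the packed 16-bit annotation stream: each word carries a 6-bit
#' annotation code and a 10-bit interval from the previous annotation; the
#' pseudo-codes SKIP (long intervals), NUM/SUB/CHN (field updates) and AUX
#' (string payloads) are handled, and a zero word terminates the stream.
#'
#' @param path path to the annotation file.
#' @return A `data.frame` with columns `sample` (0-based) and `code`.
#' @export
read_atr <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(raw)
  i <- 1L
  time <- 0
  samples <- numeric(0)
  codes <- integer(0)
  while (i + 1L <= length(b)) {
    word <- b[i] + b[i + 1L] * 256L
    i <- i + 2L
    code <- word %/% 1024L
    data <- word %% 1024L
    if (code == 0L && data == 0L) break
    if (code == 59L) {        # SKIP: next 4 bytes hold the interval, high word first
      if (i + 3L > length(b)) break
      hi <- b[i] + b[i + 1L] * 256L
      lo <- b[i + 2L] + b[i + 3L] * 256L
      i <- i + 4L
      time <- time + hi * 65536 + lo
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN field updates: no time advance
    } else if (code == 63L) { # AUX: data = byte count, padded to even
      i <- i + data + (data %% 2L)
    } else {
      time <- time + data
      samples <- c(samples, time)
      codes <- c(codes, code)
    }
  }
  data.frame(sample = as.integer(samples), code = codes)
}
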