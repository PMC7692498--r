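# Fixture builders shared across test files. WFDB byte streams are packed
# here directly from the format definition (12-bit pairs for format 212,
# little-endian int16 for format 16, 6-bit code / 10-bit interval words for
# annotations) so the reader is checked against an independent construction.

pack_212 <- function(adc) {
  if (length(adc) %% 2 == 1) adc <- c(adc, 0L)       # pad to sample pairs
  u <- ifelse(adc < 0L, adc + 4096L, adc)            # 12-bit two's complement
  s1 <- u[seq(1, length(u), 2)]
  s2 <- u[seq(2, length(u), 2)]
  b <- as.vector(rbind(s1 %% 256L,
                       (s1 %/% 256L) + 16L * (s2 %/% 256L),
                       s2 %% 256L))
  as.raw(b)
}

pack_atr <- function(samples, codes) {
  stopifnot(length(samples) == length(codes))
  deltas <- diff(c(0L, samples))
  words <- integer(0)
  bytes <- raw(0)
  for (k in seq_along(samples)) {
    d <- deltas[k]
    if (d > 1023L) {                                  # SKIP pseudo-annotation
      bytes <- c(bytes, as.raw(c(0L, 59L * 4L)),      # code 59, data 0
                 as.raw(c((d %/% 65536L) %% 256L, d %/% 65536L %/% 256L,
                          d %% 256L, (d %/% 256L) %% 256L)))
      d <- 0L
    }
    w <- codes[k] * 1024L + d
    bytes <- c(bytes, as.raw(c(w %% 256L, w %/% 256L)))
  }
  c(bytes, as.raw(c(0L, 0L)))                         # terminating zero word
}

write_wfdb_fixture <- function(dir, name = "t100", adc, ann_samples, ann_codes,
                               fs = 360, fmt = 212L, gain = 200, adc_zero = 0L) {
  base <- file.path(dir, name)
  writeLines(c(sprintf("%s 1 %g %d", name, fs, length(adc)),
               sprintf("%s.dat %d %g 12 %d 0 0 0 lead_I", name, fmt, gain, adc_zero)),
             paste0(base, ".hea"))
  if (fmt == 212L) {
    writeBin(pack_212(as.integer(adc)), paste0(base, ".dat"))
  } else {
    writeBin(as.integer(adc), paste0(base, ".dat"), size = 2, endian = "little")
  }
  writeBin(pack_atr(as.integer(ann_samples), as.integer(ann_codes)),
           paste0(base, ".atr"))
  base
}

# A constant-output classifier head: softmax over fixed biases, so the
# validator accepts everything (p_beat ~ 1) or rejects everything, without
# training. Used for the subset bounds of validate_detections().
constant_model <- function(accept = TRUE) {
  m <- cnn_build(cnn_spec(), seed = 0)
  m$params[["out.W"]][] <- 0
  m$params[["out.b"]] <- if (accept) c(10, -10) else c(-10, 10)
  m$trained <- TRUE
  m
}

# Small architecture used by unit tests so training stays fast; the default
# architecture is exercised by the end-to-end acceptance experiment.
small_spec <- function() cnn_spec(channels = c(8L, 8L, 16L, 16L), dense = c(64L, 32L))
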