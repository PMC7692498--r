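test_that("CSV/ANN round trip preserves samples and annotations", {
  dir <- withr::local_tempdir()
  writeLines(as.character(numeric(1000)), file.path(dir, "z.csv"))
  writeLines("500", file.path(dir, "z.ann"))
  rec <- read_record(file.path(dir, "z"), "csv", fs = 360)
  expect_length(rec$samples, 1000)
  expect_identical(rec$r_peaks, 500L)

  synth <- generate_record(10, fs = 360, mean_rr = 0.9, rr_jitter = 0.05,
                           seed = 5, noise = list(noise_spec("highfreq", 0.05)),
                           record_id = "s1")
  write_record(synth, dir)
  back <- read_record(file.path(dir, "s1.csv"), "csv", fs = 360)
  expect_equal(back$samples, synth$samples, tolerance = 1e-12)
  expect_identical(back$r_peaks, synth$r_peaks)
})

test_that("missing or out-of-range annotations are explicit errors", {
  dir <- withr::local_tempdir()
  writeLines(as.character(numeric(1000)), file.path(dir, "x.csv"))
  expect_error(read_record(file.path(dir, "x"), "csv"), "annotation")
  writeLines("1200", file.path(dir, "x.ann"))
  expect_error(read_record(file.path(dir, "x"), "csv"), "1200")
})

test_that("resample_to_length is exact on constants and lines", {
  expect_equal(resample_to_length(rep(2.5, 833), 300), rep(2.5, 300))
  x <- sin(seq(0, 5, length.out = 120))
  expect_identical(resample_to_length(x, 120), x)
  ramp <- seq(0, 832, length.out = 833)
  out <- resample_to_length(ramp, 300)
  expect_lt(max(abs(out - seq(0, 832, length.out = 300))), 1e-9)
  expect_identical(out[c(1, 300)], c(0, 832))   # endpoints preserved
  expect_error(resample_to_length(x, 1), "n_out")
  expect_error(resample_to_length(1, 10), "at least 2")
})

test_that("WFDB records round-trip through independently packed bytes", {
  dir <- withr::local_tempdir()
  set.seed(42)
  adc <- as.integer(round(1000 * sin(2 * pi * (0:1999) / 200))) # in 12-bit range
  ann_s <- c(150L, 450L, 1700L)                                 # forces a SKIP word
  ann_c <- c(1L, 28L, 5L)                                       # NORMAL, rhythm, PVC
  base <- write_wfdb_fixture(dir, "t212", adc, ann_s, ann_c, fmt = 212L)
  rec <- read_wfdb(base)
  expect_equal(rec$fs, 360)
  expect_equal(rec$samples, adc / 200, tolerance = 1e-12)
  expect_identical(rec$r_peaks, c(150L, 1700L))   # rhythm code 28 is not a beat
  # negative amplitudes survive two's-complement packing
  adc2 <- as.integer(c(-2048, -1, 0, 1, 2047, -100, 100, 0))
  base2 <- write_wfdb_fixture(dir, "tneg", adc2, 3L, 1L, fmt = 212L)
  expect_equal(read_wfdb(base2)$samples, adc2 / 200, tolerance = 1e-12)
  # format 16
  base3 <- write_wfdb_fixture(dir, "t16", adc2, 3L, 1L, fmt = 16L)
  expect_equal(read_wfdb(base3)$samples, adc2 / 200, tolerance = 1e-12)
  # read_record dispatches on format
  rec2 <- read_record(paste0(base, ".hea"), "wfdb")
  expect_identical(rec2$r_peaks, rec$r_peaks)
  # missing annotation file is an error by default
  file.remove(paste0(base, ".atr"))
  expect_error(read_wfdb(base), "annotation")
})

test_that("subject splits are disjoint, deterministic, and refuse straddlers", {
  mk <- function(id, subj = id) {
    ecg_record(numeric(100), 360, record_id = id, subject_id = subj)
  }
  ids <- as.character(100:124)
  recs <- lapply(ids, mk)
  sp <- make_subject_split(recs, "odd_even")
  expect_setequal(sp$train, ids[as.integer(ids) %% 2 == 1])
  expect_setequal(sp$test, ids[as.integer(ids) %% 2 == 0])
  expect_length(intersect(sp$train, sp$test), 0)

  # two records of one subject cannot be split
  expect_error(make_subject_split(list(mk("a1", "s"), mk("a2", "s")), "random_half"),
               "subject")
  # a subject straddling the odd/even boundary is refused, never reassigned
  expect_error(make_subject_split(list(mk("101", "s"), mk("102", "s")), "odd_even"),
               "both sides")

  recs10 <- lapply(sprintf("r%02d", 1:10), mk)
  s1 <- make_subject_split(recs10, "random_half", seed = 1)
  expect_length(s1$train, 5)
  expect_length(s1$test, 5)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_identical(make_subject_split(recs10, "random_half", seed = 1), s1)
})
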