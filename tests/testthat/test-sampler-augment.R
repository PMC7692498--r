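test_that("extract_window obeys the centring and bounds contract", {
  rec <- ecg_record(0:999, 360, r_peaks = c(300L, 500L))
  expect_equal(extract_window(rec, 500, 300), 350:649)
  expect_null(extract_window(rec, 100, 300))      # 100 - 150 < 0
  expect_null(extract_window(rec, 900, 300))      # 900 + 150 > 1000
  expect_equal(extract_window(rec, 123, 1), 123)  # degenerate window
})

test_that("wave attenuation scales exactly the stated region", {
  seg <- rep(1, 300)
  out <- attenuate_wave(seg, "p_wave", 0.30, 375, 360)
  affected <- which(out != 1)
  expect_equal(affected, 16:150)                  # 0-based 15..149, 135 samples
  expect_length(affected, round(0.375 * 360))
  expect_true(all(out[affected] == 0.70))
  outt <- attenuate_wave(seg, "t_wave", 0.30, 375, 360)
  expect_equal(which(outt != 1), 152:286)         # strictly after the centre
  expect_identical(attenuate_wave(seg, "p_wave", 0), seg)
  expect_error(attenuate_wave(seg, "p_wave", 1), "frac")
})

test_that("global attenuation is multiplicative and composes", {
  expect_equal(global_attenuate(c(1, -2), 0.40), c(0.6, -1.2))
  set.seed(3)
  x <- rnorm(300)
  expect_identical(global_attenuate(x, 0), x)
  expect_equal(global_attenuate(global_attenuate(x, 0.2), 0.25),
               global_attenuate(x, 0.4))          # 0.8 * 0.75 = 0.6
  expect_error(global_attenuate(x, -0.1), "frac")
})

test_that("each eligible beat yields exactly 11 positive variants", {
  rec <- generate_record(10, fs = 360, mean_rr = 1.25, rr_jitter = 0.05, seed = 2)
  cfg <- aug_config()
  expect_identical(n_positive_variants(cfg), 11L)
  for (r in rec$r_peaks) {
    segs <- positive_variants(rec, r, cfg)
    expect_length(segs, 11)
    expect_true(all(vapply(segs, function(s) s$label, character(1)) == "beat"))
    expect_true(all(lengths(lapply(segs, `[[`, "values")) == 300))
    tags <- vapply(segs, function(s) s$variant, character(1))
    expect_setequal(tags, c("centered", "shift-5", "shift+5", "shift-10",
                            "shift+10", "shift-15", "shift+15", "p_atten",
                            "t_atten", "global20", "global40"))
  }
  # shifted windows actually hold the R peak off-centre by the shift amount
  segs <- positive_variants(rec, rec$r_peaks[3], cfg)
  ctr <- segs[[1]]$values
  sh <- segs[[which(vapply(segs, function(s) s$variant, character(1)) == "shift+15")]]
  expect_equal(which.max(sh$values), which.max(ctr) + 15)
})

test_that("degenerate configs and edge beats are handled", {
  rec <- generate_record(10, fs = 360, mean_rr = 1.25, rr_jitter = 0, seed = 2)
  bare <- aug_config(shifts = integer(0), wave_atten_frac = 0,
                     global_atten_fracs = numeric(0))
  expect_identical(n_positive_variants(bare), 1L)
  segs <- positive_variants(rec, rec$r_peaks[2], bare)
  expect_length(segs, 1)
  expect_identical(segs[[1]]$variant, "centered")
  # a beat whose window cannot fit is skipped entirely
  edge <- ecg_record(c(rep(0, 9), 1, rep(0, 400)), 360, r_peaks = 9L)
  expect_length(positive_variants(edge, 9L, aug_config()), 0)
})

test_that("negative sliding windows enumerate the feasible starts", {
  mk <- function(n, rp) ecg_record(numeric(n), 360, r_peaks = rp)
  cfg <- aug_config()
  # brute-force oracle over all feasible starts
  oracle <- function(r1, r2, L, margin = 50, stride = 5) {
    starts <- seq.int(r1 + margin, r2, by = stride)
    starts[starts + L <= r2 - margin]
  }
  cases <- list(c(0L, 1000L), c(0L, 405L), c(0L, 404L), c(100L, 1500L))
  for (cs in cases) {
    rec <- mk(cs[2] + 400L, cs)
    segs <- negative_windows(rec, cfg, window_len = 300L)
    exp_starts <- oracle(cs[1], cs[2], 300L)
    expect_length(segs, length(exp_starts))
    if (length(segs)) {
      got_starts <- vapply(segs, function(s) s$center, integer(1)) - 150L
      expect_equal(got_starts, exp_starts)
      expect_true(all(vapply(segs, function(s) s$label, character(1)) == "non_beat"))
    }
  }
  expect_length(negative_windows(mk(700L, c(0L, 300L)), cfg), 0)  # too close
  expect_length(negative_windows(mk(1405L, c(0L, 405L)), cfg), 2) # starts 50, 55
  expect_error(negative_windows(mk(500L, 100L), cfg), "2 annotated")
})

test_that("negative windows never centre near an annotated beat", {
  rec <- generate_record(8, fs = 360, mean_rr = 1.25, rr_jitter = 0.05, seed = 6)
  segs <- negative_windows(rec, aug_config())
  for (s in segs) {
    expect_gt(min(abs(s$center - rec$r_peaks)), 15)
  }
})

test_that("augmentation operators are amplitude-linear", {
  rec <- generate_record(6, fs = 360, mean_rr = 1.25, seed = 8)
  scaled <- rec
  scaled$samples <- rec$samples * 4.5
  a <- positive_variants(rec, rec$r_peaks[3], aug_config())
  b <- positive_variants(scaled, scaled$r_peaks[3], aug_config())
  for (k in seq_along(a)) {
    expect_equal(b[[k]]$values, 4.5 * a[[k]]$values)
  }
})

test_that("build_training_set counts and native-rate resampling are right", {
  rec360 <- generate_record(10, fs = 360, mean_rr = 1.25, rr_jitter = 0.05, seed = 2)
  ts <- build_training_set(rec360, aug_config(), model_len = 300L)
  n_neg <- length(negative_windows(rec360, aug_config()))
  eligible <- sum(vapply(rec360$r_peaks, function(r) {
    length(positive_variants(rec360, r, aug_config())) > 0
  }, logical(1)))
  expect_identical(nrow(ts$x), 11L * eligible + n_neg)
  expect_identical(sum(ts$label == "beat"), 11L * eligible)
  # 1000 Hz record: 833-sample native windows are resampled to 300
  rec1k <- generate_record(6, fs = 1000, mean_rr = 1.25, rr_jitter = 0.05, seed = 3)
  ts1k <- build_training_set(rec1k, aug_config(), model_len = 300L)
  expect_identical(ncol(ts1k$x), 300L)
  native <- extract_window(rec1k, rec1k$r_peaks[2], window_samples(833, 1000))
  expect_length(native, 833)
  row <- which(ts1k$meta$center == rec1k$r_peaks[2] &
                 ts1k$meta$variant == "centered")
  expect_equal(ts1k$x[row, ], resample_to_length(native, 300))
})
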