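test_that("band-pass keeps QRS frequencies and rejects baseline wander", {
  fs <- 360
  expect_equal(pt_bandpass(numeric(1000), fs), numeric(1000))
  t <- (0:(6 * fs)) / fs
  interior <- seq(fs, 5 * fs)                      # avoid filter edge effects
  inband <- sin(2 * pi * 10 * t)
  expect_gte(max(abs(pt_bandpass(inband, fs)[interior])), 0.7)
  wander <- sin(2 * pi * 0.3 * t)
  expect_lte(max(abs(pt_bandpass(wander, fs)[interior])), 0.1)
  expect_error(pt_bandpass(numeric(1000), 90), "fs")
})

test_that("five-point derivative matches a direct convolution oracle", {
  fs <- 360
  expect_equal(pt_derivative(rep(3, 50), fs), numeric(50))
  # oracle: evaluate y[n] = (fs/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4]) directly
  oracle <- function(x) {
    y <- numeric(length(x))
    for (n in 5:length(x)) {
      y[n] <- (fs / 8) * (2 * x[n] + x[n - 1] - x[n - 3] - 2 * x[n - 4])
    }
    y
  }
  set.seed(1)
  x <- rnorm(200)
  expect_equal(pt_derivative(x, fs), oracle(x))
  # linear ramp of slope m units/sample: interior output is constant
  m <- 0.37
  ramp <- m * (0:99)
  got <- pt_derivative(ramp, fs)
  expect_equal(unique(round(got[5:100], 9)), round(oracle(ramp)[50], 9))
  expect_equal(got[50], m * fs * 10 / 8)   # coefficient sum over lags is 10
  # impulse reproduces the scaled 5-tap kernel
  imp <- c(numeric(9), 1, numeric(10))
  expect_equal(pt_derivative(imp, fs)[10:14], (fs / 8) * c(2, 1, 0, -1, -2))
  expect_error(pt_derivative(1:4, fs), "5 samples")
})

test_that("squaring and moving-window integration follow their definitions", {
  expect_equal(pt_square(c(-1, 2, 0)), c(1, 4, 0))
  set.seed(2)
  x <- rnorm(40)
  expect_equal(pt_square(x), pt_square(-x))
  fs <- 360
  N <- round(0.150 * fs)
  expect_identical(N, 54)                          # 150 ms at 360 Hz
  const <- rep(2, 400)
  expect_equal(pt_mwi(const, fs)[N:400], rep(2, 400 - N + 1))
  imp <- c(numeric(99), 1, numeric(200))
  got <- pt_mwi(imp, fs)
  expect_equal(got[100:(100 + N - 1)], rep(1 / N, N))
  expect_equal(got[100 + N], 0)
  expect_error(pt_mwi(numeric(10), fs), "longer than the signal")
})

test_that("clean synthetic beats are detected exactly, with accurate localisation", {
  rec <- generate_record(20, fs = 360, mean_rr = 0.8, rr_jitter = 0, seed = 7)
  det <- pt_detect(rec)
  expect_length(det$peaks, 20)
  expect_true(all(abs(det$peaks - rec$r_peaks) <= 10))
  expect_error(pt_detect(ecg_record(numeric(100), 360)), "2 s")
})

test_that("flat input, refractory veto and scale equivariance hold", {
  fs <- 360
  expect_length(pt_detect(ecg_record(numeric(3000), fs))$peaks, 0)
  # two impulses 50 ms apart: at most one detection in that neighbourhood
  x <- numeric(3000)
  x[c(1500, 1500 + round(0.05 * fs))] <- 5
  det <- pt_detect(ecg_record(x, fs))
  expect_lte(sum(det$peaks >= 1400 & det$peaks <= 1650), 1)
  # refractory invariant on adversarial input: dense impulse train
  y <- numeric(5000)
  y[seq(500, 4500, by = 30)] <- 3
  dy <- pt_detect(ecg_record(y, fs))$peaks
  if (length(dy) > 1) expect_gte(min(diff(dy)), round(0.2 * fs))
  # amplitude-scale equivariance on a noisy record
  rec <- generate_record(15, fs = fs, mean_rr = 0.9, rr_jitter = 0.05, seed = 3,
                         noise = list(noise_spec("baseline_wander", 0.1),
                                      noise_spec("highfreq", 0.05)))
  p1 <- pt_detect(rec)$peaks
  for (c in c(0.01, 12, 3000)) {
    scaled <- rec
    scaled$samples <- rec$samples * c
    expect_identical(pt_detect(scaled)$peaks, p1)
  }
  # refractory invariant also holds on every detection set above
  for (pk in list(det$peaks, dy, p1)) {
    if (length(pk) > 1) expect_gte(min(diff(pk)), round(0.2 * fs))
  }
})

test_that("searchback recovers beats missed by the primary threshold", {
  # one beat attenuated so its integrated energy falls between THR2 and
  # THR1: it is only recoverable through the 166%-RR searchback
  rec <- generate_record(12, fs = 360, mean_rr = 0.9, rr_jitter = 0, seed = 9)
  weak <- 6L
  r <- rec$r_peaks[weak]
  lo <- r - 60; hi <- r + 60
  rec$samples[(lo:hi) + 1L] <- rec$samples[(lo:hi) + 1L] * 0.45
  det <- pt_detect(rec)
  m <- match_detections(det$peaks, rec$r_peaks, tol = 15)
  expect_gte(m[["TP"]], 11)
})
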