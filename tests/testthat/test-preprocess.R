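# Preprocessing: filters, resampling, epoching, rejection, referencing.

sine_raw <- function(freq, fs = 1000, dur = 4, amp = 1, n_ch = 1) {
  t <- (seq_len(fs * dur) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  raw_recording(matrix(rep(x, each = n_ch), nrow = n_ch, byrow = FALSE),
                fs, sprintf("ch%d", seq_len(n_ch)))
}
rms <- function(x) sqrt(mean(x^2))

test_that("broadband filter keeps the passband and kills stopband/powerline", {
  core <- 1001:3000  # interior samples, away from edge transients
  out60 <- broadband_filter(sine_raw(60))$data[1, core]
  # oracle: the designed forward-backward magnitude response at 60 Hz
  sos <- plvnet:::butter_sos(4, c(0.5, 30), 1000, "pass")
  z <- exp(2i * pi * 60 / 1000)
  h1 <- prod(apply(sos, 1, function(r) {
    Mod((r[1] + r[2] / z + r[3] / z^2) / (1 + r[5] / z + r[6] / z^2))
  }))
  expect_equal(rms(out60), h1^2, tolerance = 0.02)  # matches design (~2%)
  expect_lt(rms(out60), 0.05)                       # 60 Hz: stopband
  out10 <- broadband_filter(sine_raw(10))$data[1, core]
  expect_equal(rms(out10), rms(sin(2 * pi * 10 * (0:1999) / 1000)),
               tolerance = 0.05)                    # 10 Hz: passband
  out50 <- broadband_filter(sine_raw(50))$data[1, core]
  expect_lt(rms(out50), 0.05)                       # notch
  zeros <- raw_recording(matrix(0, 2, 1000), 1000, c("a", "b"))
  expect_equal(broadband_filter(zeros)$data, zeros$data)
  expect_error(broadband_filter(sine_raw(10, fs = 40)), "Nyquist|band")
})

test_that("filtering is zero-phase: no lag on a passband sinusoid", {
  raw <- sine_raw(10)
  out <- broadband_filter(raw)$data[1, ]
  cc <- stats::ccf(out[1001:3000], raw$data[1, 1001:3000],
                   lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling scales the sample count and preserves slow content", {
  raw <- sine_raw(5, fs = 1000, dur = 10)
  out <- resample_recording(raw, 250)
  expect_equal(out$sfreq, 250)
  expect_equal(ncol(out$data), 2500)
  ref <- sin(2 * pi * 5 * (0:2499) / 250)
  expect_gt(stats::cor(out$data[1, 50:2450], ref[50:2450]), 0.999)
  expect_identical(resample_recording(raw, 1000), raw)    # identity
  expect_error(resample_recording(raw, 2000), "upsampling")
})

test_that("epoching is exact non-overlapping segmentation", {
  raw <- raw_recording(matrix(seq_len(2 * 30000), nrow = 2, byrow = TRUE),
                       250, c("a", "b"))
  ep <- epoch_recording(raw, 2)
  expect_equal(dim(ep$data), c(60, 2, 500))
  # indexing contract: sample i of epoch k is raw sample (k-1)*500 + i
  expect_equal(ep$data[3, 1, 7], unname(raw$data[1, 2 * 500 + 7]))
  short <- raw_recording(matrix(1, 1, 5 * 250), 250, "a")
  expect_equal(dim(epoch_recording(short, 2)$data)[1], 2)  # 1 s discarded
  tiny <- raw_recording(matrix(1, 1, 100), 250, "a")
  expect_error(epoch_recording(tiny, 2), "shorter")
})

test_that("amplitude rejection drops only epochs exceeding the limit", {
  dat <- array(0, dim = c(5, 2, 500))
  dat[2, 1, 100] <- 150        # above limit on one channel/sample
  dat[4, 2, 1] <- 100          # exactly at the limit: kept
  dat[5, 1, 250] <- -150       # negative excursion
  ep <- epoched_recording(dat, 250, c("a", "b"), 2)
  res <- reject_amplitude(ep, 100)
  expect_equal(res$rejected, c(2L, 5L))
  expect_equal(dim(res$epochs$data)[1], 3)
  # idempotent
  res2 <- reject_amplitude(res$epochs, 100)
  expect_length(res2$rejected, 0)
  expect_equal(res2$epochs$data, res$epochs$data)
  allbad <- epoched_recording(array(200, dim = c(2, 1, 500)), 250, "a", 2)
  expect_error(reject_amplitude(allbad), "all epochs")
})

test_that("common average reference zeroes the cross-channel mean", {
  set.seed(1)
  ep <- epoched_recording(array(rnorm(4 * 3 * 500), dim = c(4, 3, 500)),
                          250, c("a", "b", "c"), 2)
  out <- common_average_reference(ep)
  expect_lt(max(abs(apply(out$data, c(1, 3), mean))), 1e-12)
  expect_equal(common_average_reference(out)$data, out$data)  # idempotent
  # two channels become +/-(a - b)/2
  a <- sin(2 * pi * 7 * (0:499) / 250); b <- cos(2 * pi * 9 * (0:499) / 250)
  two <- epoched_recording(array(c(a, b), dim = c(1, 2, 500))[1, , ,
                                                              drop = FALSE],
                           250, c("x", "y"), 2)
  two$data[1, 1, ] <- a; two$data[1, 2, ] <- b
  ref <- common_average_reference(two)
  expect_equal(ref$data[1, 1, ], (a - b) / 2, tolerance = 1e-12)
  expect_equal(ref$data[1, 2, ], (b - a) / 2, tolerance = 1e-12)
  one <- epoched_recording(array(1, dim = c(1, 1, 500)), 250, "a", 2)
  expect_error(common_average_reference(one), "2 channels")
})

test_that("band filter separates the analysis bands", {
  t <- (0:1999) / 250
  x <- sin(2 * pi * 10 * t)
  ep <- epoched_recording(array(x, dim = c(1, 1, 2000)), 250, "a", 8)
  in_alpha <- band_filter(ep, band = "alpha")
  expect_equal(rms(in_alpha$data[1, 1, 300:1700]), rms(x[300:1700]),
               tolerance = 0.05)
  expect_identical(in_alpha$band, "alpha")
  in_delta <- band_filter(ep, band = "delta")
  expect_lt(rms(in_delta$data[1, 1, 300:1700]), 0.05 * rms(x))
  zeros <- epoched_recording(array(0, dim = c(1, 1, 500)), 250, "a", 2)
  expect_equal(band_filter(zeros, band = "theta")$data, zeros$data)
  expect_error(band_filter(ep, band = "gamma"), "unknown band")
  expect_error(band_filter(ep), "band")
})

test_that("clean synthetic data passes the pipeline without rejections", {
  cfg <- synth_config(n_participants = 1, duration = 12, artifact_rate = 0,
                      seed = 5)
  raw <- generate_condition(cfg, "comfort", 1)$raw
  pp <- preprocess_recording(raw, band = "alpha")
  expect_length(pp$rejected, 0)
  expect_equal(dim(pp$epochs$data)[1], 6)
  expect_identical(pp$epochs$band, "alpha")
})
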