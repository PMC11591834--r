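# Synthetic generator: analytic oracle, calibration, determinism, contracts.

test_that("expected_plv matches closed forms and a Monte-Carlo oracle", {
  expect_equal(expected_plv(0, 0), 1)
  expect_equal(expected_plv(sqrt(log(2)), sqrt(log(2))), 0.5)
  expect_equal(expected_plv(0.5, 0.5), exp(-0.25))
  # wrapped-normal mean resultant, 1e6 draws
  expect_equal(mc_wrapped_normal_plv(0.5, 0.5), exp(-0.25),
               tolerance = 2e-3)
  expect_error(expected_plv(-0.1, 0.5), "non-negative")
  m <- expected_plv_matrix(c(0, 0.5, 1))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 3))
  expect_equal(m[2, 3], exp(-(0.25 + 1) / 2))
})

test_that("config validation enforces the stated invariants", {
  expect_error(synth_config(sfreq = 20), "twice the highest")
  expect_error(synth_config(artifact_rate = 1.5), "artifact_rate")
  expect_error(synth_config(noise_sd = -1), "non-negative")
  expect_error(synth_config(duration = 1), "shorter than one epoch")
  expect_error(synth_config(jitter_sd = list(comfort = 0.5)), "named list")
  expect_error(synth_config(jitter_sd = list(comfort = 0.5, fatigue = 0.9)),
               "fatigue jitter")
  expect_error(synth_config(jitter_sd = list(comfort = -0.5,
                                             fatigue = -0.5)),
               "non-negative")
})

test_that("spatial calibration hits its targets and is monotone by condition", {
  cal <- calibrate_spatial_coupling(0.51, 0.53)
  expect_equal(unname(cal$achieved["comfort", ]), c(0.51, 0.72),
               tolerance = 0.005)
  expect_equal(unname(cal$achieved["fatigue", "mean"]), 0.53,
               tolerance = 0.005)
  # fatigue top-20% stays inside the plausible 0.72-0.76 window
  expect_gte(cal$achieved["fatigue", "top"], 0.72)
  expect_lte(cal$achieved["fatigue", "top"], 0.76)
  # every pair strengthens under fatigue
  expect_true(all(cal$v_fatigue <= cal$v_comfort + 1e-12))
  expect_error(calibrate_spatial_coupling(0.53, 0.51), "below comfort")
})

test_that("coupling_mixing reproduces the kernel as latent distances", {
  cal <- calibrate_spatial_coupling(0.50, 0.54)
  A <- coupling_mixing(cal$v_comfort)
  d2 <- as.matrix(dist(A))^2
  expect_equal(d2, cal$v_comfort, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("generation is deterministic in the seed and varies across it", {
  cfg <- synth_config(n_participants = 1, duration = 10, seed = 42)
  a <- generate_condition(cfg, "fatigue", 1)
  b <- generate_condition(cfg, "fatigue", 1)
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth, b$truth)
  c2 <- generate_condition(cfg, "fatigue", 2)
  expect_false(identical(a$raw$data, c2$raw$data))
  cfg2 <- synth_config(n_participants = 1, duration = 10, seed = 43)
  expect_false(identical(generate_condition(cfg2, "fatigue", 1)$raw$data,
                         a$raw$data))
})

test_that("zero jitter and zero noise lock all channels perfectly", {
  cfg <- synth_config(n_participants = 1, duration = 12,
                      bands = synth_bands()[3, ],
                      jitter_sd = list(comfort = 0, fatigue = 0),
                      noise_sd = 0, artifact_rate = 0, participant_sd = 0,
                      seed = 2)
  gc <- generate_condition(cfg, "comfort", 1)
  expect_equal(unname(gc$truth$expected_plv$alpha[1, 2]), 1)
  ep <- epoch_recording(gc$raw, 2)
  pm <- plv_matrix(instantaneous_phase(ep))
  expect_true(all(pm$values > 0.999))
})

test_that("generate_study writes recordings, manifest and ground truth", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_participants = 2, duration = 6, seed = 3)
  manifest <- generate_study(cfg, dir)
  expect_equal(nrow(manifest), 4)      # 2 participants x 2 conditions
  expect_true(all(file.exists(file.path(dir, manifest$path))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_length(gt, 4)
  # roundtrip one recording
  rec <- read_recording(file.path(dir, manifest$path[1]))
  expect_equal(rec$channel_labels, default_montage()$label)
  expect_equal(rec$sfreq, 250)
  expect_equal(rec$condition, manifest$condition[1])
  # group-mean fatigue coupling exceeds comfort in every band (analytic)
  for (b in c("delta", "theta", "alpha")) {
    pc <- gt[["P01_comfort"]]$expected_plv[[b]]
    pf <- gt[["P01_fatigue"]]$expected_plv[[b]]
    expect_gt(mean(pf[upper.tri(pf)]), mean(pc[upper.tri(pc)]))
  }
})

test_that("artifact injection trips the amplitude rule at the stated rate", {
  cfg <- synth_config(n_participants = 1, duration = 60, artifact_rate = 0.2,
                      seed = 6)
  gc <- generate_condition(cfg, "comfort", 1)
  expect_gt(length(gc$truth$artifact_windows), 0)
  ep <- epoch_recording(broadband_filter(gc$raw), 2)
  rej <- reject_amplitude(ep)
  # every injected window must be caught (filtering can smear into one
  # neighboring epoch, so allow supersets)
  expect_true(all(gc$truth$artifact_windows %in% rej$rejected))
  # no artifacts -> no rejections
  cfg0 <- synth_config(n_participants = 1, duration = 30, artifact_rate = 0,
                       seed = 6)
  gc0 <- generate_condition(cfg0, "comfort", 1)
  ep0 <- epoch_recording(broadband_filter(gc0$raw), 2)
  expect_length(reject_amplitude(ep0)$rejected, 0)
})

test_that("waveform pipeline recovers analytic PLV at sigma = 0.5", {
  cfg <- synth_config(n_participants = 1, duration = 120,
                      bands = synth_bands()[3, ],
                      jitter_sd = list(comfort = 0.5, fatigue = 0.5),
                      artifact_rate = 0, participant_sd = 0, seed = 11)
  gc <- generate_condition(cfg, "comfort", 1)
  pp <- preprocess_phases(gc$raw, "alpha", analytic = "continuous")
  pm <- plv_matrix(pp$phases, pooling = "pooled")
  off <- pm$values[upper.tri(pm$values)]
  expect_lt(abs(mean(off) - exp(-0.25)), 0.03)
})

test_that("phase-level estimates converge to the analytic PLV", {
  # errors at 20 / 60 / 200 epochs shrink monotonically below 0.03
  errs <- vapply(c(20, 60, 200), function(ne) {
    sims <- simulate_plv_study(0.5, n_participants = 1, n_epochs = ne,
                               n_samples = 500, n_channels = 12, seed = 77)
    v <- sims$comfort[[1]]$values
    abs(mean(v[upper.tri(v)]) - exp(-0.25))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
  expect_lt(errs[3], 0.03)
})
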