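test_that("hrf kernel has unit peak at the requested latency", {
  pars <- list(peak_time = 6, undershoot_ratio = 0.15, dispersion = 1)
  k <- hrf_kernel(pars, fs = 7.94)
  expect_equal(max(k), 1)
  # argmax within one sample of the dense-grid argmax
  dense <- hrf_kernel(pars, fs = 1000)
  t_coarse <- (which.max(k) - 1) / 7.94
  t_dense <- (which.max(dense) - 1) / 1000
  expect_lt(abs(t_coarse - t_dense), 1 / 7.94 + 1e-9)
  expect_lt(abs(t_dense - 6), 0.01)

  # no undershoot: non-negative, positive integral
  k0 <- hrf_kernel(list(peak_time = 6, undershoot_ratio = 0,
                        dispersion = 1), 7.94)
  expect_true(all(k0 >= 0))
  expect_gt(sum(k0), 0)
  # undershoot bounded by its ratio
  expect_gt(min(k), -0.15 - 1e-6)

  expect_error(hrf_kernel(list(peak_time = 6, dispersion = 0), 7.94),
               "dispersion")
  expect_error(hrf_kernel(list(peak_time = -1, dispersion = 1), 7.94),
               "peak_time")
})

test_that("session generation is deterministic under a fixed seed", {
  a <- generate_session(small_config(seed = 9), small_layout())
  b <- generate_session(small_config(seed = 9), small_layout())
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$events, b$events)
  expect_identical(a$headtrack, b$headtrack)
})

test_that("events are balanced, strictly increasing, jittered", {
  ses <- generate_session(small_config(seed = 3), small_layout())
  ev <- ses$events
  expect_equal(nrow(ev), 16)
  expect_equal(as.vector(table(ev$direction)), c(8, 8))
  expect_true(all(diff(ev$onset) > 0))
  gaps <- diff(ev$onset) - ev$duration[-nrow(ev)] - 6   # = jitter draws
  expect_true(all(gaps >= 2 - 1e-9 & gaps <= 4 + 1e-9))
})

test_that("zero gain and zero noise give constant intensities", {
  ses <- generate_session(small_config(seed = 2, tuning_gain = 0,
                                       response_amplitude = 0,
                                       noise = quiet_noise()),
                          small_layout())
  for (w in names(ses$intensity)) {
    rng <- apply(ses$intensity[[w]], 1, function(x) diff(range(x)))
    expect_true(all(rng == 0))
    expect_true(all(ses$intensity[[w]] > 0))
  }
})

test_that("noise-free sessions invert to ground truth through the MBLL", {
  # well-separated trials: the baseline window is then free of residual
  # response, making the closed-form inversion exact (see vignette on the
  # geometric- vs arithmetic-mean baseline gap for overlapping trials)
  ses <- generate_session(small_config(seed = 5, noise = quiet_noise(),
                                       inter_trial_interval = 35),
                          small_layout())
  ep760 <- epoch(ses$intensity$w760, ses$events, ses$fs)
  ep830 <- epoch(ses$intensity$w830, ses$events, ses$fs)
  co <- to_concentration(ep760, ep830)
  expect_true(all(co$valid_channel))
  for (tr in c(1, 7)) {
    for (k in ses$truth$channel_idx[1:2]) {
      expect_equal(co$hbo[tr, k, ], truth_epoch(ses, k, tr, "hbo"),
                   tolerance = 1e-8)
      expect_equal(co$hbr[tr, k, ], truth_epoch(ses, k, tr, "hbr"),
                   tolerance = 1e-8)
    }
  }
})

test_that("noise-only channels show the configured physiological spectrum", {
  ses <- generate_session(small_config(seed = 11, tuning_gain = 0,
                                       response_amplitude = 0),
                          small_layout())
  # attenuation of a channel, dominated by the noise processes
  x <- -log(ses$intensity$w830[1, ])
  sp <- spec.pgram(ts(x - mean(x), frequency = ses$fs), taper = 0,
                   plot = FALSE, detrend = TRUE)
  peak_power <- function(f0, half = 0.05) {
    mean(sp$spec[abs(sp$freq - f0) < half])
  }
  floor_power <- mean(sp$spec[sp$freq > 2 & sp$freq < 3])
  for (f0 in c(1.1, 0.3, 0.1)) {
    expect_gt(peak_power(f0), 5 * floor_power)
  }
})

test_that("head-track trace respects the configured motion bounds", {
  ses <- generate_session(small_config(seed = 6), small_layout())
  ht <- ses$headtrack
  # coupled oscillation 1.5 deg with 1.3 jitter cap plus slow wander
  expect_lt(max(abs(ht[, c("yaw", "pitch")])), 3)
  expect_lt(max(abs(ht[, c("x", "y", "z")])), 1)
  expect_equal(nrow(ht), length(ses$time_track))

  # coupling off leaves movement windows statistically like rest
  ses0 <- generate_session(
    small_config(seed = 6,
                 head_motion = list(amplitude_cm = 0.3, angle_deg = 1.5,
                                    direction_coupling = FALSE)),
    small_layout())
  mo <- ses0$events$onset[1]
  inwin <- ses0$time_track >= mo & ses0$time_track <= mo + 10
  expect_lt(diff(range(ses0$headtrack[inwin, "yaw"])), 0.5)
})

test_that("session bundles round-trip through their plain-text format", {
  ses <- generate_session(small_config(seed = 31), small_layout())
  d <- tempfile()
  write_session(ses, d)
  expect_setequal(list.files(d),
                  c("layout.json", "events.tsv", "headtrack.tsv",
                    "nirs_w760.tsv", "nirs_w830.tsv", "truth.json"))
  back <- read_session(d)
  expect_equal(back$fs, ses$fs)
  expect_equal(back$events$onset, ses$events$onset, tolerance = 1e-8)
  expect_equal(back$intensity$w830, ses$intensity$w830, tolerance = 1e-6)
  expect_equal(dim(back$headtrack), dim(ses$headtrack))
  # the reloaded bundle preprocesses like the in-memory one
  co1 <- preprocess_session(ses)
  co2 <- preprocess_session(back)
  expect_equal(co2$hbo, co1$hbo, tolerance = 1e-4)
  expect_equal(co2$valid_channel, co1$valid_channel)
  unlink(d, recursive = TRUE)
})

test_that("head motion does not touch intensities unless optically coupled", {
  cfg_on <- small_config(seed = 8)
  cfg_off <- small_config(seed = 8,
                          head_motion = list(amplitude_cm = 0.3,
                                             angle_deg = 1.5,
                                             direction_coupling = FALSE))
  # same seed: identical RNG path up to the track stage is not guaranteed,
  # so compare through the decoupled forward model instead: optics gain 0
  # means the intensity block never reads the track
  s_on <- generate_session(cfg_on, small_layout())
  expect_equal(s_on$config$motion_to_optics_gain, 0)
  s_g <- generate_session(small_config(seed = 8, motion_to_optics_gain = 0.01),
                          small_layout())
  expect_false(isTRUE(all.equal(s_on$intensity$w830, s_g$intensity$w830)))
})
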