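test_that("low-pass filter has unit DC gain and the analytic cutoff gain", {
  fs <- 7.94
  spec_c <- filter_spec(0.12, mode = "causal")
  x <- rep(3.7, 500)
  expect_equal(lowpass(x, spec_c, fs), x, tolerance = 1e-9)

  # steady-state amplitude of a sinusoid at the cutoff: |H| = 1/sqrt(2)
  # for any Butterworth order (analytic magnitude response)
  tt <- (0:19999) / fs
  s <- sin(2 * pi * 0.12 * tt)
  y <- lowpass(s, spec_c, fs)
  tail_amp <- (max(y[10000:20000]) - min(y[10000:20000])) / 2
  expect_equal(tail_amp, 1 / sqrt(2), tolerance = 0.01)

  # acausal filtering is zero-phase: a symmetric pulse keeps its peak index
  pulse <- exp(-((0:799) - 400)^2 / (2 * 40^2))
  ya <- lowpass(pulse, filter_spec(0.3, mode = "acausal"), fs)
  expect_equal(which.max(ya), 401)
  # while the causal pass delays it
  yc <- lowpass(pulse, filter_spec(0.3, mode = "causal"), fs)
  expect_gt(which.max(yc), 401)

  expect_error(lowpass(s, filter_spec(4), fs), "Nyquist")
  expect_error(lowpass(rnorm(5), spec_c, fs), "too short")
})

test_that("epoching yields the documented sample count and window", {
  fs <- 7.94
  ser <- matrix(rnorm(2 * 3000), 2)
  ev <- data.frame(onset = c(50, 120, 150), duration = 10,
                   direction = c("left", "down", "left"))
  ep <- epoch(ser, ev, fs)
  # 41 s window at 7.94 Hz: round(325.54) + 1 samples
  expect_equal(dim(ep$data), c(3, 2, 327))
  expect_equal(ep$labels, ev$direction)
  expect_equal(ep$time[1], -round(6 * fs) / fs)
  expect_lt(abs(ep$time[1] + 6), 1 / fs)
  # trials 2 and 3 overlap (30 s apart, 41 s windows): both kept intact
  expect_false(anyNA(ep$data))

  # zero trials: empty set, no error
  ep0 <- epoch(ser, ev[0, ], fs)
  expect_equal(dim(ep0$data)[1], 0)

  # window exceeding the recording names the offending trial
  expect_error(epoch(ser, data.frame(onset = 2, duration = 10), fs),
               "trial 1")
})

test_that("concentration conversion inverts a hand-computed 2x2 system", {
  # epsilon = [[1,2],[3,1]]; inject dA = eps %*% c(1, -0.5) on top of a
  # flat baseline; conversion must return exactly (1, -0.5)
  eps <- rbind(c(1, 2), c(3, 1))
  ext <- extinction_table(eps)
  fs <- 10
  nle <- round(41 * fs) + 1
  target <- c(hbo = 1, hbr = -0.5)
  dA <- as.vector(eps %*% target)                 # c(0, -0.5)... by hand: 1*1+2*(-.5)=0; 3*1+1*(-.5)=2.5
  mk <- function(dA1) {
    ser <- matrix(1, 1, 900)
    ser[1, 500:700] <- exp(-dA1)                 # step after the baseline
    ser
  }
  ev <- data.frame(onset = 49.0, duration = 10, direction = "left")
  ep760 <- epoch(mk(dA[1]), ev, fs)
  ep830 <- epoch(mk(dA[2]), ev, fs)
  co <- to_concentration(ep760, ep830, ext)
  j <- 150                                        # inside the step
  expect_equal(co$hbo[1, 1, j], 1, tolerance = 1e-10)
  expect_equal(co$hbr[1, 1, j], -0.5, tolerance = 1e-10)
  # linearity: doubling the attenuation doubles the concentrations
  co2 <- to_concentration(epoch(mk(2 * dA[1]), ev, fs),
                          epoch(mk(2 * dA[2]), ev, fs), ext)
  expect_equal(co2$hbo[1, 1, j], 2, tolerance = 1e-10)
  expect_equal(co2$hbr[1, 1, j], -1, tolerance = 1e-10)
})

test_that("flat intensities give zero concentration change", {
  fs <- 7.94
  ser <- matrix(2.5, 2, 1000)
  ev <- data.frame(onset = c(30, 70), duration = 10)
  co <- to_concentration(epoch(ser, ev, fs), epoch(ser, ev, fs))
  expect_true(all(abs(co$hbo) < 1e-12))
  expect_true(all(abs(co$hbr) < 1e-12))
  expect_true(all(co$valid_channel))
})

test_that("one negative sample invalidates the channel for the whole set", {
  fs <- 7.94
  ser760 <- matrix(1, 3, 1000)
  ser830 <- matrix(1, 3, 1000)
  ser830[2, 400] <- -0.01                         # single bad sample, one trial
  ev <- data.frame(onset = c(30, 70), duration = 10)
  co <- to_concentration(epoch(ser760, ev, fs), epoch(ser830, ev, fs))
  expect_equal(co$valid_channel, c(TRUE, FALSE, TRUE))
  # flagged, not dropped: arrays keep all channels
  expect_equal(dim(co$hbo)[2], 3)
})

test_that("two-step channel selection puts validity before distance", {
  fs <- 7.94
  ser <- matrix(1 + 0.01 * sin(seq_len(1000) / 9), 3, 1000, byrow = TRUE)
  ser2 <- ser
  ser2[2, 500] <- -1                              # 3 cm channel goes invalid
  ev <- data.frame(onset = c(30, 70), duration = 10)
  channels <- data.frame(distance = c(1, 3, 6), region = "contra_SM")
  co_ok <- to_concentration(epoch(ser, ev, fs), epoch(ser, ev, fs))
  expect_equal(select_channels(co_ok, channels), 2L)
  expect_equal(select_channels(co_ok, channels, 0, 2), 1L)
  co_bad <- to_concentration(epoch(ser, ev, fs), epoch(ser2, ev, fs))
  expect_warning(idx <- select_channels(co_bad, channels), "empty")
  expect_length(idx, 0)
})

test_that("filtering before epoching is not equivalent to the reverse order", {
  ses <- generate_session(small_config(seed = 13), small_layout())
  spec <- filter_spec(0.12)
  co_std <- preprocess_session(ses, spec)
  # reversed order: epoch raw, convert, then filter each trial's trace
  ep760 <- epoch(ses$intensity$w760, ses$events, ses$fs)
  ep830 <- epoch(ses$intensity$w830, ses$events, ses$fs)
  co_rev <- to_concentration(ep760, ep830)
  k <- select_channels(co_std, ses$layout$channels)[1]
  rev_trace <- lowpass(co_rev$hbo[1, k, ], spec, ses$fs)
  # the short per-trial segment hits the filter transient differently
  expect_gt(max(abs(rev_trace - co_std$hbo[1, k, ])), 1e-3)
})
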