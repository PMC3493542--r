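# shared fixtures: a small montage and short sessions keep most tests fast;
# full-size cohorts are reserved for the acceptance checks

small_layout <- function() {
  # 3 co-located sources + 9 detectors: 3 x 12 = 36 channels
  grid <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2))
  contra <- cbind(grid$x, grid$y + 2, 9)       # flat-ish patch, cm
  other <- rbind(c(6, 2, 6), c(6, 4.5, 6), c(0, 10, 4))
  lay <- nirs_layout(
    id = c(sprintf("C%d", 1:9), "I1", "I2", "P1"),
    role = c("colocated", "detector", "detector",
             "detector", "colocated", "detector",
             "detector", "detector", "colocated",
             "colocated", "detector", "detector"),
    position = rbind(contra, other),
    region = c(rep("contra_SM", 9), "ipsi_SM", "ipsi_SM", "prefrontal")
  )
  project_layout(lay, "contra_SM")
}

# short session: 8 trials/direction, tight timing; ~0.3 s to generate
small_config <- function(seed = 1, inter_trial_interval = 6, ...) {
  sim_config(n_trials_per_direction = 8,
             inter_trial_interval = inter_trial_interval,
             seed = seed, ...)
}

quiet_noise <- function() {
  list(cardiac_hz = 1.1, resp_hz = 0.3, mayer_hz = 0.1,
       cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
       drift_sd = 0, white_sd = 0)
}

# memoised default-size session shared across test files
.fixture_env <- new.env()
default_session <- function() {
  if (is.null(.fixture_env$ses)) {
    .fixture_env$ses <- generate_session(sim_config(seed = 42),
                                         default_montage())
  }
  .fixture_env$ses
}

# ground-truth concentration of channel k over the epoch of trial `tr`,
# baseline-referenced the way the pipeline is (independent index arithmetic)
truth_epoch <- function(ses, k, tr, what = "hbo", pre = 6, post = 25) {
  fs <- ses$fs
  row <- match(k, ses$truth$channel_idx)
  dur <- ses$events$duration[tr]
  i0 <- floor(ses$events$onset[tr] * fs) + 1
  npre <- round(pre * fs)
  nlen <- round((pre + dur + post) * fs) + 1
  idx <- (i0 - npre):(i0 - npre + nlen - 1)
  x <- ses$truth[[what]][row, idx]
  tt <- (seq_along(idx) - 1 - npre) / fs
  x - mean(x[tt >= -1 & tt < 0])
}
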