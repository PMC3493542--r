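#' Simulation configuration for synthetic fNIRS sessions
#'
#' Bundles every parameter of the synthetic session generator. Defaults
#' emulate one recording session of the motor paradigm the package targets:
#' 30 trials per direction of 10 s periodic hand movement (left vs. down),
#' two-wavelength optical recordings at 7.94 Hz, 6-DOF head tracking at
#' 30 Hz, direction-tuned hemodynamic responses on a subset of the
#' contralateral long-distance channels, and physiological noise (cardiac,
#' respiratory, Mayer wave, drift, white) entering in the attenuation
#' domain.
#'
#' @param n_trials_per_direction trials per movement direction (default 30).
#' @param directions movement directions, a subset of
#'   `c("left", "down", "up", "right")`.
#' @param fs_nirs optical sampling rate, Hz.
#' @param fs_track head-tracker sampling rate, Hz.
#' @param movement_duration movement block length, s.
#' @param prep_jitter `c(min, max)` of the uniform jitter (s) between the
#'   preparation cue and movement onset; breaks phase locking of periodic
#'   physiology to the trial grid.
#' @param inter_trial_interval rest between movement end and the next
#'   preparation cue, s.
#' @param hrf hemodynamic response kernel parameters:
#'   `peak_time` (s), `undershoot_ratio` (relative undershoot depth, >= 0),
#'   `dispersion` (gamma time scale, s). See [hrf_kernel()].
#' @param response_amplitude peak oxyhemoglobin response to one movement
#'   block on responding channels, in µM·mm (concentration x pathlength, the
#'   unit the modified Beer-Lambert conversion reports).
#' @param tuning_gain multiplicative amplitude contrast between the two
#'   directions on tuned channels (0 = no direction information). Each tuned
#'   channel draws its own contrast from
#'   `tuning_gain * U(0.5, 1.5)`, and half the tuned channels prefer each
#'   direction (for some channels the response is higher for one direction,
#'   for others the opposite).
#' @param tuned_channel_fraction fraction of contralateral long-distance
#'   channels carrying direction tuning.
#' @param hbr_ratio scale linking deoxy- to oxyhemoglobin responses
#'   (negative: HbR falls as HbO rises); HbR is additionally delayed by
#'   `hbr_delay` s.
#' @param hbr_delay delay of the HbR response relative to HbO, s.
#' @param noise list of noise parameters: component frequencies
#'   `cardiac_hz`, `resp_hz`, `mayer_hz` (Hz), amplitudes `cardiac_amp`,
#'   `resp_amp`, `mayer_amp` (µM·mm HbO-equivalent), random-walk scale
#'   `drift_sd` and white-noise `white_sd` (µM·mm). All enter the intensity
#'   model through attenuation, as extra-cortical physiology does.
#' @param head_motion list: `amplitude_cm` (translation amplitude),
#'   `angle_deg` (rotation amplitude), `direction_coupling` (logical: head
#'   oscillations at the movement frequency, yaw for left / pitch for down,
#'   during movement blocks).
#' @param motion_to_optics_gain attenuation change per cm of head
#'   displacement (default 0: small head movements leave the optics
#'   untouched; large-amplitude regimes can be emulated by raising it).
#' @param session convenience preset: `1` (default; hand movements with
#'   direction-tuned responses plus small involuntary coupled head motion)
#'   or `2` (control: voluntary coupled head movements, roughly three times
#'   larger, and no hand movement, hence no cortical response at all).
#' @param seed integer seed making the session reproducible; `NULL` uses the
#'   current RNG state.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_trials_per_direction = 30,
                       directions = c("left", "down"),
                       fs_nirs = 7.94,
                       fs_track = 30,
                       movement_duration = 10,
                       prep_jitter = c(2, 4),
                       inter_trial_interval = 18,
                       hrf = list(peak_time = 6, undershoot_ratio = 0.15,
                                  dispersion = 1),
                       response_amplitude = 30,
                       tuning_gain = 0.3,
                       tuned_channel_fraction = 0.5,
                       hbr_ratio = -0.35,
                       hbr_delay = 1,
                       noise = list(cardiac_hz = 1.1, resp_hz = 0.3,
                                    mayer_hz = 0.1, cardiac_amp = 5,
                                    resp_amp = 8, mayer_amp = 10,
                                    drift_sd = 8, white_sd = 3),
                       head_motion = list(amplitude_cm = 0.3,
                                          angle_deg = 1.5,
                                          direction_coupling = TRUE),
                       motion_to_optics_gain = 0,
                       session = 1,
                       seed = NULL) {
  if (session == 2) {
    # control session: head moves, hand does not
    response_amplitude <- 0
    tuning_gain <- 0
    head_motion$amplitude_cm <- 3 * head_motion$amplitude_cm
    head_motion$angle_deg <- min(3 * head_motion$angle_deg, 3)
    head_motion$direction_coupling <- TRUE
  } else if (session != 1) {
    stopf("session must be 1 or 2")
  }
  directions <- match.arg(directions, c("left", "down", "up", "right"),
                          several.ok = TRUE)
  if (anyDuplicated(directions)) stopf("duplicate directions")
  if (fs_nirs <= 0 || fs_track <= 0) stopf("sampling rates must be > 0")
  if (tuning_gain < 0) stopf("tuning_gain must be >= 0")
  if (length(prep_jitter) != 2 || any(prep_jitter < 0) ||
      prep_jitter[2] < prep_jitter[1]) {
    stopf("prep_jitter must be a non-negative range c(min, max)")
  }
  if (movement_duration <= 0) stopf("movement_duration must be > 0")
  if (tuned_channel_fraction < 0 || tuned_channel_fraction > 1) {
    stopf("tuned_channel_fraction must be in [0, 1]")
  }
  structure(list(
    n_trials_per_direction = n_trials_per_direction,
    directions = directions, fs_nirs = fs_nirs, fs_track = fs_track,
    movement_duration = movement_duration, prep_jitter = prep_jitter,
    inter_trial_interval = inter_trial_interval, hrf = hrf,
    response_amplitude = response_amplitude, tuning_gain = tuning_gain,
    tuned_channel_fraction = tuned_channel_fraction, hbr_ratio = hbr_ratio,
    hbr_delay = hbr_delay, noise = noise, head_motion = head_motion,
    motion_to_optics_gain = motion_to_optics_gain, session = session,
    seed = seed
  ), class = "sim_config")
}

#' Hemodynamic response kernel
#'
#' Double-gamma impulse response: a gamma-shaped positive lobe peaking at
#' `peak_time` minus a later, `undershoot_ratio`-scaled lobe peaking 10 s
#' after it, normalised to unit peak. Convolved with a 10 s boxcar it decays
#' back to ~0 within 25 s of block end, matching typical motor-cortex
#' responses.
#'
#' @param hrf_params list with `peak_time` (s, > 0), `undershoot_ratio`
#'   (>= 0) and `dispersion` (s, > 0).
#' @param fs sampling rate, Hz.
#' @return numeric kernel sampled at `fs`, 0 to 32 s, peak value 1.
#' @export
#' @examples
#' k <- hrf_kernel(list(peak_time = 6, undershoot_ratio = 0.15,
#'                      dispersion = 1), fs = 7.94)
#' plot(seq_along(k) / 7.94, k, type = "l")
hrf_kernel <- function(hrf_params, fs) {
  p <- hrf_params$peak_time
  u <- hrf_params$undershoot_ratio %||% 0
  b <- hrf_params$dispersion %||% 1
  if (is.null(p) || p <= 0) stopf("hrf peak_time must be > 0")
  if (b <= 0) stopf("hrf dispersion must be > 0")
  if (u < 0) stopf("hrf undershoot_ratio must be >= 0")
  t <- seq(0, 32, by = 1 / fs)
  gshape <- function(t, d) ifelse(t <= 0, 0, (t / d)^(d / b) * exp(-(t - d) / b))
  h <- gshape(t, p) - u * gshape(t, p + 10)
  h / max(h)
}

#' Generate a synthetic recording session
#'
#' Produces a complete session bundle with known ground truth: raw
#' two-wavelength light intensities for every channel of `layout`, the
#' event table, a 6-DOF head-tracking trace, and the true noise-free
#' concentration responses of the responding channels.
#'
#' The forward model: every contralateral long-distance channel carries a
#' hemodynamic response `scale * gain(direction) * (hrf (*) boxcar)` in
#' ΔHbO (µM·mm), with `gain` differing between directions only on tuned
#' channels; ΔHbR is a delayed, negatively scaled copy. Responses and
#' physiological noise are mapped to attenuation changes at 760 and 830 nm
#' through the extinction table and exponentiated onto per-channel baseline
#' intensities, `I = I0 * exp(-ΔA)`. Short-distance and
#' non-contralateral channels receive noise but no direction-tuned cortical
#' term. The head-track trace contains slow wander, sensor noise and — when
#' coupling is on — small direction-locked oscillations at the 0.25 Hz
#' movement frequency (yaw/x for left-right, pitch/z for down-up) during
#' movement blocks.
#'
#' @param config a [sim_config()].
#' @param layout a `nirs_layout` (default [default_montage()]).
#' @param ext extinction table used by the forward model (default
#'   [extinction_table()]); the inverse (MBLL) step with the same table
#'   recovers the ground truth exactly in the noise-free case.
#' @return an object of class `nirs_session`: list with elements
#'   `intensity` (list of channel x time matrices `w760`, `w830`), `time`,
#'   `fs`, `events` (data frame: onset, duration, direction), `headtrack`
#'   (time x 6 matrix: x, y, z cm; yaw, pitch, roll deg), `fs_track`,
#'   `layout`, `truth` (list: `channel_idx` of responding channels, their
#'   clean `hbo`/`hbr` time courses, per-channel `contrast` and `tuned`
#'   mask), and `config`.
#' @export
generate_session <- function(config = sim_config(), layout = default_montage(),
                             ext = extinction_table()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fs <- config$fs_nirs
    dirs <- config$directions
    ntr <- config$n_trials_per_direction
    ndir <- length(dirs)
    dur <- config$movement_duration

    ## -- events: balanced pseudo-random order, jittered onsets ------------
    direction <- sample(rep(dirs, each = ntr))
    n_ev <- ndir * ntr
    jit <- stats::runif(n_ev, config$prep_jitter[1], config$prep_jitter[2])
    onset <- numeric(n_ev)
    prev_end <- 30              # settle-in pad before the first trial
    for (i in seq_len(n_ev)) {
      onset[i] <- prev_end + config$inter_trial_interval + jit[i]
      prev_end <- onset[i] + dur
    }
    events <- data.frame(onset = onset, duration = dur,
                         direction = direction, stringsAsFactors = FALSE)
    t_end <- prev_end + 35
    nt <- floor(t_end * fs) + 1
    tt <- (seq_len(nt) - 1) / fs

    ## -- channel response structure ---------------------------------------
    ch <- layout$channels
    nch <- nrow(ch)
    resp_idx <- which(ch$region == "contra_SM" & ch$distance >= 2.5 &
                        ch$distance <= 5.2)
    nresp <- length(resp_idx)
    n_tuned <- round(config$tuned_channel_fraction * nresp)
    tuned_local <- sample(nresp, n_tuned)
    contrast <- numeric(nch)
    contrast[resp_idx[tuned_local]] <-
      config$tuning_gain * stats::runif(n_tuned, 0.5, 1.5)
    # preference: half the tuned channels respond more to the first
    # direction, half to the second (and analogously for 4 directions)
    pref <- rep(NA_character_, nch)
    pref[resp_idx[tuned_local]] <- rep_len(dirs, n_tuned)
    scale_k <- numeric(nch)
    scale_k[resp_idx] <- stats::runif(nresp, 0.7, 1.3)

    # per-direction gain per channel: tuned channels split the contrast
    # around 1 in favour of their preferred direction
    gains <- matrix(1, nch, ndir, dimnames = list(NULL, dirs))
    for (j in seq_len(ndir)) {
      is_pref <- !is.na(pref) & pref == dirs[j]
      gains[is_pref, j] <- 1 + contrast[is_pref] / 2
      gains[!is.na(pref) & pref != dirs[j], j] <-
        1 - contrast[!is.na(pref) & pref != dirs[j]] / 2
    }

    ## -- clean responses ---------------------------------------------------
    kern <- hrf_kernel(config$hrf, fs)
    amp_jit <- exp(stats::rnorm(n_ev, 0, 0.2))   # trial-to-trial variability
    # per-direction weighted boxcars convolved once with the kernel
    R <- matrix(0, ndir, nt)
    for (j in seq_len(ndir)) {
      box <- numeric(nt)
      for (i in which(direction == dirs[j])) {
        i0 <- floor(onset[i] * fs) + 1
        i1 <- min(floor((onset[i] + dur) * fs) + 1, nt)
        box[i0:i1] <- box[i0:i1] + amp_jit[i]
      }
      R[j, ] <- stats::convolve(box, rev(kern), type = "open")[seq_len(nt)]
    }
    # normalise so that a unit-gain channel peaks at response_amplitude
    peak <- max(stats::convolve(c(rep(1, round(dur * fs)), numeric(length(kern))),
                                rev(kern), type = "open"))
    R <- R / peak * config$response_amplitude

    truth_hbo <- (gains * scale_k) %*% R          # nch x nt, zero off-response rows
    dlag <- round(config$hbr_delay * fs)
    Rlag <- cbind(matrix(0, ndir, dlag), R[, seq_len(nt - dlag), drop = FALSE])
    truth_hbr <- config$hbr_ratio * ((gains * scale_k) %*% Rlag)

    ## -- physiological noise (µM·mm HbO/HbR equivalents) ------------------
    nz <- config$noise
    osc <- function(f, amp, phase) amp * sin(2 * pi * f * tt + phase)
    shared_hbo <- osc(nz$cardiac_hz, nz$cardiac_amp, stats::runif(1, 0, 2 * pi)) +
      osc(nz$resp_hz, nz$resp_amp, stats::runif(1, 0, 2 * pi)) +
      osc(nz$mayer_hz, nz$mayer_amp, stats::runif(1, 0, 2 * pi))
    drift_shared <- if (nz$drift_sd > 0) {
      cumsum(stats::rnorm(nt)) * nz$drift_sd / sqrt(nt)
    } else numeric(nt)
    shared_hbo <- shared_hbo + drift_shared
    w_k <- stats::runif(nch, 0.5, 1.5)

    noise_hbo <- tcrossprod(0.7 * w_k, shared_hbo)
    any_noise <- nz$cardiac_amp > 0 || nz$resp_amp > 0 || nz$mayer_amp > 0
    if (any_noise) {
      # per-channel replicas with own phases and slightly jittered rates
      for (comp in list(c(nz$cardiac_hz, nz$cardiac_amp),
                        c(nz$resp_hz, nz$resp_amp),
                        c(nz$mayer_hz, nz$mayer_amp))) {
        if (comp[2] <= 0) next
        fj <- comp[1] * stats::runif(nch, 0.95, 1.05)
        ph <- stats::runif(nch, 0, 2 * pi)
        noise_hbo <- noise_hbo +
          0.7 * comp[2] * sin(outer(2 * pi * fj, tt) + ph)
      }
    }
    if (nz$drift_sd > 0) {
      own_drift <- apply(matrix(stats::rnorm(nch * nt), nch, nt), 1, cumsum)
      noise_hbo <- noise_hbo + t(own_drift) * (0.7 * nz$drift_sd / sqrt(nt))
    }
    if (nz$white_sd > 0) {
      noise_hbo <- noise_hbo + matrix(stats::rnorm(nch * nt, 0, nz$white_sd),
                                      nch, nt)
    }
    noise_hbr <- -0.3 * noise_hbo
    if (nz$white_sd > 0) {
      noise_hbr <- noise_hbr + matrix(stats::rnorm(nch * nt, 0, nz$white_sd),
                                      nch, nt)
    }

    C_hbo <- truth_hbo + noise_hbo
    C_hbr <- truth_hbr + noise_hbr
    rm(noise_hbo, noise_hbr)

    ## -- head tracking ------------------------------------------------------
    hm <- config$head_motion
    fs2 <- config$fs_track
    nt2 <- floor(t_end * fs2) + 1
    tt2 <- (seq_len(nt2) - 1) / fs2
    wander <- function(sd) cumsum(stats::rnorm(nt2)) * sd / sqrt(nt2)
    track <- cbind(
      x = wander(0.03), y = wander(0.03), z = wander(0.03),
      yaw = wander(0.08), pitch = wander(0.08), roll = wander(0.08)
    )
    track <- track + matrix(stats::rnorm(nt2 * 6, 0, 0.002), nt2, 6)
    if (isTRUE(hm$direction_coupling)) {
      dof_of <- c(left = "yaw", right = "yaw", down = "pitch", up = "pitch")
      sgn_of <- c(left = 1, right = -1, down = 1, up = -1)
      lin_of <- c(left = "x", right = "x", down = "z", up = "z")
      for (i in seq_len(n_ev)) {
        inwin <- tt2 >= onset[i] & tt2 <= onset[i] + dur
        tau <- tt2[inwin] - onset[i]
        ramp <- pmin(1, tau / 1, (dur - tau) / 1)   # 1 s on/off ramps
        s <- sin(2 * pi * 0.25 * tau) * ramp *
          stats::runif(1, 0.7, 1.3) * sgn_of[direction[i]]
        track[inwin, dof_of[direction[i]]] <-
          track[inwin, dof_of[direction[i]]] + hm$angle_deg * s
        track[inwin, lin_of[direction[i]]] <-
          track[inwin, lin_of[direction[i]]] + hm$amplitude_cm * s
      }
    }

    ## -- intensities --------------------------------------------------------
    E <- ext$matrix    # 2x2: rows 760/830, cols HbO/HbR
    dA760 <- E[1, 1] * C_hbo + E[1, 2] * C_hbr
    dA830 <- E[2, 1] * C_hbo + E[2, 2] * C_hbr
    rm(C_hbo, C_hbr)
    if (config$motion_to_optics_gain > 0) {
      disp <- sqrt(track[, "x"]^2 + track[, "y"]^2 + track[, "z"]^2)
      disp_n <- stats::approx(tt2, disp, xout = tt, rule = 2)$y
      coup <- stats::runif(nch, -1, 1) * config$motion_to_optics_gain
      dA760 <- dA760 + tcrossprod(coup, disp_n)
      dA830 <- dA830 + tcrossprod(coup, disp_n)
    }
    I0 <- exp(stats::rnorm(nch, 0, 0.2))
    intensity <- list(w760 = I0 * exp(-dA760), w830 = I0 * exp(-dA830))

    structure(list(
      intensity = intensity, time = tt, fs = fs, events = events,
      headtrack = track, time_track = tt2, fs_track = fs2, layout = layout,
      truth = list(channel_idx = resp_idx,
                   hbo = truth_hbo[resp_idx, , drop = FALSE],
                   hbr = truth_hbr[resp_idx, , drop = FALSE],
                   contrast = contrast,
                   tuned = contrast > 0,
                   preferred = pref),
      config = config
    ), class = "nirs_session")
  })
}

#' @export
print.nirs_session <- function(x, ...) {
  cat(sprintf(
    "<nirs_session> %d channels x %d samples at %.2f Hz (%.1f min), %d trials (%s)\n",
    nrow(x$intensity$w760), length(x$time), x$fs,
    max(x$time) / 60, nrow(x$events),
    paste(sprintf("%s=%d", names(table(x$events$direction)),
                  table(x$events$direction)), collapse = ", ")))
  cat(sprintf("  head track: %d samples at %g Hz; %d tuned channels\n",
              nrow(x$headtrack), x$fs_track, sum(x$truth$tuned)))
  invisible(x)
}

#' Write a session bundle to a directory of plain-text files
#'
#' Serialises a synthetic session as `layout.json`, `nirs_w760.tsv` /
#' `nirs_w830.tsv` (channels x time intensity matrices), `events.tsv`
#' (onset, duration, direction), `headtrack.tsv` (time, x, y, z, yaw,
#' pitch, roll) and `truth.json` (tuned-channel mask and contrasts).
#'
#' @param session a `nirs_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_layout(session$layout, file.path(dir, "layout.json"))
  utils::write.table(session$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ht <- data.frame(time = session$time_track, session$headtrack)
  utils::write.table(ht, file.path(dir, "headtrack.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (w in names(session$intensity)) {
    utils::write.table(session$intensity[[w]],
                       file.path(dir, sprintf("nirs_%s.tsv", w)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(fs = session$fs, fs_track = session$fs_track,
         tuned = session$truth$tuned, contrast = session$truth$contrast),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  need <- c("layout.json", "events.tsv", "nirs_w760.tsv", "nirs_w830.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stopf("session bundle %s lacks: %s", dir, paste(missing, collapse = ", "))
  }
  layout <- read_layout(file.path(dir, "layout.json"))
  events <- utils::read.delim(file.path(dir, "events.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  intensity <- lapply(c(w760 = "nirs_w760.tsv", w830 = "nirs_w830.tsv"),
                      function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  })
  ht <- utils::read.delim(file.path(dir, "headtrack.tsv"))
  nt <- ncol(intensity$w760)
  structure(list(
    intensity = lapply(intensity, unname),
    time = (seq_len(nt) - 1) / meta$fs, fs = meta$fs,
    events = events,
    headtrack = as.matrix(ht[, c("x", "y", "z", "yaw", "pitch", "roll")]),
    time_track = ht$time, fs_track = meta$fs_track, layout = layout,
    truth = list(tuned = meta$tuned, contrast = meta$contrast),
    config = NULL
  ), class = "nirs_session")
}
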