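#' Resample a head-tracking trace to the optical sampling rate
#'
#' Anti-aliased rational resampling of each degree of freedom from the
#' tracker rate to the fNIRS rate: the trace is first band-limited below
#' the output Nyquist frequency by a zero-phase Butterworth low-pass
#' (90% of Nyquist, 4th order forward-backward), then evaluated by cubic
#' spline on the exact rational output grid. The rate ratio is
#' represented exactly by continued fractions (7.94/30 is 397/1500) and
#' attached as an attribute.
#'
#' @param trace numeric vector or time x DOF matrix, uniformly sampled.
#' @param fs_in input rate, Hz.
#' @param fs_out output rate, Hz (default 7.94).
#' @param timestamps optional sample times; if given, they must be
#'   uniform (non-uniform traces are rejected, not silently interpolated).
#' @return resampled vector/matrix; attribute `"ratio"` holds `c(p, q)`.
#' @export
resample_track <- function(trace, fs_in = 30, fs_out = 7.94,
                           timestamps = NULL) {
  if (!is.null(timestamps)) {
    dt <- diff(timestamps)
    if (length(dt) > 0 &&
        (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
      stopf("timestamps are not uniform; resampling requires a uniform grid")
    }
  }
  if (fs_out >= fs_in) stopf("only downsampling (fs_out < fs_in) is supported")
  pq <- rational_ratio(fs_out / fs_in)
  one <- function(col) {
    aa <- lowpass(col, filter_spec(0.9 * fs_out / 2, order = 4,
                                   mode = "acausal"), fs_in)
    t_in <- (seq_along(col) - 1) / fs_in
    # output grid: multiples of q/(p*fs_in) inside the recording
    n_out <- floor((length(col) - 1) * pq[1] / pq[2]) + 1
    t_out <- (seq_len(n_out) - 1) * pq[2] / (pq[1] * fs_in)
    stats::spline(t_in, aa, xout = t_out)$y
  }
  res <- if (is.matrix(trace)) apply(trace, 2, one) else one(trace)
  attr(res, "ratio") <- pq
  res
}

# continued-fraction rational approximation p/q of x, q bounded
rational_ratio <- function(x, max_den = 10000, tol = 1e-9) {
  a <- floor(x); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1
  frac <- x - a
  while (abs(p1 / q1 - x) > tol * x && q1 < max_den && frac > tol) {
    frac <- 1 / frac
    a <- floor(frac)
    frac <- frac - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(p = p1, q = q1)
}

#' Preprocess a head-tracking trace exactly like the fNIRS signals
#'
#' Resamples the 6-DOF trace to the optical rate, applies the same causal
#' low-pass filter, cuts the same trial windows, and references every
#' trial to its baseline (mean over the second preceding movement onset),
#' so the epochs express change of head position/orientation relative to
#' just before the movement.
#'
#' @param session a `nirs_session` (uses `headtrack`, `fs_track`, `events`,
#'   `fs`).
#' @param spec causal [filter_spec()] (default 0.12 Hz, as the decoding
#'   branch uses for fNIRS).
#' @param pre,post epoch window, s.
#' @return list of class `track_epochs`: `data` (trials x 6 x samples,
#'   baseline-referenced; x/y/z in cm, yaw/pitch/roll in deg), `time`,
#'   `labels`, `fs`, `dof` names.
#' @export
track_pipeline <- function(session, spec = filter_spec(0.12),
                           pre = 6, post = 25) {
  tr <- resample_track(session$headtrack, session$fs_track, session$fs,
                       timestamps = session$time_track)
  filt <- lowpass(t(tr), spec, session$fs)         # DOF x time
  ep <- epoch(filt, session$events, session$fs, pre, post)
  bsel <- ep$time >= -1 & ep$time < 0
  base <- apply(ep$data[, , bsel, drop = FALSE], c(1, 2), mean)
  data <- ep$data - as.vector(base)                # recycles trials x DOF
  structure(list(data = data, time = ep$time, labels = ep$labels,
                 fs = ep$fs, dof = c("x", "y", "z", "yaw", "pitch", "roll")),
            class = "track_epochs")
}

#' Time-resolved decoding of movement direction from head motion
#'
#' Identical decoding machinery to the fNIRS branch
#' ([time_resolved_da()]), applied to the six baseline-referenced
#' position/orientation features. Used as the motion-artifact control: if
#' optical decoding reflected head motion, its DA time course would mirror
#' this one (a rapid rise at movement onset and a plateau until movement
#' end) rather than the slow hemodynamic rise.
#'
#' @param epochs a `track_epochs` from [track_pipeline()].
#' @param folds,repeats,lambda,seed,alpha see [time_resolved_da()].
#' @return a `da_curve`.
#' @export
decode_track <- function(epochs, folds = 10, repeats = 5, lambda = 0.25,
                         seed = NULL, alpha = 0.001) {
  stopifnot(inherits(epochs, "track_epochs"))
  if (length(unique(epochs$labels)) < 2) stopf("need >= 2 classes")
  decode_array(epochs$data, epochs$labels, epochs$time, window = 1,
               folds = folds, repeats = repeats, lambda = lambda,
               seed = seed, alpha = alpha)
}
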