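#' Extinction coefficient table
#'
#' Natural-log molar absorption coefficients of oxy- and deoxyhemoglobin at
#' 760 and 830 nm, expressed per µM of chromophore per mm of pathlength so
#' that attenuation changes convert directly to concentration x pathlength
#' in µM·mm. Values are converted from the standard Prahl compilation of
#' hemoglobin spectra; they stand in for the unpublished average of the
#' historical tabulations and can be replaced wholesale.
#'
#' @param matrix optional 2x2 replacement matrix, rows = wavelengths
#'   (760, 830 nm), columns = chromophores (HbO, HbR), units (µM·mm)^-1.
#' @return list of class `extinction_table` with elements `matrix`,
#'   `inverse`, `wavelengths`, `chromophores`.
#' @export
extinction_table <- function(matrix = NULL) {
  if (is.null(matrix)) {
    matrix <- rbind(`760` = c(HbO = 1.349e-4, HbR = 3.566e-4),
                    `830` = c(HbO = 2.243e-4, HbR = 1.596e-4))
  }
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(2, 2)) || !all(is.finite(matrix))) {
    stopf("extinction matrix must be finite 2x2")
  }
  if (abs(det(matrix)) < .Machine$double.eps * max(abs(matrix))^2) {
    stopf("extinction matrix is singular; HbO/HbR cannot be separated")
  }
  structure(list(matrix = matrix, inverse = solve(matrix),
                 wavelengths = c(760, 830), chromophores = c("HbO", "HbR")),
            class = "extinction_table")
}

#' Low-pass filter specification
#'
#' @param cutoff cutoff frequency, Hz (must satisfy `0 < cutoff < fs/2` when
#'   applied).
#' @param order Butterworth order.
#' @param mode `"causal"` (single forward pass; usable online, introduces
#'   group delay) or `"acausal"` (forward-backward pass, zero net phase
#'   shift; needs the whole recording). Offline analyses default to acausal
#'   0.15 Hz; the decoding branch uses causal 0.12 Hz, a cutoff corrected
#'   for the halved -3 dB point of the single-pass filter relative to the
#'   two-pass one.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff, order = 3, mode = c("causal", "acausal")) {
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  if (order < 1) stopf("order must be >= 1")
  structure(list(cutoff = cutoff, order = order, mode = mode),
            class = "filter_spec")
}

#' Butterworth low-pass filtering
#'
#' Applies the filter of `spec` to one series or to every row of a matrix.
#' Causal mode is a single forward pass (the filter state is initialised at
#' the first sample's level, so a constant input passes through unchanged);
#' acausal mode is a forward-backward pass with zero net phase shift. DC
#' gain is 1 in both modes.
#'
#' @param series numeric vector, or matrix with series in rows.
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return filtered data, same shape as the input.
#' @export
lowpass <- function(series, spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2) {
    stopf("cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
          spec$cutoff, fs / 2)
  }
  if (is.matrix(series)) {
    return(t(apply(series, 1, lowpass, spec = spec, fs = fs)))
  }
  if (length(series) <= 3 * spec$order) {
    stopf("series too short (%d samples) for order-%d filtering",
          length(series), spec$order)
  }
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  if (spec$mode == "causal") {
    # remove the level before filtering so the start-up transient decays
    # from 0, not from the signal's DC offset
    x0 <- series[1]
    as.numeric(signal::filter(bf, series - x0)) + x0
  } else {
    x0 <- series[1]
    as.numeric(signal::filtfilt(bf, series - x0)) + x0
  }
}

#' Cut a continuous multi-channel recording into trials
#'
#' Extracts, for every event, the window from 6 s before movement onset
#' (MO) to 25 s after movement end (ME). All trials are kept — no
#' rejection — and all must have equal duration so the result is a dense
#' trials x channels x samples array. Sample counts use round-half-away-
#' from-zero, so a window of `w` seconds yields `round(w * fs) + 1`
#' samples.
#'
#' @param series channels x time numeric matrix (continuous recording).
#' @param events data frame with `onset` and `duration` (s); any other
#'   columns (e.g. `direction`) are carried through as labels.
#' @param fs sampling rate, Hz.
#' @param pre seconds before MO (default 6).
#' @param post seconds after ME (default 25).
#' @return list of class `epoch_set`: `data` (trials x channels x samples),
#'   `time` (s relative to MO), `labels` (the events' `direction`, if
#'   present), `events`, `fs`.
#' @export
epoch <- function(series, events, fs, pre = 6, post = 25) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  ntr <- nrow(events)
  if (ntr == 0) {
    return(structure(list(data = array(numeric(0), c(0, nrow(series), 0)),
                          time = numeric(0), labels = character(0),
                          events = events, fs = fs),
                     class = "epoch_set"))
  }
  if (length(unique(events$duration)) > 1) {
    stopf("all trials must share one movement duration to epoch uniformly")
  }
  dur <- events$duration[1]
  npre <- round_half_away(pre * fs)
  nlen <- round_half_away((pre + dur + post) * fs) + 1
  nt <- ncol(series)
  data <- array(NA_real_, c(ntr, nrow(series), nlen))
  for (i in seq_len(ntr)) {
    i0 <- floor(events$onset[i] * fs) + 1   # sample at/just before MO
    a <- i0 - npre
    b <- a + nlen - 1
    if (a < 1 || b > nt) {
      stopf("trial %d window [%d, %d] exceeds the recording (1..%d samples)",
            i, a, b, nt)
    }
    data[i, , ] <- series[, a:b]
  }
  structure(list(
    data = data,
    time = (seq_len(nlen) - 1 - npre) / fs,
    labels = if (!is.null(events$direction)) events$direction else NULL,
    events = events, fs = fs
  ), class = "epoch_set")
}

#' Convert epoched intensities to hemoglobin concentration changes
#'
#' Modified Beer-Lambert conversion, per trial and channel: each
#' wavelength's intensity is divided by its baseline (the mean over the
#' second preceding MO), the negative natural logarithm gives the
#' attenuation change, and the inverse extinction matrix maps the two
#' wavelengths' attenuations to ΔHbO / ΔHbR in µM·mm (no pathlength
#' division).
#'
#' Channels whose intensity ratio is non-positive anywhere (so the
#' logarithm would be complex) on any trial are flagged invalid rather than
#' dropped — the flag is the first step of channel selection.
#'
#' @param ep760,ep830 `epoch_set`s of intensities at 760 and 830 nm
#'   (identical trials/channels/time).
#' @param ext an [extinction_table()].
#' @param baseline `c(lo, hi)` window in s relative to MO, closed-open
#'   (default `[-1, 0)`).
#' @return list of class `conc_epochs`: `hbo`, `hbr` (trials x channels x
#'   samples, µM·mm), `valid_channel` (logical), `time`, `labels`, `fs`,
#'   `baseline`.
#' @export
to_concentration <- function(ep760, ep830, ext = extinction_table(),
                             baseline = c(-1, 0)) {
  stopifnot(inherits(ep760, "epoch_set"), inherits(ep830, "epoch_set"))
  if (!identical(dim(ep760$data), dim(ep830$data))) {
    stopf("the two wavelengths' epoch sets differ in shape")
  }
  dm <- dim(ep760$data)
  ntr <- dm[1]; nch <- dm[2]; nlen <- dm[3]
  tt <- ep760$time
  bsel <- tt >= baseline[1] & tt < baseline[2]
  if (!any(bsel)) stopf("baseline window [%g, %g) contains no samples",
                        baseline[1], baseline[2])
  valid <- rep(TRUE, nch)
  hbo <- array(NA_real_, dm)
  hbr <- array(NA_real_, dm)
  inv <- ext$inverse
  for (w in 1:2) {
    ep <- if (w == 1) ep760 else ep830
    # baseline per trial x channel: mean over the second before MO
    base <- apply(ep$data[, , bsel, drop = FALSE], c(1, 2), mean)
    bad_base <- apply(base <= 0, 2, any)
    ratio <- ep$data / as.vector(base)     # recycles trials x channels
    bad_ratio <- apply(ratio <= 0, 2, any)
    valid <- valid & !(bad_base | bad_ratio)
    dA <- -log(pmax(ratio, .Machine$double.xmin))
    hbo <- if (w == 1) inv[1, 1] * dA else hbo + inv[1, 2] * dA
    hbr <- if (w == 1) inv[2, 1] * dA else hbr + inv[2, 2] * dA
  }
  structure(list(hbo = hbo, hbr = hbr, valid_channel = valid,
                 time = tt, labels = ep760$labels, fs = ep760$fs,
                 baseline = baseline),
            class = "conc_epochs")
}

#' Two-step channel selection
#'
#' Step 1 keeps channels whose concentration conversion produced only real
#' values on every trial (`valid_channel`); step 2 keeps those with
#' source-detector distance inside `[lo, hi]` cm. The default window 2.5 to
#' 5.2 cm selects the cortex-penetrating long-distance channels; `lo = 0,
#' hi = 2` gives the scalp-only short-distance control set.
#'
#' @param conc a `conc_epochs`.
#' @param channels the layout's channel table (rows aligned with the
#'   concentration arrays' channel dimension).
#' @param lo,hi distance window, cm.
#' @param region optional region tag to restrict to (e.g. `"contra_SM"`).
#' @return integer channel indices, in ascending order.
#' @export
select_channels <- function(conc, channels, lo = 2.5, hi = 5.2,
                            region = NULL) {
  stopifnot(inherits(conc, "conc_epochs"))
  keep <- conc$valid_channel &
    channels$distance >= lo & channels$distance <= hi
  if (!is.null(region)) keep <- keep & channels$region == region
  idx <- which(keep)
  if (length(idx) == 0) warnf("channel selection [%g, %g] cm is empty", lo, hi)
  idx
}

#' Full fNIRS preprocessing of one session
#'
#' Convenience wrapper running the pipeline in its fixed order: low-pass
#' filter the continuous intensities (both wavelengths), cut into trials,
#' convert to concentration changes. Filtering precedes epoching because
#' the filter needs the continuous signal; converting before filtering is
#' not equivalent.
#'
#' @param session a `nirs_session` (or any list with `intensity`, `events`,
#'   `fs`).
#' @param spec a [filter_spec()]; default causal 0.12 Hz as used for
#'   decoding. Use `filter_spec(0.15, mode = "acausal")` for offline maps.
#' @param ext an [extinction_table()].
#' @param pre,post epoch window, s (see [epoch()]).
#' @return a `conc_epochs`.
#' @export
preprocess_session <- function(session, spec = filter_spec(0.12),
                               ext = extinction_table(), pre = 6, post = 25) {
  f760 <- lowpass(session$intensity$w760, spec, session$fs)
  f830 <- lowpass(session$intensity$w830, spec, session$fs)
  ep760 <- epoch(f760, session$events, session$fs, pre, post)
  ep830 <- epoch(f830, session$events, session$fs, pre, post)
  to_concentration(ep760, ep830, ext)
}
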