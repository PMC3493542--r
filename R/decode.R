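#' Repeated stratified cross-validated decoding accuracy
#'
#' Decoding accuracy (DA) is the percentage of correctly classified
#' held-out trials. Each repeat draws fresh label-stratified folds; within
#' a repeat the correct predictions are pooled over folds, and the reported
#' DA is the mean over repeats. Training and test sets are mutually
#' exclusive in every split, and any hyperparameter selection
#' (`lambda = "auto"`) runs nested inside the training folds only.
#'
#' @param features trials x features matrix.
#' @param labels class labels.
#' @param folds number of folds (>= 2, <= trials).
#' @param repeats number of repeated cross-validations (5-10 is typical).
#' @param lambda shrinkage passed to [rlda()] (`"auto"` or fixed).
#' @param seed optional seed for the fold draws.
#' @return list of class `cv_da`: `da` (%), `per_repeat` (%), `folds`,
#'   `repeats`, `n_trials`.
#' @export
cross_validated_da <- function(features, labels, folds = 10, repeats = 10,
                               lambda = "auto", seed = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (n < folds) stopf("%d trials cannot fill %d folds", n, folds)
  with_seed(seed, {
    per_repeat <- vapply(seq_len(repeats), function(r) {
      100 * cv_correct(features, labels, folds, lambda) / n
    }, numeric(1))
    structure(list(da = mean(per_repeat), per_repeat = per_repeat,
                   folds = folds, repeats = repeats, n_trials = n),
              class = "cv_da")
  })
}

# one repeat: pooled correct count over a fresh stratified fold draw
cv_correct <- function(features, labels, folds, lambda) {
  lev <- sort(unique(labels))
  fid <- stratified_folds(labels, folds)
  correct <- 0L
  for (f in sort(unique(fid))) {
    tr <- fid != f
    if (length(unique(labels[tr])) < length(lev)) {
      stopf("a class is absent from a training fold; reduce folds")
    }
    lam <- lambda
    if (identical(lambda, "auto")) {
      lam <- select_lambda(features[tr, , drop = FALSE], labels[tr],
                           grid = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                           inner_folds = 5)
    }
    fit <- finish_rlda(rlda_core(features[tr, , drop = FALSE], labels[tr], lev),
                       lam)
    pred <- predict(fit, features[!tr, , drop = FALSE])
    correct <- correct + sum(pred == labels[!tr])
  }
  correct
}

#' Time-resolved decoding of movement direction from concentration epochs
#'
#' Runs an independent repeated cross-validation at every epoch sample,
#' using as features the per-channel signal amplitude at that sample (HbO,
#' HbR, or both concatenated), optionally stacked over a sliding window of
#' consecutive samples. Returns the full DA(t) curve with its dispersion
#' over repeats and the exact binomial significance threshold.
#'
#' @param conc a `conc_epochs`.
#' @param channel_idx channel indices used as features (non-empty).
#' @param chromophore `"hbo"`, `"hbr"` or `"both"` (concatenated, doubling
#'   the feature dimension).
#' @param window number of consecutive samples per feature vector (1 =
#'   single time point); windows reaching past the epoch are truncated with
#'   a warning.
#' @param folds,repeats,lambda,seed see [cross_validated_da()]. The default
#'   fixed `lambda` keeps the hundreds of per-sample CVs tractable;
#'   `"auto"` enables nested selection.
#' @param alpha significance level of the chance threshold.
#' @return a `da_curve` (see [da_curve()]).
#' @export
time_resolved_da <- function(conc, channel_idx,
                             chromophore = c("hbo", "hbr", "both"),
                             window = 1, folds = 10, repeats = 5,
                             lambda = 0.25, seed = NULL, alpha = 0.001) {
  chromophore <- match.arg(chromophore)
  if (length(channel_idx) == 0) stopf("channel set is empty")
  arr <- switch(chromophore,
    hbo = conc$hbo[, channel_idx, , drop = FALSE],
    hbr = conc$hbr[, channel_idx, , drop = FALSE],
    both = {
      a <- conc$hbo[, channel_idx, , drop = FALSE]
      b <- conc$hbr[, channel_idx, , drop = FALSE]
      ab <- array(NA_real_, dim(a) + c(0, dim(b)[2], 0))
      ab[, seq_len(dim(a)[2]), ] <- a
      ab[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
      ab
    })
  decode_array(arr, conc$labels, conc$time, window = window, folds = folds,
               repeats = repeats, lambda = lambda, seed = seed, alpha = alpha)
}

# shared time-resolved decoding engine over a trials x features x samples
# array (used by the fNIRS and head-tracking branches alike)
decode_array <- function(arr, labels, time, window = 1, folds = 10,
                         repeats = 5, lambda = 0.25, seed = NULL,
                         alpha = 0.001) {
  dm <- dim(arr)
  ntr <- dm[1]; nfeat <- dm[2]; nlen <- dm[3]
  if (window > nlen) {
    warnf("sliding window (%d samples) longer than the epoch; truncated",
          window)
    window <- nlen
  }
  t_classes <- length(unique(labels))
  with_seed(seed, {
    da <- sem <- numeric(nlen)
    for (s in seq_len(nlen)) {
      hi <- min(s + window - 1, nlen)
      feat <- arr[, , s:hi, drop = FALSE]
      dim(feat) <- c(ntr, nfeat * (hi - s + 1))
      per_rep <- vapply(seq_len(repeats), function(r) {
        100 * cv_correct(feat, labels, folds, lambda) / ntr
      }, numeric(1))
      da[s] <- mean(per_rep)
      sem[s] <- stats::sd(per_rep) / sqrt(repeats)
    }
    da_curve(time = time, da = da, sem = sem, n_trials = ntr,
             t_classes = t_classes, alpha = alpha)
  })
}

#' Construct a decoding-accuracy curve object
#'
#' @param time time axis, s relative to movement onset.
#' @param da decoding accuracy, percent.
#' @param sem dispersion of `da` (over repeats or subjects).
#' @param n_trials number of decoded trials behind each DA value.
#' @param t_classes number of classes (chance level = 100 / t_classes).
#' @param alpha level of the binomial significance threshold.
#' @return list of class `da_curve` with the above fields plus `chance`
#'   and `threshold` (the significance level in percent, see
#'   [significance_level()]).
#' @export
da_curve <- function(time, da, sem = NULL, n_trials, t_classes = 2,
                     alpha = 0.001) {
  stopifnot(length(time) == length(da), all(da >= 0), all(da <= 100))
  structure(list(time = time, da = da, sem = sem, n_trials = n_trials,
                 t_classes = t_classes, alpha = alpha,
                 chance = 100 / t_classes,
                 threshold = significance_level(t_classes, n_trials, alpha)),
            class = "da_curve")
}

#' @export
print.da_curve <- function(x, ...) {
  cat(sprintf(
    "<da_curve> %d time points, %d trials, %d classes (chance %.1f%%)\n",
    length(x$time), x$n_trials, x$t_classes, x$chance))
  cat(sprintf("  max DA %.1f%% at %.1f s; significance level %.1f%% (p < %g)\n",
              max(x$da), x$time[which.max(x$da)], x$threshold, x$alpha))
  invisible(x)
}

#' @export
plot.da_curve <- function(x, movement_end = NULL, ...) {
  graphics::plot(x$time, x$da, type = "l", lwd = 2, ylim = c(0, 100),
                 xlab = "time relative to movement onset (s)",
                 ylab = "decoding accuracy (%)", ...)
  if (!is.null(x$sem)) {
    graphics::polygon(c(x$time, rev(x$time)),
                      c(x$da + x$sem, rev(x$da - x$sem)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(x$time, x$da, lwd = 2)
  }
  graphics::abline(h = x$chance, col = "black")
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(v = 0, col = "grey30")
  if (!is.null(movement_end)) graphics::abline(v = movement_end, col = "grey30")
  invisible(x)
}

#' Exact binomial tail probability of guessing performance
#'
#' Probability of predicting the correct one of `t` equiprobable targets at
#' least `k` times out of `n` by chance:
#' `sum_{j=k..n} C(n, j) (1/t)^j (1 - 1/t)^(n-j)`, evaluated through the
#' binomial distribution function, which is numerically stable for `n`
#' well beyond 10^4.
#'
#' @param t number of targets (>= 2).
#' @param n number of decoded trials.
#' @param k number of correct predictions, `0 <= k <= n`.
#' @return the tail probability; 1 for `k = 0`.
#' @export
binomial_p <- function(t, n, k) {
  if (t < 2 || n < 1 || any(k < 0) || any(k > n)) {
    stopf("invalid binomial arguments t=%s n=%s k=%s", t, n,
          paste(range(k), collapse = ".."))
  }
  stats::pbinom(k - 1, n, 1 / t, lower.tail = FALSE)
}

#' Significance level of a decoding accuracy
#'
#' The smallest number of correct trials `k` whose chance tail probability
#' does not exceed `alpha`, expressed as a decoding accuracy
#' `l = 100 * k / n` (%). Accuracies above `l` are significant at `alpha`.
#' If even `k = n` is not significant (tiny `n`), 100 is returned, which no
#' accuracy exceeds.
#'
#' @param t number of targets.
#' @param n number of decoded trials.
#' @param alpha level, `0 < alpha <= 1`.
#' @return threshold `l` in percent.
#' @export
significance_level <- function(t, n, alpha = 0.001) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  p <- binomial_p(t, n, 0:n)
  k <- which(p <= alpha)
  if (length(k) == 0) return(100)
  100 * (k[1] - 1) / n
}

#' Peak decoding accuracy of a smoothed DA curve
#'
#' Low-pass filters the DA(t) series (acausal 3rd-order Butterworth,
#' default 0.5 Hz) to suppress sample-to-sample fluctuation, then takes the
#' maximum inside the analysis window (default 5-20 s after movement
#' onset). The binomial p-value uses the implied correct-trial count
#' `k = floor(DA/100 * n)` (rounding down: conservative).
#'
#' @param curve a `da_curve`.
#' @param fs sampling rate of the curve, Hz.
#' @param smooth_cutoff low-pass cutoff for the DA series, Hz.
#' @param window `c(lo, hi)` in s after movement onset.
#' @param alpha significance level.
#' @return list: `da` (%), `time` (s), `p`, `significant`, `k`.
#' @export
max_da <- function(curve, fs, smooth_cutoff = 0.5, window = c(5, 20),
                   alpha = 0.05) {
  stopifnot(inherits(curve, "da_curve"))
  sel <- curve$time >= window[1] & curve$time <= window[2]
  if (!any(sel)) stopf("window [%g, %g] s lies outside the curve",
                       window[1], window[2])
  sm <- lowpass(curve$da, filter_spec(smooth_cutoff, mode = "acausal"), fs)
  i <- which(sel)[which.max(sm[sel])]
  k <- floor(sm[i] / 100 * curve$n_trials)
  p <- binomial_p(curve$t_classes, curve$n_trials, k)
  list(da = sm[i], time = curve$time[i], p = p, significant = p < alpha,
       k = k)
}

#' Per-subject peak-DA table with FDR correction
#'
#' Applies [max_da()] to each subject's curve and flags significance after
#' Benjamini-Hochberg correction across subjects.
#'
#' @param curves list of `da_curve`s, one per subject.
#' @param fs curve sampling rate, Hz.
#' @param q FDR level.
#' @param ... passed to [max_da()].
#' @return data frame: subject, da, time, p, fdr_significant.
#' @export
max_da_table <- function(curves, fs, q = 0.05, ...) {
  rows <- lapply(curves, max_da, fs = fs, ...)
  out <- data.frame(
    subject = seq_along(curves),
    da = vapply(rows, `[[`, numeric(1), "da"),
    time = vapply(rows, `[[`, numeric(1), "time"),
    p = vapply(rows, `[[`, numeric(1), "p")
  )
  out$fdr_significant <- fdr_correct(out$p, q)
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical rejection flags.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Decoding accuracy versus number of channels
#'
#' Evaluates DA at one time point for channel subsets of increasing size,
#' either averaging over random subsets or growing the set greedily from
#' the channels with the highest single-channel DA ("best channels
#' first"; the single-channel ranking is computed once, by default with a
#' ten-times 10-fold CV).
#'
#' @param conc a `conc_epochs`.
#' @param pool channel indices to draw from.
#' @param time_point epoch time (s after MO) at which to decode.
#' @param sizes subset sizes (sizes above the pool are clipped, with a
#'   warning).
#' @param mode `"random"` or `"best_first"`.
#' @param reps random subsets per size (random mode).
#' @param folds,repeats,lambda,seed CV settings ([cross_validated_da()]).
#' @param rank_repeats repeats of the single-channel ranking CV.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return data frame: `size`, `da` (mean over reps for random mode), and
#'   for `best_first` the attribute `"ranking"` (channel indices by rank).
#' @export
subset_analysis <- function(conc, pool, time_point,
                            sizes = seq_along(pool),
                            mode = c("random", "best_first"), reps = 35,
                            folds = 10, repeats = 5, lambda = 0.25,
                            seed = NULL, rank_repeats = 10,
                            chromophore = c("hbo", "hbr")) {
  mode <- match.arg(mode)
  chromophore <- match.arg(chromophore)
  if (length(pool) == 0) stopf("channel pool is empty")
  s_idx <- which.min(abs(conc$time - time_point))
  if (abs(conc$time[s_idx] - time_point) > 1 / conc$fs) {
    stopf("time point %g s lies outside the epoch", time_point)
  }
  if (any(sizes > length(pool))) {
    warnf("subset sizes above the pool size %d were clipped", length(pool))
    sizes <- unique(pmin(sizes, length(pool)))
  }
  X <- conc[[chromophore]][, pool, s_idx, drop = FALSE]
  dim(X) <- dim(X)[1:2]
  labs <- conc$labels
  with_seed(seed, {
    da_of <- function(cols) {
      mean(vapply(seq_len(repeats), function(r) {
        100 * cv_correct(X[, cols, drop = FALSE], labs, folds, lambda) /
          nrow(X)
      }, numeric(1)))
    }
    if (mode == "random") {
      da <- vapply(sizes, function(sz) {
        mean(vapply(seq_len(reps), function(r) {
          da_of(sample(length(pool), sz))
        }, numeric(1)))
      }, numeric(1))
      data.frame(size = sizes, da = da)
    } else {
      single <- vapply(seq_along(pool), function(j) {
        mean(vapply(seq_len(rank_repeats), function(r) {
          100 * cv_correct(X[, j, drop = FALSE], labs, folds, lambda) /
            nrow(X)
        }, numeric(1)))
      }, numeric(1))
      ranking <- order(single, decreasing = TRUE)
      da <- vapply(sizes, function(sz) da_of(ranking[seq_len(sz)]),
                   numeric(1))
      structure(data.frame(size = sizes, da = da),
                ranking = pool[ranking], single_da = single[ranking])
    }
  })
}

#' Source-detector-distance profile of the best-decoding channels
#'
#' Histograms the source-detector distances of the `top_k` channels with
#' the highest single-channel DA, and normalises each bin by the total
#' number of recorded channels at that distance, yielding the likelihood
#' that a channel of a given distance ranks among the best. Bins without
#' any recorded channel are reported as NA, not 0/0.
#'
#' @param single_da per-channel single-channel DA (aligned with `pool`).
#' @param pool channel indices the DAs refer to.
#' @param channels the layout channel table.
#' @param top_k number of top channels (clipped to the pool with a
#'   warning).
#' @param breaks histogram breaks over distance (cm).
#' @return data frame: `bin_lo`, `bin_hi`, `count` (top-k channels in
#'   bin), `total` (recorded channels in bin), `likelihood`.
#' @export
distance_profile <- function(single_da, pool, channels, top_k = 10,
                             breaks = seq(0, 8, by = 0.5)) {
  if (length(single_da) != length(pool)) {
    stopf("single_da and pool lengths differ")
  }
  if (top_k > length(pool)) {
    warnf("top_k = %d exceeds the %d available channels; using all",
          top_k, length(pool))
    top_k <- length(pool)
  }
  top <- pool[order(single_da, decreasing = TRUE)[seq_len(top_k)]]
  d_top <- channels$distance[top]
  d_all <- channels$distance[pool]
  cnt <- graphics::hist(d_top, breaks = breaks, plot = FALSE)$counts
  tot <- graphics::hist(d_all, breaks = breaks, plot = FALSE)$counts
  data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    count = cnt, total = tot,
    likelihood = ifelse(tot > 0, cnt / tot, NA_real_)
  )
}
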