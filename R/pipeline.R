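#' Run the full analysis pipeline on simulated subjects
#'
#' Orchestrates simulate -> preprocess -> map -> decode -> head-track
#' control for a cohort of synthetic subjects and assembles the standard
#' report: per-subject time-resolved DA curves (contralateral long-distance
#' channels), the short-distance and ipsilateral control curves, the
#' head-tracking DA curve, per-channel SNR maps, a per-subject peak-DA
#' table with FDR flags, and the subject-average curve with its pooled
#' binomial significance threshold. Every random draw derives from `seed`,
#' so a run is reproducible from its configuration alone.
#'
#' @param n_subjects number of simulated subjects.
#' @param sim a [sim_config()] template; each subject uses
#'   `seed + subject index` as simulation seed (per-subject HRF/noise
#'   realisations differ, the design does not).
#' @param layout a `nirs_layout`.
#' @param spec_causal causal filter for the decoding branch.
#' @param spec_acausal acausal filter for maps.
#' @param folds,repeats,lambda CV settings for time-resolved decoding.
#' @param chromophore feature signal (`"hbo"`, `"hbr"`, `"both"`).
#' @param window sliding-window length in samples (1 = single time point).
#' @param alpha significance level for DA thresholds.
#' @param analyses subset of `c("decode", "map", "track", "controls")`;
#'   omitted analyses are skipped and absent from the report.
#' @param seed master seed.
#' @param out_dir optional directory; when given, curve tables (TSV), the
#'   peak-DA table, a JSON summary and a manifest are written there.
#' @return list of class `nirs_report`: `subjects` (per-subject results),
#'   `table` (peak-DA data frame), `group` (average curve as `da_curve`
#'   with trials pooled across subjects for its threshold), `manifest`.
#' @export
run_pipeline <- function(n_subjects = 2, sim = sim_config(),
                         layout = default_montage(),
                         spec_causal = filter_spec(0.12),
                         spec_acausal = filter_spec(0.15, mode = "acausal"),
                         folds = 10, repeats = 5, lambda = 0.25,
                         chromophore = "hbo", window = 1, alpha = 0.001,
                         analyses = c("decode", "map", "track", "controls"),
                         seed = 1, out_dir = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  subjects <- vector("list", n_subjects)
  ch <- layout$channels
  for (i in seq_len(n_subjects)) {
    sim_i <- sim
    sim_i$seed <- seed + i
    ses <- generate_session(sim_i, layout)
    conc <- preprocess_session(ses, spec_causal)
    contra <- select_channels(conc, ch, 2.5, 5.2, region = "contra_SM")
    res <- list(n_contra = length(contra))
    if ("decode" %in% analyses) {
      res$curve <- time_resolved_da(conc, contra, chromophore,
                                    window = window, folds = folds,
                                    repeats = repeats, lambda = lambda,
                                    seed = seed * 100 + i, alpha = alpha)
    }
    if ("controls" %in% analyses) {
      short <- select_channels(conc, ch, 0, 2, region = "contra_SM")
      short <- short[ch$distance[short] > 0]
      ipsi <- which(conc$valid_channel & ch$distance > 0 &
                      ch$distance < 5.2 &
                      ch$region %in% c("ipsi_SM", "prefrontal", "occipital"))
      res$curve_short <- time_resolved_da(conc, short, chromophore,
                                          folds = folds, repeats = repeats,
                                          lambda = lambda,
                                          seed = seed * 100 + i + 50000,
                                          alpha = alpha)
      res$curve_ipsi <- time_resolved_da(conc, ipsi, chromophore,
                                         folds = folds, repeats = repeats,
                                         lambda = lambda,
                                         seed = seed * 100 + i + 90000,
                                         alpha = alpha)
    }
    if ("map" %in% analyses) {
      conc_ac <- preprocess_session(ses, spec_acausal)
      contra_ac <- select_channels(conc_ac, ch, 2.5, 5.2,
                                   region = "contra_SM")
      res$snr_map <- snr_map(conc_ac, contra_ac, layout,
                             movement_end = sim$movement_duration)
      res$truth_contrast <- ses$truth$contrast
    }
    if ("track" %in% analyses) {
      res$curve_track <- decode_track(track_pipeline(ses, spec_causal),
                                      folds = folds, repeats = repeats,
                                      lambda = lambda,
                                      seed = seed * 100 + i + 130000,
                                      alpha = alpha)
    }
    subjects[[i]] <- res
  }
  report <- structure(list(subjects = subjects), class = "nirs_report")
  if ("decode" %in% analyses) {
    curves <- lapply(subjects, `[[`, "curve")
    report$table <- max_da_table(curves, fs = sim$fs_nirs)
    avg <- rowMeans(vapply(curves, `[[`, numeric(length(curves[[1]]$da)),
                           "da"))
    sem <- apply(vapply(curves, `[[`, numeric(length(curves[[1]]$da)),
                        "da"), 1, stats::sd) / sqrt(n_subjects)
    # group threshold from trials pooled across subjects
    report$group <- da_curve(curves[[1]]$time, avg, sem,
                             n_trials = sum(vapply(curves, `[[`,
                                                   numeric(1), "n_trials")),
                             t_classes = curves[[1]]$t_classes,
                             alpha = alpha)
  }
  report$manifest <- list(
    package = "nirsdirect",
    version = as.character(utils::packageVersion("nirsdirect")),
    seed = seed, n_subjects = n_subjects, analyses = analyses,
    folds = folds, repeats = repeats, lambda = lambda,
    chromophore = chromophore, window = window, alpha = alpha,
    sim = unclass(sim)
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.nirs_report <- function(x, ...) {
  cat(sprintf("<nirs_report> %d subjects; analyses: %s\n",
              length(x$subjects),
              paste(x$manifest$analyses, collapse = ", ")))
  if (!is.null(x$table)) {
    cat("  peak DA (5-20 s, smoothed):\n")
    print(x$table, row.names = FALSE)
  }
  if (!is.null(x$group)) {
    cat(sprintf("  group max DA %.1f%% at %.1f s (threshold %.1f%%)\n",
                max(x$group$da), x$group$time[which.max(x$group$da)],
                x$group$threshold))
  }
  invisible(x)
}

# write the report bundle as TSV/JSON files
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$table)) wr(report$table, "peak_da.tsv")
  if (!is.null(report$group)) {
    wr(data.frame(time = report$group$time, da = report$group$da,
                  sem = report$group$sem), "group_da_curve.tsv")
  }
  for (i in seq_along(report$subjects)) {
    s <- report$subjects[[i]]
    for (nm in intersect(names(s), c("curve", "curve_short", "curve_ipsi",
                                     "curve_track"))) {
      wr(data.frame(time = s[[nm]]$time, da = s[[nm]]$da, sem = s[[nm]]$sem),
         sprintf("subject%02d_%s.tsv", i, sub("curve_?", "da_", nm)))
    }
    if (!is.null(s$snr_map)) {
      wr(data.frame(channel = names(s$snr_map$snr), snr = s$snr_map$snr),
         sprintf("subject%02d_snr.tsv", i))
    }
  }
  summary <- list(
    manifest = report$manifest,
    peak_da = report$table,
    group_max_da = if (!is.null(report$group)) max(report$group$da)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
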