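#' Trial-averaged response curves per direction
#'
#' Mean and standard error over trials of each direction, per channel and
#' time point, for one chromophore.
#'
#' @param conc a `conc_epochs`.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return list of class `direction_means`: `mean` and `sem`, each a named
#'   list (one per direction) of channels x time matrices; `time`;
#'   `n_trials` per direction.
#' @export
direction_means <- function(conc, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  x <- conc[[chromophore]]
  labs <- conc$labels
  dirs <- sort(unique(labs))
  out_m <- list(); out_s <- list(); ntr <- integer(0)
  for (d in dirs) {
    sel <- which(labs == d)
    if (length(sel) < 2) {
      stopf("direction %s has %d trial(s); >= 2 needed for a s.e.m.",
            d, length(sel))
    }
    xd <- x[sel, , , drop = FALSE]
    m <- apply(xd, c(2, 3), mean)
    s <- apply(xd, c(2, 3), stats::sd) / sqrt(length(sel))
    out_m[[d]] <- m; out_s[[d]] <- s; ntr[d] <- length(sel)
  }
  structure(list(mean = out_m, sem = out_s, time = conc$time,
                 n_trials = ntr, chromophore = chromophore),
            class = "direction_means")
}

#' Direction-contrast signal-to-noise ratio of one channel
#'
#' SNR = |difference of the two directions' trial means| divided by the
#' standard deviation of the mean-corrected trials pooled across both
#' directions (each trial has its own direction's mean subtracted; the
#' pooled set is treated as one sample, n-1 denominator). Computed per time
#' point, then aggregated over `time_sel` (by default the mean over
#' movement end +/- 1 s).
#'
#' @param conc a `conc_epochs` with exactly two label values.
#' @param channel channel index.
#' @param time_sel logical or integer selector into `conc$time`; default
#'   `NULL` means ME +/- 1 s where ME is inferred from the events carried
#'   by `movement_end`.
#' @param movement_end movement end time, s after MO (default 10).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return a single non-negative SNR value.
#' @export
snr <- function(conc, channel, time_sel = NULL, movement_end = 10,
                chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  labs <- conc$labels
  dirs <- sort(unique(labs))
  if (length(dirs) != 2) stopf("SNR contrast is defined for exactly 2 directions")
  if (is.null(time_sel)) {
    time_sel <- conc$time >= movement_end - 1 & conc$time <= movement_end + 1
  }
  x <- conc[[chromophore]][, channel, time_sel, drop = FALSE]
  dim(x) <- dim(x)[c(1, 3)]                      # trials x selected samples
  i1 <- labs == dirs[1]; i2 <- labs == dirs[2]
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[i2, , drop = FALSE])
  corrected <- x
  corrected[i1, ] <- sweep(x[i1, , drop = FALSE], 2, m1)
  corrected[i2, ] <- sweep(x[i2, , drop = FALSE], 2, m2)
  sds <- apply(corrected, 2, stats::sd)
  if (all(sds == 0)) {
    warnf("zero pooled standard deviation on channel %d; SNR reported as 0",
          channel)
    return(0)
  }
  mean(abs(m1 - m2) / sds)
}

#' Per-channel SNR map over a channel set
#'
#' @param conc a `conc_epochs`.
#' @param channel_idx channel indices to evaluate (typically the selected
#'   contralateral long-distance channels).
#' @param layout the session's `nirs_layout` (for 2D midpoints).
#' @param grid_n interpolation grid resolution per axis.
#' @param ... passed to [snr()].
#' @return list of class `snr_map`: `snr` (named by channel index),
#'   `midpoints` (2D), and `field` (interpolated grid, see
#'   [interpolate_map()]).
#' @export
snr_map <- function(conc, channel_idx, layout, grid_n = 60, ...) {
  vals <- vapply(channel_idx, function(k) snr(conc, k, ...), numeric(1))
  ch <- layout$channels
  pts <- if (is.null(ch$mu)) {
    matrix(NA_real_, length(channel_idx), 2)     # layout never projected
  } else {
    cbind(ch$mu[channel_idx], ch$mv[channel_idx])
  }
  field <- NULL
  ok <- stats::complete.cases(pts)
  if (sum(ok) >= 3) {
    field <- interpolate_map(pts[ok, , drop = FALSE], vals[ok], grid_n)
  }
  structure(list(snr = stats::setNames(vals, channel_idx),
                 midpoints = pts, field = field),
            class = "snr_map")
}

#' Piecewise-linear interpolation of channel values over the scalp patch
#'
#' Triangulates the channel midpoints (Delaunay, by exhaustive circumcircle
#' test — montage-scale point counts make this exact approach cheap) and
#' interpolates barycentrically within each triangle. The field is exact at
#' the data points and masked (NA) outside the convex hull; no
#' extrapolation.
#'
#' @param points n x 2 matrix of 2D positions (>= 3, not collinear).
#' @param values numeric vector of length n.
#' @param grid_n grid resolution per axis.
#' @return list with `x`, `y` (grid axes), `z` (grid_n x grid_n matrix,
#'   NA outside the hull), `triangles` (m x 3 vertex indices).
#' @export
interpolate_map <- function(points, values, grid_n = 60) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stopf("need >= 3 points to interpolate, got %d", n)
  tri <- delaunay_triangles(points)
  if (nrow(tri) == 0) stopf("points are collinear; no triangulation exists")
  gx <- seq(min(points[, 1]), max(points[, 1]), length.out = grid_n)
  gy <- seq(min(points[, 2]), max(points[, 2]), length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  grid <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  filled <- rep(FALSE, nrow(grid))
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    a <- points[v[1], ]; b <- points[v[2], ]; c <- points[v[3], ]
    den <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    todo <- which(!filled)
    if (length(todo) == 0) break
    w1 <- ((b[2] - c[2]) * (grid[todo, 1] - c[1]) +
             (c[1] - b[1]) * (grid[todo, 2] - c[2])) / den
    w2 <- ((c[2] - a[2]) * (grid[todo, 1] - c[1]) +
             (a[1] - c[1]) * (grid[todo, 2] - c[2])) / den
    w3 <- 1 - w1 - w2
    eps <- 1e-9
    inside <- w1 >= -eps & w2 >= -eps & w3 >= -eps
    hit <- todo[inside]
    z[hit] <- w1[inside] * values[v[1]] + w2[inside] * values[v[2]] +
      w3[inside] * values[v[3]]
    filled[hit] <- TRUE
  }
  list(x = gx, y = gy, z = z, triangles = tri)
}

# Delaunay triangulation by exhaustive circumcircle test: a triangle
# belongs to the triangulation iff its open circumdisc contains no other
# point. O(n^4) worst case; montages have tens of midpoints.
delaunay_triangles <- function(points) {
  n <- nrow(points)
  # collapse coincident points: only the first of a duplicate set is used
  key <- paste(signif(points[, 1], 10), signif(points[, 2], 10))
  uniq <- !duplicated(key)
  idx <- which(uniq)
  pts <- points[idx, , drop = FALSE]
  m <- nrow(pts)
  out <- list()
  if (m < 3) return(matrix(integer(0), 0, 3))
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next                       # degenerate (collinear)
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    dd <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2
    dd[c(i, j, k)] <- Inf
    if (all(dd >= r2 * (1 - 1e-9))) {
      out[[length(out) + 1]] <- idx[c(i, j, k)]
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

#' Average response of a cortical region
#'
#' Mean time course over all trials and all valid channels of one region
#' with source-detector distance below `max_dist` (used for the ipsilateral
#' sensorimotor, prefrontal and occipital summary insets next to the
#' contralateral map).
#'
#' @param conc a `conc_epochs`.
#' @param channels the layout channel table.
#' @param region region tag.
#' @param max_dist maximum source-detector distance, cm.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return numeric time course (length = samples).
#' @export
region_average <- function(conc, channels, region, max_dist = 5.2,
                           chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  keep <- which(channels$region == region & channels$distance < max_dist &
                  channels$distance > 0 & conc$valid_channel)
  if (length(keep) == 0) stopf("region %s has no valid channel below %g cm",
                               region, max_dist)
  x <- conc[[chromophore]][, keep, , drop = FALSE]
  apply(x, 3, mean)
}

#' @export
print.snr_map <- function(x, ...) {
  cat(sprintf("<snr_map> %d channels, SNR range [%.3f, %.3f]%s\n",
              length(x$snr), min(x$snr), max(x$snr),
              if (is.null(x$field)) "" else
                sprintf(", %dx%d interpolated field",
                        length(x$field$x), length(x$field$y))))
  invisible(x)
}

#' @export
plot.snr_map <- function(x, ...) {
  if (is.null(x$field)) stopf("no interpolated field to plot")
  graphics::image(x$field$x, x$field$y, x$field$z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "u (cm)", ylab = "v (cm)",
                  main = "Direction-contrast SNR", ...)
  graphics::points(x$midpoints, pch = 20, cex = 0.6)
  invisible(x)
}
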