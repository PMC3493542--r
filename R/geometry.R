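#' Construct an optode layout
#'
#' An optode layout describes the montage: every light source and detector on
#' the scalp, its 3D position in cm, its role, and the cortical region it
#' covers. Co-located optodes act as both source and detector (the fibre
#' bundle carries light in both directions), so they appear once with role
#' `"colocated"`.
#'
#' @param id character vector of unique optode identifiers.
#' @param role character vector, each one of `"source"`, `"detector"`,
#'   `"colocated"`.
#' @param position numeric matrix, one row per optode, columns x/y/z in cm.
#' @param region character vector, each one of `"contra_SM"`, `"ipsi_SM"`,
#'   `"prefrontal"`, `"occipital"` (sensorimotor cortex contralateral /
#'   ipsilateral to the moving hand, prefrontal, occipital).
#'
#' @return An object of class `nirs_layout`: a list with the optode table
#'   (data frame) and the enumerated channel table (see
#'   [enumerate_channels()]).
#' @export
#' @examples
#' lay <- nirs_layout(
#'   id = c("S1", "D1", "D2"),
#'   role = c("colocated", "detector", "detector"),
#'   position = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
#'   region = rep("contra_SM", 3)
#' )
#' lay$channels
nirs_layout <- function(id, role, position, region) {
  id <- as.character(id)
  role <- match.arg(role, c("source", "detector", "colocated"),
                    several.ok = TRUE)
  region <- match.arg(region, c("contra_SM", "ipsi_SM", "prefrontal",
                                "occipital"), several.ok = TRUE)
  position <- as.matrix(position)
  n <- length(id)
  if (anyDuplicated(id)) stopf("duplicate optode ids: %s",
                               paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(role) != n || nrow(position) != n || length(region) != n) {
    stopf("id, role, position rows and region must all have length %d", n)
  }
  if (ncol(position) != 3 || !all(is.finite(position))) {
    stopf("position must be an n x 3 matrix of finite coordinates (cm)")
  }
  optodes <- data.frame(id = id, role = role,
                        x = position[, 1], y = position[, 2], z = position[, 3],
                        region = region, stringsAsFactors = FALSE)
  layout <- structure(list(optodes = optodes, channels = NULL),
                      class = "nirs_layout")
  layout$channels <- enumerate_channels(layout)
  layout
}

#' @export
print.nirs_layout <- function(x, ...) {
  op <- x$optodes
  cat(sprintf("<nirs_layout> %d optodes (%d sources, %d detecting), %d channels\n",
              nrow(op), sum(op$role != "detector"), sum(op$role != "source"),
              nrow(x$channels)))
  cat("  regions:", paste(sprintf("%s=%d", names(table(op$region)),
                                  table(op$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all source-detector channels of a layout
#'
#' A channel is one (source, detecting optode) pair; light injected at the
#' source and measured at the detector samples the tissue between them. Every
#' optode with role `"source"` or `"colocated"` emits; every optode with role
#' `"detector"` or `"colocated"` detects. A co-located optode paired with
#' itself gives a zero-distance channel (kept here; distance-based selection
#' removes it later). The channel count therefore equals
#' n_sources x n_detecting_optodes.
#'
#' @param layout a `nirs_layout` (or a bare list with an `optodes` data
#'   frame).
#' @return data frame with one row per channel: `source_id`, `detector_id`,
#'   `distance` (cm, Euclidean), `region` (the common region tag if source
#'   and detector share one, else `"cross"`), and midpoint coordinates
#'   `mx`, `my`, `mz` (cm). 2D midpoints are added by [project_layout()].
#' @export
enumerate_channels <- function(layout) {
  op <- layout$optodes
  if (anyDuplicated(op$id)) stopf("duplicate optode ids")
  src <- op[op$role %in% c("source", "colocated"), , drop = FALSE]
  det <- op[op$role %in% c("detector", "colocated"), , drop = FALSE]
  if (nrow(src) == 0 || nrow(det) == 0) {
    return(data.frame(source_id = character(), detector_id = character(),
                      distance = numeric(), region = character(),
                      mx = numeric(), my = numeric(), mz = numeric(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(s = seq_len(nrow(src)), d = seq_len(nrow(det)))
  ps <- as.matrix(src[grid$s, c("x", "y", "z")])
  pd <- as.matrix(det[grid$d, c("x", "y", "z")])
  dist <- sqrt(rowSums((ps - pd)^2))
  mid <- (ps + pd) / 2
  reg_s <- src$region[grid$s]
  reg_d <- det$region[grid$d]
  data.frame(
    source_id = src$id[grid$s],
    detector_id = det$id[grid$d],
    distance = dist,
    region = ifelse(reg_s == reg_d, reg_s, "cross"),
    mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
    stringsAsFactors = FALSE
  )
}

#' Project 3D positions onto their least-squares best-fit plane
#'
#' Centers the coordinates and returns the scores on the two
#' largest-variance principal axes; this is the plane minimising the sum of
#' squared orthogonal distances. Used to flatten the (curved) scalp patch of
#' optodes into 2D map coordinates. The sign of each axis is fixed so that
#' the largest-magnitude loading is positive, making maps reproducible.
#'
#' @param positions numeric matrix n x 3 (cm), n >= 3, not collinear.
#' @return n x 2 matrix of plane coordinates (cm), rows matching the input
#'   order.
#' @export
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 2) # already flat
#' project_best_fit_plane(pts)
project_best_fit_plane <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3) stopf("need at least 3 points, got %d", nrow(positions))
  if (!all(is.finite(positions))) stopf("positions must be finite")
  ctr <- scale(positions, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  # rank check: collinear points have a single non-negligible singular value
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-8) {
    stopf("points are collinear or coincident: best-fit plane is not defined (rank < 2)")
  }
  v <- sv$v[, 1:2, drop = FALSE]
  # sign convention: largest-|loading| entry of each axis made positive
  for (j in 1:2) {
    k <- which.max(abs(v[, j]))
    if (v[k, j] < 0) v[, j] <- -v[, j]
  }
  scores <- ctr %*% v
  colnames(scores) <- c("u", "v")
  scores
}

#' Attach 2D map coordinates to a layout's channels
#'
#' Projects the positions of the optodes in one region (default the
#' contralateral sensorimotor patch) onto their best-fit plane and places
#' each within-region channel midway between its source and detector in the
#' projected plane.
#'
#' @param layout a `nirs_layout`.
#' @param region region whose optodes define the projection plane.
#' @return the layout with `channels$mu`, `channels$mv` filled (NA for
#'   channels outside `region`) and the per-optode plane coordinates stored
#'   in `layout$plane[[region]]`.
#' @export
project_layout <- function(layout, region = "contra_SM") {
  op <- layout$optodes
  sel <- op$region == region
  if (sum(sel) < 3) stopf("region %s has fewer than 3 optodes", region)
  uv <- project_best_fit_plane(as.matrix(op[sel, c("x", "y", "z")]))
  coords <- data.frame(id = op$id[sel], u = uv[, 1], v = uv[, 2],
                       stringsAsFactors = FALSE)
  ch <- layout$channels
  if (is.null(ch$mu)) { ch$mu <- NA_real_; ch$mv <- NA_real_ }
  in_reg <- ch$region == region
  iu <- match(ch$source_id, coords$id)
  id <- match(ch$detector_id, coords$id)
  ok <- in_reg & !is.na(iu) & !is.na(id)
  ch$mu[ok] <- (coords$u[iu[ok]] + coords$u[id[ok]]) / 2
  ch$mv[ok] <- (coords$v[iu[ok]] + coords$v[id[ok]]) / 2
  layout$channels <- ch
  layout$plane <- c(layout$plane, stats::setNames(list(coords), region))
  layout
}

#' Select channels by source-detector distance
#'
#' Penetration depth of near-infrared light grows with source-detector
#' separation: channels below ~2 cm sample mostly scalp ("short-distance"),
#' channels between 2.5 and 5.2 cm reach cortical tissue ("long-distance").
#' The interval is closed on both ends.
#'
#' @param channels channel data frame (from [enumerate_channels()]).
#' @param lo,hi distance window in cm, `lo <= hi`.
#' @return the subset of rows with `lo <= distance <= hi`, in input order.
#' @export
select_by_distance <- function(channels, lo = 2.5, hi = 5.2) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi) {
    stopf("need numeric lo <= hi, got lo=%s hi=%s", lo, hi)
  }
  channels[channels$distance >= lo & channels$distance <= hi, , drop = FALSE]
}

#' Write / read a layout as JSON
#'
#' The on-disk format is a JSON array of optode records
#' `{id, role, xyz (cm), region}`; validated on load by reconstructing the
#' layout through [nirs_layout()].
#'
#' @param layout a `nirs_layout`.
#' @param path file path.
#' @return `read_layout()` returns a `nirs_layout`; `write_layout()` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  op <- layout$optodes
  recs <- lapply(seq_len(nrow(op)), function(i) {
    list(id = op$id[i], role = op$role[i],
         xyz = c(op$x[i], op$y[i], op$z[i]), region = op$region[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(recs) == 0) stopf("layout file %s contains no optodes", path)
  pos <- t(vapply(recs, function(r) {
    xyz <- unlist(r$xyz)
    if (length(xyz) != 3) stopf("optode %s: xyz must have 3 coordinates", r$id)
    as.numeric(xyz)
  }, numeric(3)))
  nirs_layout(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    role = vapply(recs, function(r) as.character(r$role), character(1)),
    position = pos,
    region = vapply(recs, function(r) as.character(r$region), character(1))
  )
}
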