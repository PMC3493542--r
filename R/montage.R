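#' Default 32-optode montage
#'
#' Builds the packaged example montage: 32 optodes on a sphere of head-like
#' radius, of which 9 are co-located sources and 23 pure detectors, arranged
#' as a dense 21-optode patch (6 sources, 15 detectors) over the
#' sensorimotor cortex contralateral to the moving (right) hand, plus small
#' groups over ipsilateral sensorimotor (1 source, 4 detectors), prefrontal
#' (1 source, 2 detectors) and occipital (1 source, 2 detectors) areas.
#' All 32 optodes detect, so the layout enumerates 9 x 32 = 288
#' source-detector channels.
#'
#' The coordinates are a synthetic emulation of a typical montage of this
#' shape (grid spacing ~1.5 cm on a 9.25 cm sphere), not measured positions.
#'
#' @param radius head sphere radius in cm.
#' @param spacing grid spacing of the contralateral patch in cm.
#' @return a `nirs_layout` with 2D map coordinates attached for the
#'   contralateral patch (see [project_layout()]).
#' @export
#' @examples
#' m <- default_montage()
#' nrow(m$channels) # 288
default_montage <- function(radius = 9.25, spacing = 1.5) {
  # tangent-plane placement: point = R * normalize(c + (x e1 + y e2)/R)
  place <- function(center, e1, e2, xy) {
    center <- center / sqrt(sum(center^2))
    p <- t(apply(xy, 1, function(r) {
      v <- center + (r[1] * e1 + r[2] * e2) / radius
      radius * v / sqrt(sum(v^2))
    }))
    p
  }
  # contralateral (left hemisphere, right hand): around C3, 3 x 7 grid
  cc <- c(-sin(35 * pi / 180), 0, cos(35 * pi / 180))
  e1 <- c(0, 1, 0)                      # anterior-posterior
  e2c <- cross3(cc, e1)                 # medial-lateral in tangent plane
  gx <- (rep(1:7, times = 3) - 4) * spacing
  gy <- (rep(1:3, each = 7) - 2) * spacing
  contra_xy <- cbind(gx, gy)
  contra_pos <- place(cc, e1, e2c, contra_xy)
  # sources interleaved through the patch (cols 2,4,6 on rows 1 and 3)
  contra_src <- c(2, 4, 6, 16, 18, 20)
  contra_role <- ifelse(seq_len(21) %in% contra_src, "colocated", "detector")

  ci <- c(sin(35 * pi / 180), 0, cos(35 * pi / 180))   # ipsilateral SM
  e2i <- cross3(ci, e1)
  ipsi_xy <- cbind(c(0, -2.8, 2.8, 0, 0),
                   c(0, 0, 0, -2.8, 2.8))
  ipsi_pos <- place(ci, e1, e2i, ipsi_xy)
  ipsi_role <- c("colocated", rep("detector", 4))

  cp <- c(sin(20 * pi / 180) * 0.3, sin(60 * pi / 180), cos(60 * pi / 180))  # prefrontal, right of midline
  e2p <- cross3(cp / sqrt(sum(cp^2)), e1)
  pf_xy <- cbind(c(0, -2.8, 2.8), c(0, 0, 0))
  pf_pos <- place(cp, e1, e2p, pf_xy)
  pf_role <- c("colocated", "detector", "detector")

  co <- c(sin(15 * pi / 180) * 0.3, -sin(55 * pi / 180), cos(55 * pi / 180)) # occipital
  e2o <- cross3(co / sqrt(sum(co^2)), e1)
  oc_xy <- pf_xy
  oc_pos <- place(co, e1, e2o, oc_xy)
  oc_role <- pf_role

  pos <- rbind(contra_pos, ipsi_pos, pf_pos, oc_pos)
  role <- c(contra_role, ipsi_role, pf_role, oc_role)
  region <- c(rep("contra_SM", 21), rep("ipsi_SM", 5),
              rep("prefrontal", 3), rep("occipital", 3))
  ns <- cumsum(role %in% "colocated")
  id <- ifelse(role == "colocated",
               sprintf("S%d", ns),
               sprintf("D%d", cumsum(role == "detector")))
  lay <- nirs_layout(id = id, role = role, position = pos, region = region)
  project_layout(lay, "contra_SM")
}

# cross product of two 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
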