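# Minimum-area rotated rectangle of a point set: rotating calipers over
# the convex hull. For every hull edge, the hull is rotated so the edge is
# axis-aligned and the axis-aligned bounding box area recorded; the
# minimum-area orientation wins, ties broken by the smallest absolute
# angle to the x-axis so symmetric shapes give deterministic output.

#' Minimum-area enclosing rectangle of 2D points
#'
#' @param pts n x 2 matrix, n >= 3 with at least 3 non-collinear points.
#' @return List with `width`, `height` (side lengths along/across the
#'   chosen edge), `angle_deg`, `area` and the 4 x 2 `corners` matrix.
#' @export
min_area_rect <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  pts <- unique(pts)
  abort_if(nrow(pts) < 3, "need at least 3 distinct points")
  hull_idx <- grDevices::chull(pts)
  hull <- pts[hull_idx, , drop = FALSE]
  abort_if(nrow(hull) < 3, "points are collinear; no enclosing rectangle")

  edges <- diff(rbind(hull, hull[1, , drop = FALSE]))
  angles <- atan2(edges[, 2], edges[, 1]) %% (pi / 2)
  angles <- unique(round(angles, 12))
  best <- NULL
  for (th in angles) {
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    q <- hull %*% rot
    w <- diff(range(q[, 1])); h <- diff(range(q[, 2]))
    area <- w * h
    ang <- th * 180 / pi
    if (is.null(best) || area < best$area - 1e-9 ||
        (abs(area - best$area) <= 1e-9 &&
         abs(ang) < abs(best$angle_deg))) {
      lo <- c(min(q[, 1]), min(q[, 2])); hi <- c(max(q[, 1]), max(q[, 2]))
      corners <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]),
                       c(hi[1], hi[2]), c(lo[1], hi[2])) %*% t(rot)
      best <- list(width = w, height = h, angle_deg = ang,
                   area = area, corners = corners)
    }
  }
  best
}
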