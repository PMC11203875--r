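# Shared low-level geometry helpers.

# Per-step speeds (m/s) from an n x 3 centroid matrix; length n-1.
step_speeds <- function(centroids, frame_rate_fps) {
  if (nrow(centroids) < 2L) return(numeric(0))
  d <- diff(centroids)
  sqrt(rowSums(d^2)) * frame_rate_fps
}

# Turning angles (degrees) between consecutive displacement vectors of an
# n x 3 centroid matrix; length n-2, angle i belongs to interior vertex
# i+1. 0 deg = straight flight, 180 deg = full reversal. A zero-length
# displacement contributes a 0 deg turn by convention (the angle is
# otherwise undefined).
turning_angles_deg <- function(centroids) {
  n <- nrow(centroids)
  if (n < 3L) return(numeric(0))
  v <- diff(centroids)                       # (n-1) x 3
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  dotp <- rowSums(a * b)
  denom <- na * nb
  cosang <- ifelse(denom > 0, pmin(1, pmax(-1, dotp / denom)), 1)
  acos(cosang) * 180 / pi
}

# Axis-aligned bounding-box extents (length-3) of an N x 3 point matrix.
bbox_extents <- function(points) {
  if (nrow(points) == 0L) return(c(0, 0, 0))
  apply(points, 2L, function(col) diff(range(col)))
}

# Outline box volume: product of the axis-aligned extents.
obv_volume <- function(points) prod(bbox_extents(points))

# Normalise rows to unit vectors (zero rows left as-is).
unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) v else v / nv
}
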