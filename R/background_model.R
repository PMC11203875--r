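# Voxel-grid static-background model (pipeline step 1).
#
# The arena walls (net) are static, so voxels that are occupied in at
# least `min_occupancy_frames` of the first `n_training_frames` frames are
# declared background, and every point falling in such a voxel is removed
# from all frames thereafter.

# Encode floor(coord / voxel) integer triples as exact doubles so that set
# membership can use R's hashed `%in%`. Half-open cells: a point exactly
# on a boundary belongs to the higher-index voxel (floor does this).
.VOXEL_K <- 32768   # per-axis key range; 32768^3 < 2^53 so keys are exact
.VOXEL_B <- 16384

voxel_keys <- function(points, voxel_size_m) {
  if (nrow(points) == 0L) return(numeric(0))
  ijk <- floor(points / voxel_size_m)
  if (any(abs(ijk) >= .VOXEL_B))
    stop("coordinates too large for the voxel key encoding")
  ((ijk[, 1] + .VOXEL_B) * .VOXEL_K + (ijk[, 2] + .VOXEL_B)) * .VOXEL_K +
    (ijk[, 3] + .VOXEL_B)
}

#' Fit the static-background voxel set
#'
#' Examines the first `n_training_frames` frames on a cubic voxel grid
#' anchored at the camera origin; a voxel occupied (>= 1 point) in at
#' least `min_occupancy_frames` of them is designated background.
#'
#' @param frames list of exactly `n_training_frames` [frame_cloud()]s
#'   (the first frames of the recording).
#' @param voxel_size_m voxel edge length in metres (default 0.05).
#' @param n_training_frames number of training frames (default 4).
#' @param min_occupancy_frames occupancy threshold in frames (default 2).
#' @return An object of class `voxel_background`.
#' @export
fit_background <- function(frames, voxel_size_m = 0.05,
                           n_training_frames = 4L,
                           min_occupancy_frames = 2L) {
  if (!is.list(frames) || length(frames) != n_training_frames)
    stop(sprintf("exactly %d training frames are required", n_training_frames))
  if (!(voxel_size_m > 0)) stop("`voxel_size_m` must be positive")
  per_frame <- lapply(frames, function(f)
    unique(voxel_keys(f$points, voxel_size_m)))
  counts <- table(unlist(per_frame))
  keys <- as.numeric(names(counts)[counts >= min_occupancy_frames])
  structure(
    list(voxel_size_m = voxel_size_m,
         occupied_keys = sort(keys),
         n_training_frames = as.integer(n_training_frames),
         min_occupancy_frames = as.integer(min_occupancy_frames)),
    class = "voxel_background")
}

#' @export
print.voxel_background <- function(x, ...) {
  cat(sprintf("<voxel_background> %d voxels (%.0f mm grid, >=%d of %d frames)\n",
              length(x$occupied_keys), 1000 * x$voxel_size_m,
              x$min_occupancy_frames, x$n_training_frames))
  invisible(x)
}

#' Remove background points from a frame
#'
#' Drops exactly the points whose voxel key is in the fitted background
#' set; point order is preserved. Idempotent.
#'
#' @param frame a [frame_cloud()].
#' @param bg a fitted [fit_background()] model.
#' @return A [frame_cloud()] with the surviving points.
#' @export
remove_background <- function(frame, bg) {
  stopifnot(inherits(frame, "frame_cloud"), inherits(bg, "voxel_background"))
  if (nrow(frame$points) == 0L) return(frame)
  keys <- voxel_keys(frame$points, bg$voxel_size_m)
  keep <- !(keys %in% bg$occupied_keys)
  out <- frame
  out$points <- frame$points[keep, , drop = FALSE]
  out
}
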