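# Per-frame flight kinematics and the kinematic refinement filters
# (pipeline steps 5-6): zero-OBV removal, turning-angle screening, the
# iterative IQR outlier screen, and descriptive statistics.

#' Per-frame kinematics of a trajectory
#'
#' Speed at frame t is `||c_t - c_(t-1)|| * frame_rate` (undefined at the
#' first frame); the turning angle at frame t is the angle between
#' `c_t - c_(t-1)` and `c_(t+1) - c_t` (undefined at both endpoints).
#' Undefined entries are `NA`, never zero-filled. Also reports the outline
#' box volume, point count, point density (undefined when OBV = 0) and
#' distance from the camera.
#'
#' @param trajectory a `moth_trajectory` with >= 2 detections.
#' @param frame_rate_fps frame rate in Hz (default 55).
#' @return data.frame with one row per tracked frame.
#' @export
compute_kinematics <- function(trajectory, frame_rate_fps = 55) {
  stopifnot(inherits(trajectory, "moth_trajectory"))
  n <- length(trajectory$detections)
  if (n < 2L) stop("speed requires a trajectory of at least 2 frames")
  cent <- trajectory_centroids(trajectory)
  counts <- vapply(trajectory$detections, `[[`, numeric(1), "point_count")
  obv <- vapply(trajectory$detections, `[[`, numeric(1), "obv_m3")
  speed <- c(NA_real_, step_speeds(cent, frame_rate_fps))
  ang <- c(NA_real_, turning_angles_deg(cent), NA_real_)
  data.frame(
    frame_index = trajectory_frames(trajectory),
    centroid_x = cent[, 1], centroid_y = cent[, 2], centroid_z = cent[, 3],
    speed_mps = speed,
    turning_angle_deg = ang,
    obv_m3 = obv,
    point_count = counts,
    density_pts_per_m3 = ifelse(obv > 0, counts / obv, NA_real_),
    distance_from_camera_m = sqrt(rowSums(cent^2)))
}

.split_filter <- function(trajectories, remove, reason, detail = NULL) {
  log <- data.frame(
    trajectory_id = vapply(trajectories, `[[`, integer(1), "trajectory_id"),
    removed = remove, reason = ifelse(remove, reason, ""))
  if (!is.null(detail)) log$detail <- detail
  list(kept = trajectories[!remove], removed = trajectories[remove], log = log)
}

#' Remove trajectories containing a zero-volume outline box
#'
#' An outline box with zero volume (no thickness: all of a frame's points
#' on one plane) is a stereo artefact — in the original recordings such
#' frames clustered at the camera's ~0.9 m minimum effective range. A
#' trajectory is removed iff any of its frames has OBV = 0 (within
#' `tol_m3`). The removal log records the distance from the camera of the
#' first offending frame.
#'
#' @param trajectories list of `moth_trajectory`.
#' @param tol_m3 absolute volume tolerance (default 1e-12 m^3).
#' @return List with `kept`, `removed` and a `log` data.frame.
#' @export
filter_zero_obv <- function(trajectories, tol_m3 = 1e-12) {
  hit_dist <- rep(NA_real_, length(trajectories))
  remove <- vapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    obv <- vapply(tr$detections, `[[`, numeric(1), "obv_m3")
    j <- which(obv <= tol_m3)
    if (length(j)) {
      hit_dist[i] <<- sqrt(sum(tr$detections[[j[1]]]$centroid^2))
      TRUE
    } else FALSE
  }, logical(1))
  .split_filter(trajectories, remove, "zero_obv", detail = hit_dist)
}

#' Remove trajectories with a sharp turning angle
#'
#' Turning angles in `(max_angle_deg, 180]` mark reciprocating noise; a
#' trajectory is removed iff any of its turning angles strictly exceeds
#' `max_angle_deg` (a turn of exactly `max_angle_deg` is kept).
#'
#' @param trajectories list of `moth_trajectory`.
#' @param max_angle_deg threshold in degrees (default 110).
#' @return List with `kept`, `removed` and a `log` data.frame.
#' @export
filter_turning_angle <- function(trajectories, max_angle_deg = 110) {
  remove <- vapply(trajectories, function(tr) {
    ang <- turning_angles_deg(trajectory_centroids(tr))
    any(ang > max_angle_deg)
  }, logical(1))
  .split_filter(trajectories, remove, "turning_angle")
}

# Automated stand-in for the visual 3D-animation confirmation: a flagged
# trajectory is confirmed as noise when it barely moves over its lifetime
# or its frame record is discontinuous.
is_noise_proxy <- function(trajectory, max_net_displacement_m = 0.05) {
  cent <- trajectory_centroids(trajectory)
  net <- sqrt(sum((cent[nrow(cent), ] - cent[1, ])^2))
  gaps <- any(diff(trajectory_frames(trajectory)) != 1L)
  net < max_net_displacement_m || gaps
}

#' Iterative IQR outlier screen
#'
#' Repeats until no further removal (or `max_iterations`): pool the
#' per-frame OBV and turning-angle values of all currently kept
#' trajectories; flag any trajectory containing a frame beyond the Tukey
#' fences (`Q3 + fence_k * IQR`, and also `Q1 - fence_k * IQR` for OBV;
#' the turning-angle fence is one-sided — small angles are smooth
#' flight, not noise). Flagged trajectories are confirmed by an automated
#' movement proxy (net displacement below 5 cm over the lifetime, or any
#' frame discontinuity) in place of a visual animation check; only
#' confirmed trajectories are removed.
#'
#' @param trajectories list of `moth_trajectory` (>= 4 for meaningful
#'   quartiles; fewer is a warning no-op).
#' @param fence_k Tukey fence multiplier (default 1.5).
#' @param max_iterations iteration cap (default 10).
#' @param max_net_displacement_m noise-proxy displacement bound (default
#'   0.05 m).
#' @return List with `kept`, `removed`, `log` and `n_iterations`.
#' @export
iqr_outlier_screen <- function(trajectories, fence_k = 1.5,
                               max_iterations = 10L,
                               max_net_displacement_m = 0.05) {
  if (length(trajectories) < 4L) {
    warning("fewer than 4 trajectories; IQR screen skipped")
    out <- .split_filter(trajectories, rep(FALSE, length(trajectories)),
                         "iqr_outlier")
    out$n_iterations <- 0L
    return(out)
  }
  kept <- trajectories
  removed <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    obv_all <- unlist(lapply(kept, function(tr)
      vapply(tr$detections, `[[`, numeric(1), "obv_m3")))
    ang_all <- unlist(lapply(kept, function(tr)
      turning_angles_deg(trajectory_centroids(tr))))
    qo <- stats::quantile(obv_all, c(0.25, 0.75), names = FALSE)
    qa <- stats::quantile(ang_all, c(0.25, 0.75), names = FALSE)
    obv_lo <- qo[1] - fence_k * (qo[2] - qo[1])
    obv_hi <- qo[2] + fence_k * (qo[2] - qo[1])
    ang_hi <- qa[2] + fence_k * (qa[2] - qa[1])
    flagged <- vapply(kept, function(tr) {
      obv <- vapply(tr$detections, `[[`, numeric(1), "obv_m3")
      ang <- turning_angles_deg(trajectory_centroids(tr))
      any(obv < obv_lo | obv > obv_hi) || any(ang > ang_hi)
    }, logical(1))
    confirmed <- flagged & vapply(kept, is_noise_proxy, logical(1),
                                  max_net_displacement_m)
    if (!any(confirmed) || iter >= max_iterations) break
    removed <- c(removed, kept[confirmed])
    kept <- kept[!confirmed]
    if (length(kept) < 4L) break
  }
  ids_removed <- vapply(removed, `[[`, integer(1), "trajectory_id")
  all_ids <- vapply(trajectories, `[[`, integer(1), "trajectory_id")
  out <- .split_filter(trajectories, all_ids %in% ids_removed, "iqr_outlier")
  out$n_iterations <- iter
  out
}

#' Descriptive statistics of surviving trajectories
#'
#' Pools the defined per-frame speeds and turning angles across the kept
#' trajectories and reports mean, SD, median and quartiles, plus
#' per-trajectory mean speed.
#'
#' @param trajectories non-empty list of `moth_trajectory`.
#' @param frame_rate_fps frame rate in Hz (default 55).
#' @return An object of class `trajectory_stats`: list with `pooled`
#'   (data.frame over metrics), `per_trajectory` and `n_trajectories`.
#' @export
summarize_trajectories <- function(trajectories, frame_rate_fps = 55) {
  if (length(trajectories) == 0L) stop("no trajectories to summarise")
  kin <- lapply(trajectories, compute_kinematics, frame_rate_fps = frame_rate_fps)
  speeds <- unlist(lapply(kin, function(k) k$speed_mps))
  angles <- unlist(lapply(kin, function(k) k$turning_angle_deg))
  speeds <- speeds[!is.na(speeds)]
  angles <- angles[!is.na(angles)]
  pool_row <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(mean = mean(x), sd = stats::sd(x), q1 = q[1], median = q[2],
               q3 = q[3], n = length(x))
  }
  pooled <- rbind(cbind(metric = "speed_mps", pool_row(speeds)),
                  if (length(angles))
                    cbind(metric = "turning_angle_deg", pool_row(angles)))
  per_traj <- data.frame(
    trajectory_id = vapply(trajectories, `[[`, integer(1), "trajectory_id"),
    n_frames = vapply(trajectories, function(tr) length(tr$detections),
                      integer(1)),
    mean_speed_mps = vapply(kin, function(k)
      mean(k$speed_mps, na.rm = TRUE), numeric(1)))
  structure(list(pooled = pooled, per_trajectory = per_traj,
                 n_trajectories = length(trajectories)),
            class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf("<trajectory_stats> %d trajectories\n", x$n_trajectories))
  print(x$pooled, row.names = FALSE)
  invisible(x)
}

#' Export speed / turning-angle histogram and boxplot panels
#'
#' Writes one PNG per data category (e.g. entire / retained / removed)
#' with a histogram and boxplot of the pooled speed and turning angle —
#' the standard at-a-glance comparison of flight versus noise statistics.
#'
#' @param categories named list of trajectory lists.
#' @param dir output directory (created if needed).
#' @param frame_rate_fps frame rate in Hz.
#' @return Character vector of files written, invisibly.
#' @export
export_speed_angle_panels <- function(categories, dir, frame_rate_fps = 55) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(categories)) {
    trajs <- categories[[nm]]
    if (length(trajs) == 0L) next
    kin <- lapply(trajs, compute_kinematics, frame_rate_fps = frame_rate_fps)
    sp <- unlist(lapply(kin, `[[`, "speed_mps"))
    an <- unlist(lapply(kin, `[[`, "turning_angle_deg"))
    sp <- sp[!is.na(sp)]; an <- an[!is.na(an)]
    path <- file.path(dir, paste0("speed_angle_", nm, ".png"))
    grDevices::png(path, width = 900, height = 600)
    graphics::par(mfrow = c(2, 2))
    graphics::hist(sp, main = paste(nm, "speed"), xlab = "speed (m/s)")
    graphics::abline(v = mean(sp), lty = 2)
    if (length(an)) {
      graphics::hist(an, main = paste(nm, "turning angle"),
                     xlab = "turning angle (deg)")
      graphics::abline(v = mean(an), lty = 2)
    } else graphics::plot.new()
    graphics::boxplot(sp, horizontal = TRUE, main = "", xlab = "speed (m/s)")
    if (length(an))
      graphics::boxplot(an, horizontal = TRUE, main = "",
                        xlab = "turning angle (deg)")
    grDevices::dev.off()
    written <- c(written, path)
  }
  invisible(written)
}
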