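# Gated nearest-neighbour track linking (pipeline step 3) and short-lead
# position prediction.

#' Link detected objects across two consecutive frames
#'
#' Each frame-t object proposes its nearest frame-t+1 centroid; the
#' proposal stands iff the distance is within the gate. When two frame-t
#' objects propose the same successor, the closer pair wins (ties broken
#' by lower frame-t index) and the loser is left unmatched — it does not
#' fall back to its second-nearest candidate, mirroring the per-object
#' nearest-selection rule.
#'
#' @param objects_t,objects_t1 lists of [detected_object()]s from frames t
#'   and t+1 (either may be empty).
#' @param gate_m maximum allowed centroid distance in metres (default 0.09).
#' @return Integer matrix with columns `index_t`, `index_t1`, one row per
#'   match (possibly 0 rows).
#' @export
link_frames <- function(objects_t, objects_t1, gate_m = 0.09) {
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("index_t", "index_t1")))
  if (length(objects_t) == 0L || length(objects_t1) == 0L) return(empty)
  ct <- do.call(rbind, lapply(objects_t, `[[`, "centroid"))
  c1 <- do.call(rbind, lapply(objects_t1, `[[`, "centroid"))
  # nearest successor for every frame-t object
  d2 <- outer(rowSums(ct^2), rep(1, nrow(c1))) +
    outer(rep(1, nrow(ct)), rowSums(c1^2)) - 2 * ct %*% t(c1)
  d2[d2 < 0] <- 0
  nn <- max.col(-d2, ties.method = "first")
  nd <- sqrt(d2[cbind(seq_len(nrow(ct)), nn)])
  cand <- which(nd <= gate_m)
  if (length(cand) == 0L) return(empty)
  ord <- cand[order(nd[cand], cand)]
  taken <- logical(nrow(c1))
  rows <- list()
  for (i in ord) {
    j <- nn[i]
    if (!taken[j]) {
      taken[j] <- TRUE
      rows[[length(rows) + 1L]] <- c(i, j)
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("index_t", "index_t1")
  out[order(out[, 1]), , drop = FALSE]
}

new_trajectory <- function(id, detections, label = "unlabeled") {
  structure(list(trajectory_id = as.integer(id), detections = detections,
                 label = label),
            class = "moth_trajectory")
}

#' @export
print.moth_trajectory <- function(x, ...) {
  fr <- trajectory_frames(x)
  cat(sprintf("<moth_trajectory> id %d: frames %d-%d (%d), label '%s'\n",
              x$trajectory_id, fr[1], fr[length(fr)], length(fr), x$label))
  invisible(x)
}

#' Centroid path of a trajectory
#'
#' @param trajectory a `moth_trajectory`.
#' @return n x 3 matrix of per-frame centroids.
#' @export
trajectory_centroids <- function(trajectory) {
  do.call(rbind, lapply(trajectory$detections, `[[`, "centroid"))
}

#' Frame indices of a trajectory
#'
#' @param trajectory a `moth_trajectory`.
#' @return Integer vector of consecutive frame indices.
#' @export
trajectory_frames <- function(trajectory) {
  vapply(trajectory$detections, `[[`, integer(1), "frame_index")
}

#' Build trajectories from per-frame detections
#'
#' Greedily links detections across consecutive frames with
#' [link_frames()]. A trajectory terminates as soon as it finds no
#' successor (a single missed frame ends it — discontinuity is itself a
#' noise signature); unmatched detections seed new trajectories.
#' Trajectories shorter than `min_length_frames` (the time-series-length
#' filter) are discarded.
#'
#' @param detections_by_frame list over frames (chronological) of lists of
#'   [detected_object()]s.
#' @param gate_m linking gate in metres (default 0.09).
#' @param min_length_frames minimum time series length in frames
#'   (default 10).
#' @return List of `moth_trajectory` objects sorted by start frame then
#'   id; ids reflect creation order.
#' @export
build_trajectories <- function(detections_by_frame, gate_m = 0.09,
                               min_length_frames = 10L) {
  active <- list()    # each: list(id, detections)
  done <- list()
  next_id <- 1L
  for (objs in detections_by_frame) {
    if (length(active) > 0L && length(objs) > 0L) {
      last_dets <- lapply(active, function(tr)
        tr$detections[[length(tr$detections)]])
      m <- link_frames(last_dets, objs, gate_m)
    } else {
      m <- matrix(integer(0), ncol = 2)
    }
    matched_t <- if (nrow(m)) m[, 1] else integer(0)
    matched_t1 <- if (nrow(m)) m[, 2] else integer(0)
    new_active <- list()
    # extend matched tracks
    for (k in seq_len(nrow(m))) {
      tr <- active[[m[k, 1]]]
      tr$detections[[length(tr$detections) + 1L]] <- objs[[m[k, 2]]]
      new_active[[length(new_active) + 1L]] <- tr
    }
    # close unmatched tracks
    for (i in setdiff(seq_along(active), matched_t))
      done[[length(done) + 1L]] <- active[[i]]
    # seed new tracks from unmatched detections
    for (j in setdiff(seq_along(objs), matched_t1)) {
      new_active[[length(new_active) + 1L]] <-
        list(id = next_id, detections = list(objs[[j]]))
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$detections) >= min_length_frames, done)
  trajs <- lapply(done, function(tr) new_trajectory(tr$id, tr$detections))
  starts <- vapply(trajs, function(tr) tr$detections[[1]]$frame_index,
                   integer(1))
  ids <- vapply(trajs, `[[`, integer(1), "trajectory_id")
  trajs[order(starts, ids)]
}

#' Predict a position a few frames ahead
#'
#' Constant-velocity linear extrapolation from the last two centroids:
#' `c_T + steps_ahead * (c_T - c_(T-1))`. At 55 fps a two-step lead
#' compensates roughly the camera-to-actuation latency of a laser-zapping
#' system.
#'
#' @param trajectory a `moth_trajectory` with >= 2 detections.
#' @param steps_ahead integer lead in frames (default 2).
#' @return Length-3 predicted position (metres).
#' @export
predict_position <- function(trajectory, steps_ahead = 2L) {
  cent <- trajectory_centroids(trajectory)
  n <- nrow(cent)
  if (n < 2L) stop("prediction requires at least 2 detections")
  cent[n, ] + steps_ahead * (cent[n, ] - cent[n - 1L, ])
}

#' Update-interval and prediction-lead timing
#'
#' At a stereo update rate of `frame_rate_fps`, one update takes
#' `1000 / frame_rate_fps` milliseconds and a `steps_ahead`-frame
#' prediction leads by `steps_ahead` update intervals.
#'
#' @param frame_rate_fps camera update rate (default 55 fps).
#' @param steps_ahead prediction lead in frames (default 2).
#' @return List with `update_interval_ms` and `lead_time_ms`.
#' @export
prediction_timing <- function(frame_rate_fps = 55, steps_ahead = 2L) {
  list(update_interval_ms = 1000 / frame_rate_fps,
       lead_time_ms = steps_ahead * 1000 / frame_rate_fps)
}
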