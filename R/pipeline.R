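# End-to-end pipeline orchestration: background subtraction -> clustering
# and size filter -> gated tracking with the TSL filter -> SVM moth/noise
# classification -> zero-OBV filter -> turning-angle filter -> optional
# IQR outlier screen -> descriptive statistics.

#' Pipeline configuration
#'
#' Collects every stage's tunable with its default: 5 cm background
#' voxels trained on the first 4 frames (occupancy >= 2), 1 cm cluster
#' link distance, 20-900 point size window, 9 cm tracking gate, 10-frame
#' minimum time series length, 10-frame classifier window, 110 degree
#' turning-angle limit, 1.5x IQR fences and 55 fps.
#'
#' @param voxel_size_m background voxel edge (default 0.05).
#' @param n_training_frames,min_occupancy_frames background model fit
#'   (defaults 4, 2).
#' @param link_dist_m cluster chaining distance (default 0.01).
#' @param min_pts,max_pts cluster size window (defaults 20, 900).
#' @param gate_m track linking gate (default 0.09).
#' @param min_length_frames minimum time series length (default 10).
#' @param window_frames classifier feature window (default 10).
#' @param max_angle_deg turning-angle removal threshold (default 110).
#' @param fence_k IQR fence multiplier (default 1.5).
#' @param frame_rate_fps frame rate (default 55).
#' @param steps_ahead prediction lead in frames (default 2).
#' @param track_from_frame first frame handed to the tracker; the
#'   background-training frames 0-3 are filtered and emitted but tracking
#'   starts after them by default (default 4; set 0 to track from the
#'   start).
#' @param classify_mode `"batch"` or `"sliding"` (see [classify()]).
#' @param run_iqr_screen run the iterative IQR outlier screen
#'   (default TRUE).
#' @param model optional pre-trained [train_classifier()] model.
#' @param model_path optional path to a [save_classifier()] JSON; ignored
#'   when `model` is given. When neither is supplied a default model is
#'   trained on simulated labelled trajectories using `seed`.
#' @param seed RNG seed for the default classifier training (default 0).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size_m = 0.05,
                            n_training_frames = 4L,
                            min_occupancy_frames = 2L,
                            link_dist_m = 0.01,
                            min_pts = 20L, max_pts = 900L,
                            gate_m = 0.09,
                            min_length_frames = 10L,
                            window_frames = 10L,
                            max_angle_deg = 110,
                            fence_k = 1.5,
                            frame_rate_fps = 55,
                            steps_ahead = 2L,
                            track_from_frame = 4L,
                            classify_mode = "batch",
                            run_iqr_screen = TRUE,
                            model = NULL,
                            model_path = NULL,
                            seed = 0L) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_model <- function(config) {
  if (!is.null(config$model)) return(config$model)
  if (!is.null(config$model_path)) return(load_classifier(config$model_path))
  train_default_classifier(seed = config$seed,
                           window_frames = config$window_frames)
}

#' Train the default moth/noise classifier on simulated trajectories
#'
#' Trains on labelled trajectories drawn from the simulator's motion
#' models (120 per class by default). Used by [run_pipeline()] when no
#' model is supplied.
#'
#' @param n_per_class training trajectories per class (default 120).
#' @param seed RNG seed (default 0).
#' @param window_frames feature window (default 10).
#' @param config [scene_config()] supplying the motion models.
#' @return A `moth_classifier`.
#' @export
train_default_classifier <- function(n_per_class = 120L, seed = 0L,
                                     window_frames = 10L,
                                     config = scene_config()) {
  sim <- simulate_labeled_trajectories(n_per_class, n_per_class,
                                       config = config, seed = seed)
  feats <- t(vapply(sim$trajectories, extract_features,
                    numeric(2), window_frames = window_frames))
  train_classifier(feats, sim$labels, seed = seed)
}

#' Run the full detection and denoising pipeline
#'
#' Executes all stages in order on a frame sequence (or a PLY frame
#' directory) and returns a structured run report with per-stage counts
#' — each stage's kept + removed equals its input, asserted — the kept
#' trajectories, and pooled flight statistics. Identical config and input
#' give an identical report.
#'
#' @param config a [pipeline_config()].
#' @param input a [frame_sequence()] or a directory of per-frame PLYs.
#' @param out_dir optional output directory: one trajectory CSV per kept
#'   trajectory plus `report.json`.
#' @return An object of class `pipeline_report`: list with `counts`,
#'   `trajectories` (kept), `removed` (with per-filter reasons), `stats`
#'   (or NULL if nothing survives) and the numeric `config` echo.
#' @export
run_pipeline <- function(config = pipeline_config(), input,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seq <- if (inherits(input, "frame_sequence")) input else
    read_frame_sequence(input, frame_rate = config$frame_rate_fps)
  nf <- length(seq$frames)
  if (nf < config$n_training_frames)
    stop("sequence shorter than the background training window")

  # step 1: background model
  bg <- fit_background(seq$frames[seq_len(config$n_training_frames)],
                       voxel_size_m = config$voxel_size_m,
                       n_training_frames = config$n_training_frames,
                       min_occupancy_frames = config$min_occupancy_frames)
  filtered <- lapply(seq$frames, remove_background, bg = bg)
  n_pts_in <- sum(vapply(seq$frames, function(f) nrow(f$points), integer(1)))
  n_pts_fg <- sum(vapply(filtered, function(f) nrow(f$points), integer(1)))

  # step 2: clustering + size filter (from track_from_frame on)
  first <- config$track_from_frame + 1L
  track_frames <- filtered[first:nf]
  n_clusters <- 0L; n_objects <- 0L
  detections <- lapply(track_frames, function(f) {
    groups <- cluster_points(f, config$link_dist_m)
    n_clusters <<- n_clusters + length(groups)
    objs <- filter_by_size(f, groups, config$min_pts, config$max_pts)
    n_objects <<- n_objects + length(objs)
    objs
  })

  # step 3: tracking + TSL filter
  all_built <- build_trajectories(detections, gate_m = config$gate_m,
                                  min_length_frames = 1L)
  trajs <- Filter(function(tr)
    length(tr$detections) >= config$min_length_frames, all_built)
  n_tsl_removed <- length(all_built) - length(trajs)

  # step 4: SVM classification
  model <- pipeline_model(config)
  svm_labels <- vapply(trajs, function(tr)
    classify(tr, model, config$window_frames, mode = config$classify_mode),
    character(1))
  trajs <- mapply(function(tr, lab) { tr$label <- lab; tr },
                  trajs, svm_labels, SIMPLIFY = FALSE)
  moth_trajs <- trajs[svm_labels == "moth"]
  svm_removed <- trajs[svm_labels == "noise"]
  stopifnot(length(moth_trajs) + length(svm_removed) == length(trajs))

  # step 5: zero-OBV filter
  obv <- filter_zero_obv(moth_trajs)
  stopifnot(length(obv$kept) + length(obv$removed) == length(moth_trajs))

  # step 6: turning-angle filter
  ang <- filter_turning_angle(obv$kept, config$max_angle_deg)
  stopifnot(length(ang$kept) + length(ang$removed) == length(obv$kept))

  # iterative IQR screen
  if (config$run_iqr_screen && length(ang$kept) >= 4L) {
    iqr <- iqr_outlier_screen(ang$kept, fence_k = config$fence_k)
  } else {
    iqr <- list(kept = ang$kept, removed = list(), n_iterations = 0L)
  }
  stopifnot(length(iqr$kept) + length(iqr$removed) == length(ang$kept))
  kept <- iqr$kept

  stats <- if (length(kept) > 0L)
    summarize_trajectories(kept, config$frame_rate_fps) else NULL

  counts <- list(
    n_frames = nf,
    n_points_total = n_pts_in,
    n_points_foreground = n_pts_fg,
    n_background_voxels = length(bg$occupied_keys),
    n_clusters = n_clusters,
    n_objects_size_ok = n_objects,
    n_trajectories_built = length(all_built),
    n_removed_tsl = n_tsl_removed,
    n_after_tsl = length(trajs),
    n_removed_svm = length(svm_removed),
    n_removed_zero_obv = length(obv$removed),
    n_removed_turning_angle = length(ang$removed),
    n_removed_iqr = length(iqr$removed),
    iqr_iterations = iqr$n_iterations,
    n_final_trajectories = length(kept))

  removed <- list(tsl = Filter(function(tr)
    length(tr$detections) < config$min_length_frames, all_built),
    svm = svm_removed, zero_obv = obv$removed,
    turning_angle = ang$removed, iqr = iqr$removed)

  report <- structure(
    list(counts = counts, trajectories = kept, removed = removed,
         stats = stats,
         config = config[vapply(config, function(x)
           is.numeric(x) || is.character(x), logical(1))]),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in kept)
      write_trajectory_csv(tr, file.path(out_dir,
        sprintf("trajectory_%03d.csv", tr$trajectory_id)),
        frame_rate_fps = config$frame_rate_fps)
    writeLines(report_json(report), file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-26s %s\n", nm, x$counts[[nm]]))
  if (!is.null(x$stats)) {
    sp <- x$stats$pooled[x$stats$pooled$metric == "speed_mps", ]
    cat(sprintf("  pooled speed: %.3f +/- %.3f m/s (median %.3f, n = %d)\n",
                sp$mean, sp$sd, sp$median, sp$n))
  }
  invisible(x)
}

#' Canonical JSON serialisation of a run report
#'
#' Serialises the per-stage counts, the per-trajectory summary and the
#' pooled statistics deterministically: the same config and input yield a
#' byte-identical string.
#'
#' @param report a `pipeline_report`.
#' @return Single JSON character string.
#' @export
report_json <- function(report) {
  traj_tbl <- if (length(report$trajectories)) lapply(report$trajectories,
    function(tr) list(
      trajectory_id = tr$trajectory_id,
      start_frame = tr$detections[[1]]$frame_index,
      n_frames = length(tr$detections),
      label = tr$label))
  else list()
  obj <- list(counts = report$counts,
              trajectories = traj_tbl,
              stats = if (is.null(report$stats)) NULL else
                list(pooled = report$stats$pooled,
                     per_trajectory = report$stats$per_trajectory),
              config = report$config)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", dataframe = "columns"))
}

#' Printed reference flight speeds of *Spodoptera litura*
#'
#' Published point estimates used for cross-study comparison: the
#' free-flight stereo-vision estimate (mean +/- SD 1.81 +/- 0.68 m/s,
#' median 1.75 m/s) and two tethered flight-mill estimates
#' (Tu et al. 2010: 1.14 m/s mean, SE 0.075; Noda & Kamino 1988:
#' 0.88 m/s mean, SD 0.33). Free flight is roughly 1.6 times faster than
#' the Tu et al. flight-mill value.
#'
#' @return Named list of the published values (m/s).
#' @export
slitura_speed_reference <- function() {
  list(free_flight_mean_mps = 1.81,
       free_flight_sd_mps = 0.68,
       free_flight_median_mps = 1.75,
       flight_mill_tu2010_mean_mps = 1.14,
       flight_mill_tu2010_se_mps = 0.075,
       flight_mill_noda1988_mean_mps = 0.88,
       flight_mill_noda1988_sd_mps = 0.33)
}

#' Ratio of free-flight to flight-mill mean speed
#'
#' @param free_flight_mean_mps free-flight mean speed (default the
#'   published 1.81 m/s).
#' @param flight_mill_mean_mps flight-mill mean speed (default the
#'   published Tu et al. 1.14 m/s).
#' @return The speed ratio (about 1.6 for the defaults).
#' @export
flight_speed_ratio <- function(free_flight_mean_mps =
                                 slitura_speed_reference()$free_flight_mean_mps,
                               flight_mill_mean_mps =
                                 slitura_speed_reference()$flight_mill_tu2010_mean_mps) {
  free_flight_mean_mps / flight_mill_mean_mps
}
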