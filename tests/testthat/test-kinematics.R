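test_that("speed and turning angle follow their definitions", {
  tr <- make_traj(rbind(c(0, 0, 2), c(0.03, 0, 2.01)))
  k <- compute_kinematics(tr, 55)
  expect_true(is.na(k$speed_mps[1]))
  expect_equal(k$speed_mps[2], 55 * sqrt(0.0009 + 0.0001), tolerance = 1e-12)
  # collinear equal spacing -> 0 deg; reversal -> 180 deg
  straight <- compute_kinematics(make_traj(cbind(0.02 * (0:2), 0, 2)), 55)
  expect_equal(straight$turning_angle_deg[2], 0)
  reversal <- compute_kinematics(
    make_traj(rbind(c(0, 0, 2), c(0.05, 0, 2), c(0, 0, 2))), 55)
  expect_equal(reversal$turning_angle_deg[2], 180)
  expect_true(all(is.na(reversal$turning_angle_deg[c(1, 3)])))
  expect_error(compute_kinematics(make_traj(matrix(0, 1, 3))), "2 frames")
})

test_that("density and camera distance are reported, undefined at OBV 0", {
  tr <- make_traj(rbind(c(0, 0, 2), c(0.03, 0, 2)), obv = c(1e-4, 0),
                  counts = 50L)
  k <- compute_kinematics(tr)
  expect_equal(k$density_pts_per_m3[1], 50 / 1e-4)
  expect_true(is.na(k$density_pts_per_m3[2]))
  expect_equal(k$distance_from_camera_m[1], 2)
})

test_that("zero-OBV filter removes exactly trajectories with a flat frame", {
  flat_frame <- frame_cloud(cbind(runif(30), runif(30), 0.9), 0L)  # coplanar
  flat_obj <- detected_object(flat_frame, 1:30)
  expect_equal(flat_obj$obv_m3, 0)
  good <- make_traj(smooth_path(12), id = 1L)
  bad <- make_traj(smooth_path(12), id = 2L, obv = c(rep(1e-4, 11), 0))
  res <- filter_zero_obv(list(good, bad))
  expect_equal(vapply(res$kept, `[[`, integer(1), "trajectory_id"), 1L)
  expect_equal(vapply(res$removed, `[[`, integer(1), "trajectory_id"), 2L)
  expect_equal(nrow(res$log), 2L)
})

test_that("turning-angle filter is strict at the 110 degree boundary", {
  turn_path <- function(angle_deg) {
    a <- angle_deg * pi / 180
    rbind(c(0, 0, 2), c(0.05, 0, 2),
          c(0.05, 0, 2) + 0.05 * c(cos(a), sin(a), 0))
  }
  at110 <- make_traj(turn_path(110), id = 1L)
  at120 <- make_traj(turn_path(120), id = 2L)
  res <- filter_turning_angle(list(at110, at120), 110)
  expect_equal(vapply(res$kept, `[[`, integer(1), "trajectory_id"), 1L)
  expect_equal(vapply(res$removed, `[[`, integer(1), "trajectory_id"), 2L)
  # limit 180 removes nothing; limit 0 removes any non-collinear track
  trajs <- list(make_traj(smooth_path(10), id = 1L), at120)
  expect_length(filter_turning_angle(trajs, 180)$removed, 0L)
  expect_length(filter_turning_angle(trajs, 0)$kept, 0L)
})

test_that("filters partition their input and are idempotent", {
  set.seed(40)
  trajs <- c(lapply(1:6, function(i)
    make_traj(smooth_path(15, origin = runif(3)), id = i)),
    list(make_traj(rbind(c(0, 0, 2), c(0.05, 0, 2), c(0, 0.01, 2)), id = 7L),
         make_traj(smooth_path(10), id = 8L, obv = 0)))
  for (f in list(function(x) filter_zero_obv(x),
                 function(x) filter_turning_angle(x))) {
    res <- f(trajs)
    expect_equal(length(res$kept) + length(res$removed), length(trajs))
    again <- f(res$kept)
    expect_length(again$removed, 0L)
    expect_identical(vapply(again$kept, `[[`, integer(1), "trajectory_id"),
                     vapply(res$kept, `[[`, integer(1), "trajectory_id"))
  }
})

test_that("IQR screen removes planted low-movement outlier tracks only", {
  set.seed(50)
  cfg <- scene_config()
  moths <- simulate_labeled_trajectories(20, 0, config = cfg, seed = 60)
  # planted noise: sharp (but sub-110-degree) jitter in place
  planted <- lapply(1:3, function(i) {
    zig <- rep(c(0.012, -0.009), 10)[1:15]
    cent <- cbind(0.3 + cumsum(zig), 0.1, 1.2 + 0.0015 * (1:15))
    make_traj(cent, id = 100L + i)
  })
  trajs <- c(moths$trajectories, planted)
  res <- iqr_outlier_screen(trajs)
  expect_setequal(vapply(res$removed, `[[`, integer(1), "trajectory_id"),
                  101:103)
  expect_length(res$kept, 20L)
})

test_that("IQR screen is a warning no-op below 4 trajectories and
           monotone in the fence multiplier", {
  trajs <- list(make_traj(smooth_path(10)))
  expect_warning(res <- iqr_outlier_screen(trajs), "fewer")
  expect_length(res$kept, 1L)
  set.seed(51)
  moths <- simulate_labeled_trajectories(12, 4, seed = 61)
  removed_ids <- function(k) {
    r <- iqr_outlier_screen(moths$trajectories, fence_k = k)
    vapply(r$removed, `[[`, integer(1), "trajectory_id")
  }
  expect_true(all(removed_ids(2.0) %in% removed_ids(1.0)))
})

test_that("identical trajectories are a fixed point of the screen", {
  trajs <- lapply(1:5, function(i) make_traj(smooth_path(12), id = i))
  res <- iqr_outlier_screen(trajs)
  expect_length(res$removed, 0L)
  expect_equal(res$n_iterations, 1L)
})

test_that("summary statistics are ordered and exact on constant speed", {
  v <- 1.3
  cent <- cbind((v / 55) * (0:9), 0, 2)
  s <- summarize_trajectories(list(make_traj(cent)), 55)
  sp <- s$pooled[s$pooled$metric == "speed_mps", ]
  expect_equal(sp$mean, v, tolerance = 1e-9)
  expect_equal(sp$median, v, tolerance = 1e-9)
  expect_equal(sp$sd, 0, tolerance = 1e-9)
  expect_true(sp$q1 <= sp$median && sp$median <= sp$q3)
  expect_error(summarize_trajectories(list()), "no trajectories")
})

test_that("pooled statistics agree with a flat recomputation from CSVs", {
  set.seed(70)
  trajs <- lapply(1:3, function(i)
    make_traj(smooth_path(12, origin = runif(3) + c(0, 0, 1)), id = i))
  d <- withr::local_tempdir()
  speeds <- c()
  for (tr in trajs) {
    f <- file.path(d, sprintf("trajectory_%03d.csv", tr$trajectory_id))
    write_trajectory_csv(tr, f, 55)
    speeds <- c(speeds, na.omit(read_trajectory_csv(f)$speed_mps))
  }
  s <- summarize_trajectories(trajs, 55)
  sp <- s$pooled[s$pooled$metric == "speed_mps", ]
  expect_equal(sp$mean, mean(speeds), tolerance = 1e-9)
  expect_equal(sp$median, median(speeds), tolerance = 1e-9)
  expect_equal(sp$n, length(speeds))
})

test_that("speed/angle panel export writes one image per category", {
  trajs <- lapply(1:2, function(i) make_traj(smooth_path(12), id = i))
  d <- withr::local_tempdir()
  files <- export_speed_angle_panels(list(entire = trajs, kept = trajs), d)
  expect_length(files, 2L)
  expect_true(all(file.exists(files)))
})
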