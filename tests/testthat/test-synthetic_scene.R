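test_that("scene simulation is deterministic and validates its config", {
  cfg <- scene_config(n_frames = 10, rng_seed = 5, background_density = 20)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$truth$moth_paths, b$truth$moth_paths)
  expect_error(scene_config(n_frames = 3), "at least 4")
})

test_that("background-only scenes are all-background and frame-stable", {
  cfg <- scene_config(n_moths = 0, n_noise_events = 0, n_frames = 8,
                      rng_seed = 2)
  sc <- simulate_scene(cfg)
  expect_true(all(unlist(sc$truth$frame_labels) == "background"))
  n0 <- nrow(sc$sequence$frames[[1]]$points)
  for (t in 5:8) {
    ft <- sc$sequence$frames[[t]]$points
    expect_equal(nrow(ft), n0)
    # identical up to the sub-voxel jitter
    expect_lt(max(abs(ft - sc$sequence$frames[[1]]$points)),
              2 * cfg$background_jitter_m + 1e-12)
  }
})

test_that("every emitted point carries exactly one label", {
  cfg <- scene_config(n_frames = 12, rng_seed = 9, n_noise_events = 2)
  sc <- simulate_scene(cfg)
  for (t in seq_along(sc$sequence$frames))
    expect_length(sc$truth$frame_labels[[t]],
                  nrow(sc$sequence$frames[[t]]$points))
})

test_that("ground-truth moth speed and arena confinement hold", {
  cfg <- scene_config(n_moths = 1, moth_speed_mean_mps = 1.8,
                      moth_speed_sd_mps = 0.3, rng_seed = 7, n_frames = 165)
  sc <- simulate_scene(cfg)
  sp <- na.omit(sc$truth$moth_paths$speed_mps)
  se <- sd(sp) / sqrt(length(sp))
  expect_lt(abs(mean(sp) - 1.8), 3 * se)
  # path never exits the arena box
  mp <- sc$truth$moth_paths
  expect_true(all(abs(mp$x) <= 0.9 & abs(mp$y) <= 0.9 &
                    mp$z >= 0 & mp$z <= 3.5))
})

test_that("moth paths turn smoothly, below the per-frame cap", {
  cfg <- scene_config(rng_seed = 13, n_frames = 120)
  sc <- simulate_scene(cfg)
  mp <- sc$truth$moth_paths
  ang <- mothtrack:::turning_angles_deg(as.matrix(mp[, c("x", "y", "z")]))
  expect_lte(max(ang), cfg$max_turn_deg + 1e-6)
})

test_that("transient noise reciprocates with limited net movement", {
  set.seed(3)
  for (rep in 1:5) {
    start <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), runif(1, 0.8, 2.5))
    path <- mothtrack:::simulate_reciprocating_path(40, start)
    net <- sqrt(sum((path[40, ] - path[1, ])^2))
    expect_lt(net, 0.05)
    ang <- mothtrack:::turning_angles_deg(path)
    expect_gt(mean(ang > 110), 0.8)   # mostly direction reversals
  }
})

test_that("coplanar artefacts have exactly one zero box extent at the
           near-range depth", {
  cfg <- scene_config(rng_seed = 31, n_frames = 70, n_moths = 0,
                      n_noise_events = 6, background_density = 0)
  sc <- simulate_scene(cfg)
  cop <- sc$truth$noise_events[sc$truth$noise_events$type ==
                                 "coplanar_artifact", ]
  expect_gt(nrow(cop), 0L)
  for (e in cop$event_id) {
    lab <- paste0("noise_", e)
    for (t in (cop$start_frame[cop$event_id == e]:
               cop$end_frame[cop$event_id == e]) + 1L) {
      pts <- sc$sequence$frames[[t]]$points[
        sc$truth$frame_labels[[t]] == lab, , drop = FALSE]
      if (nrow(pts) < 2) next
      ext <- apply(pts, 2, function(x) diff(range(x)))
      expect_equal(sum(ext == 0), 1L)
      expect_equal(unique(pts[, 3]), cfg$near_range_m)
    }
  }
})

test_that("rendered blobs form one cluster at the link distance", {
  skip_if_not_installed("igraph")
  set.seed(77)
  blob <- render_moth_blob(c(0.1, 0, 2), 400, 0.02)
  expect_equal(nrow(blob), 400L)
  expect_length(oracle_single_linkage(blob, 0.01), 1L)
  one <- render_moth_blob(c(0.1, 0, 2), 1, 0.01)
  expect_equal(dim(one), c(1L, 3L))
  expect_lt(sqrt(sum((one - c(0.1, 0, 2))^2)), 0.02 + 1e-9)
  expect_error(render_moth_blob(c(0, 0, 1), 0, 0.01), "at least 1")
})

test_that("labelled trajectory sets are balanced and reproducible", {
  a <- simulate_labeled_trajectories(5, 7, seed = 3)
  b <- simulate_labeled_trajectories(5, 7, seed = 3)
  expect_identical(lapply(a$trajectories, trajectory_centroids),
                   lapply(b$trajectories, trajectory_centroids))
  expect_equal(table(a$labels), table(c(rep("moth", 5), rep("noise", 7))))
})
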