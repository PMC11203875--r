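test_that("PLY write/read round-trips coordinates at float32 precision", {
  set.seed(1)
  pts <- matrix(runif(300, -2, 4), ncol = 3)
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(pts, f)
  back <- read_ply(f)
  expect_equal(dim(back), dim(pts))
  expect_lt(max(abs(back - pts)), 1e-6 * max(abs(pts)) + 1e-7)
  # ASCII dialect reads back too
  fa <- withr::local_tempfile(fileext = ".ply")
  write_ply(pts, fa, binary = FALSE)
  expect_equal(dim(read_ply(fa)), dim(pts))
  expect_lt(max(abs(read_ply(fa) - pts)), 1e-7)
})

test_that("PLY reader handles empty clouds and extra vertex properties", {
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(matrix(numeric(0), ncol = 3), f)
  expect_equal(nrow(read_ply(f)), 0L)
  # ASCII file with an extra intensity property: x/y/z extracted, rest skipped
  f2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "property float intensity", "end_header",
               "1 2 3 9", "4 5 6 8"), f2)
  expect_equal(unname(read_ply(f2)), rbind(c(1, 2, 3), c(4, 5, 6)))
})

test_that("frame sequences read in filename order and reject gaps", {
  d <- withr::local_tempdir()
  write_ply(matrix(c(0, 0, 1), 1), file.path(d, "frame_0000.ply"))
  write_ply(matrix(numeric(0), ncol = 3), file.path(d, "frame_0001.ply"))
  seq2 <- read_frame_sequence(d, frame_rate = 55)
  expect_length(seq2$frames, 2L)
  expect_equal(nrow(seq2$frames[[2]]$points), 0L)  # empty frame allowed
  expect_equal(seq2$frames[[2]]$timestamp_s, 1 / 55)
  # non-consecutive numbering is a sequence-gap error
  file.rename(file.path(d, "frame_0001.ply"), file.path(d, "frame_0002.ply"))
  expect_error(read_frame_sequence(d), "gap")
  expect_error(read_frame_sequence(file.path(d, "no_such_dir")), "exist")
})

test_that("sequence write-then-read preserves frame counts and sizes", {
  cfg <- scene_config(n_frames = 6, rng_seed = 11, background_density = 20,
                      n_noise_events = 1)
  sc <- simulate_scene(cfg)
  d <- withr::local_tempdir()
  write_frame_sequence(sc$sequence, d)
  back <- read_frame_sequence(d, frame_rate = 55)
  expect_equal(length(back$frames), length(sc$sequence$frames))
  expect_equal(vapply(back$frames, function(f) nrow(f$points), integer(1)),
               vapply(sc$sequence$frames, function(f) nrow(f$points),
                      integer(1)))
})

test_that("trajectory CSV has one row per frame and round-trips exactly", {
  tr <- make_traj(smooth_path(10), obv = 2e-4, counts = 120L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f, frame_rate_fps = 55)
  expect_length(readLines(f), 11L)          # header + 10 rows
  back <- read_trajectory_csv(f)
  expect_identical(back$centroid_x, trajectory_centroids(tr)[, 1])
  expect_identical(back$centroid_z, trajectory_centroids(tr)[, 3])
  # undefined kinematics are empty: speed on row 1, angle on rows 1-2
  expect_true(is.na(back$speed_mps[1]))
  expect_true(all(is.na(back$turning_angle_deg[1:2])))
  expect_false(anyNA(back$speed_mps[-1]))
})

test_that("single-frame trajectory leaves speed and angle columns empty", {
  tr <- make_traj(matrix(c(0, 0, 2), 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(nrow(back), 1L)
  expect_true(is.na(back$speed_mps))
  expect_true(is.na(back$turning_angle_deg))
})

test_that("frame containers validate their invariants", {
  expect_error(frame_cloud(matrix(c(0, 0, NA), 1), 0), "finite")
  expect_error(frame_cloud(matrix(0, 1, 2), 0), "3 columns")
  expect_error(frame_cloud(matrix(0, 1, 3), -1), "non-negative")
  f0 <- frame_cloud(matrix(0, 1, 3), 0)
  f2 <- frame_cloud(matrix(0, 1, 3), 2)
  expect_error(frame_sequence(list(f0, f2)), "consecutive")
})
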