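# Shared fixtures: hand-built trajectories, a brute-force clustering
# oracle, and random frame generators. Everything is generated in code.

# Build a trajectory directly from a centroid matrix (kinematics and
# filter tests don't need member points). `obv` and `counts` recycle.
make_traj <- function(centroids, id = 1L, start_frame = 0L,
                      obv = 1e-4, counts = 100L, frames = NULL) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  obv <- rep_len(obv, n)
  counts <- rep_len(as.integer(counts), n)
  if (is.null(frames)) frames <- start_frame + seq_len(n) - 1L
  dets <- lapply(seq_len(n), function(i)
    structure(list(frame_index = as.integer(frames[i]),
                   point_indices = seq_len(counts[i]),
                   centroid = centroids[i, ],
                   point_count = counts[i],
                   obv_m3 = obv[i]),
              class = "detected_object"))
  mothtrack:::new_trajectory(id, dets)
}

# A smooth constant-direction path with mild curvature: a plausible
# moth-like fixture with positive position SD and low turning SD.
smooth_path <- function(n, step = 0.03, origin = c(0, 0, 2)) {
  theta <- cumsum(rep(0.05, n))
  cbind(origin[1] + step * seq_len(n) * cos(theta),
        origin[2] + step * seq_len(n) * sin(theta) * 0.2,
        origin[3] + 0.001 * seq_len(n))
}

# Independent single-linkage oracle: connected components of the
# thresholded brute-force distance graph (igraph route, entirely
# distinct from the hclust implementation).
oracle_single_linkage <- function(pts, link) {
  n <- nrow(pts)
  if (n == 0L) return(list())
  if (n == 1L) return(list(1L))
  adj <- as.matrix(stats::dist(pts)) <= link + 1e-12
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  unname(split(seq_len(n), memb))
}

# Canonical form of a partition (order-independent comparison).
canonical_partition <- function(groups) {
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  groups[order(vapply(groups, min, integer(1)))]
}

# Random frame: sparse uniform points plus a few Gaussian clumps, the
# regime where chained linkage is non-trivial.
random_frame_points <- function(n_total, n_clumps = 3L) {
  n_clump_pts <- if (n_clumps > 0L)
    as.integer(stats::runif(n_clumps, 10, max(11, n_total / 4))) else integer(0)
  n_unif <- max(0L, n_total - sum(n_clump_pts))
  pts <- matrix(stats::runif(3 * n_unif, 0, 0.5), ncol = 3)
  for (k in seq_len(n_clumps)) {
    ctr <- stats::runif(3, 0.1, 0.4)
    pts <- rbind(pts, sweep(matrix(stats::rnorm(3 * n_clump_pts[k], sd = 0.01),
                                   ncol = 3), 2, ctr, `+`))
  }
  pts
}

# Distance of points from the nearest arena wall (default arena box).
wall_distance <- function(pts, half_w = 0.9, half_h = 0.9, depth = 3.5) {
  pmin(half_w - abs(pts[, 1]), half_h - abs(pts[, 2]), pts[, 3],
       depth - pts[, 3])
}

# Match a recovered trajectory to ground-truth moth ids frame by frame:
# returns the id vector (NA where no truth position is within `tol`).
truth_moth_ids <- function(trajectory, truth, tol = 0.03) {
  cent <- trajectory_centroids(trajectory)
  frames <- trajectory_frames(trajectory)
  vapply(seq_along(frames), function(i) {
    cand <- truth$moth_paths[truth$moth_paths$frame == frames[i], ]
    if (nrow(cand) == 0L) return(NA_integer_)
    d <- sqrt((cand$x - cent[i, 1])^2 + (cand$y - cent[i, 2])^2 +
                (cand$z - cent[i, 3])^2)
    if (min(d) > tol) NA_integer_ else cand$moth_id[which.min(d)]
  }, integer(1))
}
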