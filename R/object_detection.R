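# Chained-proximity clustering and size filtering (pipeline step 2).

#' Cluster residual points by chained 1 cm proximity
#'
#' Points are grouped into the connected components of the graph that
#' joins any two points at Euclidean distance <= `link_dist_m` (single
#' linkage: a chain of close points forms one cluster regardless of its
#' overall span). The boundary is inclusive. Implemented via
#' single-linkage agglomeration cut at the link distance, which yields
#' exactly these components.
#'
#' @param frame a [frame_cloud()] or an N x 3 point matrix
#'   (background-filtered).
#' @param link_dist_m chaining distance in metres (default 0.01).
#' @return List of integer vectors, each the point indices of one cluster
#'   (every point appears in exactly one cluster); empty list for an empty
#'   frame. Clusters are ordered by their smallest member index.
#' @export
cluster_points <- function(frame, link_dist_m = 0.01) {
  pts <- if (inherits(frame, "frame_cloud")) frame$points else as.matrix(frame)
  n <- nrow(pts)
  if (n == 0L) return(list())
  if (n == 1L) return(list(1L))
  hc <- stats::hclust(stats::dist(pts), method = "single")
  # tiny slack so distances equal to the threshold (up to fp rounding)
  # merge: "within 1 cm" is inclusive
  memb <- stats::cutree(hc, h = link_dist_m * (1 + 1e-12) + 1e-15)
  groups <- split(seq_len(n), memb)
  names(groups) <- NULL
  groups[order(vapply(groups, min, integer(1)))]
}

#' Construct a detected object from one cluster
#'
#' The object position is the arithmetic mean of its member points; the
#' outline box volume (OBV) is the product of the axis-aligned
#' bounding-box extents in camera coordinates.
#'
#' @param frame a [frame_cloud()].
#' @param point_indices integer indices of the member points.
#' @return An object of class `detected_object`.
#' @export
detected_object <- function(frame, point_indices) {
  pts <- frame$points[point_indices, , drop = FALSE]
  structure(
    list(frame_index = frame$frame_index,
         point_indices = as.integer(point_indices),
         centroid = colMeans(pts),
         point_count = length(point_indices),
         obv_m3 = obv_volume(pts)),
    class = "detected_object")
}

#' Filter clusters by point-cloud size
#'
#' Clusters with fewer than `min_pts` or more than `max_pts` points are
#' unlikely to be moths and are discarded (bounds inclusive: sizes in
#' `[min_pts, max_pts]` survive).
#'
#' @param frame the [frame_cloud()] the clusters index into.
#' @param groups list of point-index vectors from [cluster_points()].
#' @param min_pts minimum cluster size (default 20).
#' @param max_pts maximum cluster size (default 900).
#' @return List of [detected_object()]s for the surviving clusters.
#' @export
filter_by_size <- function(frame, groups, min_pts = 20L, max_pts = 900L) {
  sizes <- lengths(groups)
  keep <- sizes >= min_pts & sizes <= max_pts
  lapply(groups[keep], function(g) detected_object(frame, g))
}

#' Detect candidate objects in one background-filtered frame
#'
#' Convenience wrapper: [cluster_points()] then [filter_by_size()].
#'
#' @inheritParams cluster_points
#' @inheritParams filter_by_size
#' @return List of [detected_object()]s.
#' @export
detect_objects <- function(frame, link_dist_m = 0.01, min_pts = 20L,
                           max_pts = 900L) {
  filter_by_size(frame, cluster_points(frame, link_dist_m),
                 min_pts = min_pts, max_pts = max_pts)
}
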