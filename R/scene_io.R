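# Frame containers and PLY / CSV input-output.
#
# Coordinate convention throughout the package: camera at the origin,
# +Z = depth away from the camera, +X right, +Y up, units in metres.
# "Distance from the camera" is the Euclidean norm of a centroid.

#' Construct a single-frame point cloud
#'
#' A `frame_cloud` holds the 3D points observed in one stereo frame, in
#' metres, in the camera coordinate frame (origin at the camera, +Z depth).
#'
#' @param points numeric matrix with 3 columns (x, y, z) or anything
#'   coercible to one; zero rows are allowed (an empty frame).
#' @param frame_index non-negative integer position of the frame in its
#'   sequence.
#' @param frame_rate_fps frames per second; used to derive the timestamp.
#' @return An object of class `frame_cloud` with elements `frame_index`,
#'   `points` (N x 3 matrix) and `timestamp_s`.
#' @export
frame_cloud <- function(points, frame_index, frame_rate_fps = 55) {
  if (is.null(points)) points <- matrix(numeric(0), ncol = 3)
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("all point coordinates must be finite")
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != 1L || is.na(frame_index) || frame_index < 0L)
    stop("`frame_index` must be a single non-negative integer")
  colnames(points) <- c("x", "y", "z")
  structure(
    list(frame_index = frame_index, points = points,
         timestamp_s = frame_index / frame_rate_fps),
    class = "frame_cloud"
  )
}

#' @export
print.frame_cloud <- function(x, ...) {
  cat(sprintf("<frame_cloud> frame %d: %d points\n",
              x$frame_index, nrow(x$points)))
  invisible(x)
}

#' Construct an ordered sequence of frame clouds
#'
#' Frame indices must be consecutive starting at 0: a missing frame in a
#' recording is an input error (a gap would silently break track linking,
#' which assumes consecutive frames).
#'
#' @param frames list of [frame_cloud()] objects, in time order.
#' @param frame_rate_fps frames per second of the recording (default 55).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate_fps = 55) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of frame_cloud objects")
  ok <- vapply(frames, inherits, logical(1), what = "frame_cloud")
  if (!all(ok)) stop("all elements of `frames` must be frame_cloud objects")
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (!identical(idx, seq_along(frames) - 1L))
    stop(sprintf(
      "frame indices must be consecutive from 0; got gap or disorder near index %d",
      idx[which(idx != seq_along(frames) - 1L)[1]]))
  if (!(is.numeric(frame_rate_fps) && frame_rate_fps > 0))
    stop("`frame_rate_fps` must be positive")
  structure(list(frames = frames, frame_rate_fps = frame_rate_fps),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  n <- vapply(x$frames, function(f) nrow(f$points), integer(1))
  cat(sprintf("<frame_sequence> %d frames @ %g fps, %d points total\n",
              length(x$frames), x$frame_rate_fps, sum(n)))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

# ---------------------------------------------------------------------------
# PLY

#' Read a PLY point cloud file
#'
#' Supports ASCII and binary_little_endian PLY with a `vertex` element that
#' carries scalar `x`, `y`, `z` properties (float or double); additional
#' scalar vertex properties are skipped, list properties and further
#' elements after `vertex` are ignored.
#'
#' @param path path to a `.ply` file.
#' @return N x 3 double matrix of coordinates (possibly 0 rows).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; n_vertex <- NA_integer_
  props <- character(0); types <- character(0)
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      in_vertex <- identical(tok[2], "vertex")
      if (in_vertex) n_vertex <- as.integer(tok[3])
      else if (!is.na(n_vertex)) in_vertex <- FALSE
    } else if (tok[1] == "property" && in_vertex) {
      if (identical(tok[2], "list"))
        stop("list properties on the vertex element are not supported")
      types <- c(types, tok[2])
      props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.na(n_vertex)) stop("PLY header has no vertex element: ", path)
  need <- match(c("x", "y", "z"), props)
  if (anyNA(need)) stop("PLY vertex element lacks x/y/z properties: ", path)
  if (n_vertex == 0L) return(matrix(numeric(0), ncol = 3,
                                    dimnames = list(NULL, c("x", "y", "z"))))
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (!all(types %in% names(sizes)))
    stop("unsupported PLY property type in ", path)
  if (identical(fmt, "ascii")) {
    tokens <- scan(con, what = character(), quiet = TRUE)
    ncolp <- length(props)
    if (length(tokens) < n_vertex * ncolp)
      stop("truncated ASCII PLY body in ", path)
    vals <- matrix(as.numeric(tokens[seq_len(n_vertex * ncolp)]),
                   nrow = n_vertex, ncol = ncolp, byrow = TRUE)
    out <- vals[, need, drop = FALSE]
  } else if (identical(fmt, "binary_little_endian")) {
    rec <- sum(sizes[types])
    raw <- readBin(con, what = "raw", n = rec * n_vertex)
    if (length(raw) < rec * n_vertex) stop("truncated binary PLY body in ", path)
    offsets <- cumsum(c(0L, sizes[types]))[seq_along(types)]
    read_col <- function(j) {
      sz <- sizes[[types[j]]]
      pos <- rep(offsets[j], n_vertex) + rec * (seq_len(n_vertex) - 1L)
      bytes <- raw[as.vector(outer(seq_len(sz), pos, `+`))]
      what <- if (types[j] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(bytes, what = what, n = n_vertex, size = sz, endian = "little")
    }
    out <- vapply(need, read_col, numeric(n_vertex))
    if (n_vertex == 1L) out <- matrix(out, nrow = 1L)
  } else {
    stop("unsupported PLY format '", fmt, "' in ", path)
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write a point cloud to PLY
#'
#' Writes vertex x/y/z as float32, binary little-endian by default
#' (round-trips at float32 precision) or ASCII on request.
#'
#' @param points N x 3 numeric matrix.
#' @param path output path.
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, path, binary = TRUE) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3L) stop("`points` must have 3 columns")
  n <- nrow(points)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0L) {
    if (binary) {
      writeBin(as.vector(t(points)), con, size = 4L, endian = "little")
    } else {
      writeLines(apply(points, 1L, function(r)
        paste(formatC(r, digits = 9, format = "g"), collapse = " ")), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Frame sequences on disk

frame_file_index <- function(paths) {
  m <- regmatches(basename(paths), regexpr("[0-9]+(?=\\.ply$)",
                                           basename(paths), perl = TRUE))
  if (length(m) != length(paths))
    stop("every PLY filename must embed a frame number before '.ply'")
  as.integer(m)
}

#' Read an ordered PLY frame directory as a frame sequence
#'
#' Filenames must embed the frame number as the last integer before the
#' `.ply` extension (e.g. `frame_0007.ply`). Indices must form a
#' consecutive run; the first file becomes frame 0.
#'
#' @param directory_path directory containing one `.ply` file per frame.
#' @param frame_rate frames per second (default 55).
#' @return A [frame_sequence()].
#' @export
read_frame_sequence <- function(directory_path, frame_rate = 55) {
  if (!dir.exists(directory_path))
    stop("directory does not exist: ", directory_path)
  files <- list.files(directory_path, pattern = "\\.ply$", full.names = TRUE)
  if (length(files) == 0L) stop("no PLY files in ", directory_path)
  idx <- frame_file_index(files)
  o <- order(idx)
  files <- files[o]; idx <- idx[o]
  if (anyDuplicated(idx)) stop("duplicate frame numbers in ", directory_path)
  if (!identical(idx, seq(idx[1], length.out = length(idx))))
    stop(sprintf("sequence gap: frame numbers are not consecutive (missing %d)",
                 setdiff(seq(idx[1], idx[length(idx)]), idx)[1]))
  frames <- lapply(seq_along(files), function(i)
    frame_cloud(read_ply(files[i]), frame_index = i - 1L,
                frame_rate_fps = frame_rate))
  frame_sequence(frames, frame_rate_fps = frame_rate)
}

#' Write a frame sequence as a PLY directory
#'
#' @param sequence a [frame_sequence()].
#' @param directory_path output directory (created if needed).
#' @param binary binary or ASCII PLY.
#' @return `directory_path`, invisibly.
#' @export
write_frame_sequence <- function(sequence, directory_path, binary = TRUE) {
  stopifnot(inherits(sequence, "frame_sequence"))
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  for (f in sequence$frames)
    write_ply(f$points,
              file.path(directory_path, sprintf("frame_%05d.ply", f$frame_index)),
              binary = binary)
  invisible(directory_path)
}

# ---------------------------------------------------------------------------
# Trajectory CSV

traj_csv_columns <- c("frame_index", "centroid_x", "centroid_y", "centroid_z",
                      "point_count", "obv_m3", "speed_mps",
                      "turning_angle_deg", "distance_from_camera_m",
                      "density_pts_per_m3")

#' Write one trajectory to CSV
#'
#' One row per tracked frame with the centroid, point count, outline box
#' volume (OBV), speed, turning angle, distance from the camera and point
#' density. Speed is undefined on the first row and the turning angle on
#' the first two rows (it is reported for the turn completed at that
#' frame); undefined entries are left empty. Values are written with 17
#' significant digits so a read-back reproduces them bit-identically.
#'
#' @param trajectory a trajectory as returned by [build_trajectories()].
#' @param path output CSV path.
#' @param frame_rate_fps frame rate used for speeds (default 55).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, frame_rate_fps = 55) {
  stopifnot(inherits(trajectory, "moth_trajectory"))
  n <- length(trajectory$detections)
  if (n < 1L) stop("trajectory must have at least one frame")
  cent <- trajectory_centroids(trajectory)
  counts <- vapply(trajectory$detections, `[[`, numeric(1), "point_count")
  obv <- vapply(trajectory$detections, `[[`, numeric(1), "obv_m3")
  speed <- c(NA_real_, step_speeds(cent, frame_rate_fps))[seq_len(n)]
  ang <- turning_angles_deg(cent)          # angle at interior vertex i+1
  ang_trailing <- c(NA_real_, NA_real_, ang)[seq_len(n)]  # at arrival frame
  dist_cam <- sqrt(rowSums(cent^2))
  dens <- ifelse(obv > 0, counts / obv, NA_real_)
  df <- data.frame(
    frame_index = vapply(trajectory$detections, `[[`, integer(1), "frame_index"),
    centroid_x = cent[, 1], centroid_y = cent[, 2], centroid_z = cent[, 3],
    point_count = counts, obv_m3 = obv, speed_mps = speed,
    turning_angle_deg = ang_trailing, distance_from_camera_m = dist_cam,
    density_pts_per_m3 = dens)
  fmt <- function(x) ifelse(is.na(x), "",
                            formatC(x, digits = 17, format = "g"))
  out <- df
  for (j in setdiff(names(out), c("frame_index", "point_count")))
    out[[j]] <- fmt(df[[j]])
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return data.frame with the trajectory columns; undefined kinematics are
#'   `NA`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  missing <- setdiff(traj_csv_columns, names(df))
  if (length(missing))
    stop("trajectory CSV lacks columns: ", paste(missing, collapse = ", "))
  df
}
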