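# Linear SVM moth/noise trajectory classifier (pipeline step 4).
#
# Two shape features over the last 10 tracked frames separate real flight
# (large, smoothly directed displacement) from stereo noise (small,
# reciprocating displacement): the spatial standard deviation of the
# centroid positions and the standard deviation of the turning angles.

#' Extract classifier features from a trajectory window
#'
#' Computed on the final `window_frames` detections:
#' * `sd_position_m` — scalar spatial SD: the RMS distance of the window
#'   centroids from their mean (equivalently the quadrature norm of the
#'   per-axis population SDs). A per-axis sample-SD variant is available
#'   via `position_sd = "per_axis"` for sensitivity checks.
#' * `sd_turning_deg` — population SD of the turning angles between the
#'   window's consecutive displacement vectors (zero-length displacements
#'   count as 0 degree turns).
#'
#' Both features depend only on relative geometry, so they are invariant
#' under rigid motions of the trajectory.
#'
#' @param trajectory a `moth_trajectory` with at least `window_frames`
#'   detections.
#' @param window_frames window length in frames (default 10).
#' @param position_sd `"scalar"` (default) or `"per_axis"`.
#' @return Named numeric vector `c(sd_position_m, sd_turning_deg)`.
#' @export
extract_features <- function(trajectory, window_frames = 10L,
                             position_sd = c("scalar", "per_axis")) {
  position_sd <- match.arg(position_sd)
  cent <- trajectory_centroids(trajectory)
  n <- nrow(cent)
  if (n < window_frames)
    stop(sprintf("trajectory has %d frames; %d required", n, window_frames))
  w <- cent[(n - window_frames + 1L):n, , drop = FALSE]
  centred <- sweep(w, 2L, colMeans(w))
  sd_pos <- if (position_sd == "scalar")
    sqrt(mean(rowSums(centred^2)))
  else
    sqrt(sum(apply(w, 2L, stats::var)))
  ang <- turning_angles_deg(w)
  sd_turn <- if (length(ang) == 0L) 0 else sqrt(mean((ang - mean(ang))^2))
  c(sd_position_m = sd_pos, sd_turning_deg = sd_turn)
}

#' Train the linear moth/noise classifier
#'
#' Fits a max-margin linear SVM (via \pkg{e1071}/libsvm) on standardized
#' features. The fitted hyperplane is reduced to a 5-number linear record
#' (two weights, bias, feature means and SDs) so classification is a
#' plain, serialisable dot product with `moth` on the positive side.
#'
#' @param features numeric matrix / data.frame with columns
#'   `sd_position_m`, `sd_turning_deg` (one row per trajectory).
#' @param labels character/factor vector of `"moth"` / `"noise"`.
#' @param seed RNG seed (the fit itself is deterministic; the seed is
#'   fixed for reproducibility of any resampling wrapped around it).
#' @param cost SVM cost parameter (default 1).
#' @return An object of class `moth_classifier`.
#' @export
train_classifier <- function(features, labels, seed = 0L, cost = 1) {
  x <- as.matrix(features)
  if (ncol(x) != 2L) stop("`features` must have two columns")
  labels <- as.character(labels)
  if (!all(labels %in% c("moth", "noise")))
    stop("labels must be 'moth' or 'noise'")
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("both classes must be present in the training data")
  if (any(tab < 10L))
    warning("fewer than 10 examples in a class; the margin may be unstable")
  set.seed(seed)
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sds, "/")
  y <- factor(labels, levels = c("noise", "moth"))
  fit <- e1071::svm(xs, y, kernel = "linear", scale = FALSE, cost = cost)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the hyperplane so that moth examples score positive
  dec <- xs %*% w + b
  if (mean(dec[labels == "moth"]) < mean(dec[labels == "noise"])) {
    w <- -w; b <- -b
  }
  structure(
    list(weights = unname(w), bias = unname(b),
         feature_means = unname(mu), feature_sds = unname(sds),
         feature_names = colnames(x)),
    class = "moth_classifier")
}

#' @export
print.moth_classifier <- function(x, ...) {
  cat(sprintf("<moth_classifier> decision = %.3f*z1 + %.3f*z2 + %.3f (moth if > 0)\n",
              x$weights[1], x$weights[2], x$bias))
  invisible(x)
}

#' Decision value of the linear classifier
#'
#' @param model a `moth_classifier`.
#' @param features feature vector or matrix as from [extract_features()].
#' @return Numeric decision value(s); `moth` iff strictly positive.
#' @export
decision_value <- function(model, features) {
  x <- if (is.matrix(features)) features else matrix(features, ncol = 2)
  xs <- sweep(sweep(x, 2L, model$feature_means), 2L, model$feature_sds, "/")
  drop(xs %*% model$weights + model$bias)
}

#' Classify a trajectory as moth or noise
#'
#' Batch mode (default) evaluates the trajectory's final window once.
#' Sliding mode evaluates every length-`window_frames` window and labels
#' the trajectory `noise` if any window does — the conservative behaviour
#' a frame-by-frame real-time system would exhibit. A decision value of
#' exactly 0 is `noise` (conservative tie-break).
#'
#' @param trajectory a `moth_trajectory` with >= `window_frames` frames.
#' @param model a `moth_classifier`.
#' @param window_frames feature window (default 10).
#' @param mode `"batch"` or `"sliding"`.
#' @return `"moth"` or `"noise"`.
#' @export
classify <- function(trajectory, model, window_frames = 10L,
                     mode = c("batch", "sliding")) {
  mode <- match.arg(mode)
  n <- length(trajectory$detections)
  if (n < window_frames)
    stop("trajectory shorter than the classification window")
  windows <- if (mode == "batch") n else window_frames:n
  for (end in windows) {
    sub <- trajectory
    sub$detections <- trajectory$detections[(end - window_frames + 1L):end]
    f <- extract_features(sub, window_frames)
    if (decision_value(model, f) <= 0) return("noise")
  }
  "moth"
}

#' Save / load a classifier as a small JSON record
#'
#' The model serialises to `{w1, w2, b, feature_means, feature_sds}`.
#'
#' @param model a `moth_classifier`.
#' @param path JSON file path.
#' @return `path` invisibly (save); a `moth_classifier` (load).
#' @export
save_classifier <- function(model, path) {
  rec <- list(w1 = model$weights[1], w2 = model$weights[2], b = model$bias,
              feature_means = model$feature_means,
              feature_sds = model$feature_sds)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = c(rec$w1, rec$w2), bias = rec$b,
         feature_means = rec$feature_means, feature_sds = rec$feature_sds,
         feature_names = c("sd_position_m", "sd_turning_deg")),
    class = "moth_classifier")
}
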