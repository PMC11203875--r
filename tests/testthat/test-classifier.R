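# Loop-based independent recomputation of the two features, straight
# from their definitions.
features_by_hand <- function(cent) {
  mu <- colMeans(cent)
  sd_pos <- sqrt(mean(apply(cent, 1, function(p) sum((p - mu)^2))))
  angles <- c()
  for (i in 2:(nrow(cent) - 1)) {
    a <- cent[i, ] - cent[i - 1, ]; b <- cent[i + 1, ] - cent[i, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    ang <- if (na == 0 || nb == 0) 0 else
      acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
    angles <- c(angles, ang)
  }
  c(sd_pos, sqrt(mean((angles - mean(angles))^2)))
}

test_that("features match an independent recomputation on a fixed path", {
  cent <- rbind(c(0.00, 0.00, 2.00), c(0.03, 0.01, 2.02),
                c(0.07, 0.00, 2.03), c(0.10, -0.02, 2.06),
                c(0.12, -0.01, 2.10), c(0.15, 0.02, 2.12),
                c(0.19, 0.05, 2.11), c(0.22, 0.06, 2.14),
                c(0.24, 0.05, 2.18), c(0.28, 0.03, 2.20))
  f <- extract_features(make_traj(cent), 10L)
  expect_equal(unname(f), features_by_hand(cent), tolerance = 1e-12)
})

test_that("degenerate windows hit the documented conventions", {
  stationary <- make_traj(matrix(rep(c(0.1, 0.2, 1.5), 10), 10, byrow = TRUE))
  f <- extract_features(stationary, 10L)
  expect_equal(unname(f), c(0, 0))
  straight <- make_traj(cbind(0.02 * (1:10), 0, 2))
  f2 <- extract_features(straight, 10L)
  expect_gt(f2["sd_position_m"], 0)
  expect_equal(unname(f2["sd_turning_deg"]), 0)
  expect_error(extract_features(make_traj(smooth_path(5)), 10L), "required")
})

test_that("features are invariant under rigid motions", {
  set.seed(17)
  cent <- smooth_path(10)
  f0 <- extract_features(make_traj(cent), 10L)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    moved <- cent %*% t(Q) + matrix(rnorm(3), 10, 3, byrow = TRUE)
    expect_equal(extract_features(make_traj(moved), 10L), f0,
                 tolerance = 1e-9)
  }
})

test_that("training errors on a single class and is reproducible", {
  sim <- simulate_labeled_trajectories(20, 20, seed = 5)
  feats <- t(vapply(sim$trajectories, extract_features, numeric(2)))
  expect_error(train_classifier(feats, rep("moth", nrow(feats))), "class")
  m1 <- train_classifier(feats, sim$labels, seed = 3)
  m2 <- train_classifier(feats, sim$labels, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
  # a separable set is fit exactly
  pred <- ifelse(decision_value(m1, feats) > 0, "moth", "noise")
  expect_equal(mean(pred == sim$labels), 1)
})

test_that("moth and reciprocating-noise trajectories classify correctly", {
  model <- train_default_classifier(n_per_class = 60L, seed = 0)
  heldout <- simulate_labeled_trajectories(40, 40, seed = 1234)
  pred <- vapply(heldout$trajectories, classify, character(1), model = model)
  expect_gte(mean(pred == heldout$labels), 0.95)
  # noise trajectories barely move
  for (i in which(heldout$labels == "noise")) {
    cent <- trajectory_centroids(heldout$trajectories[[i]])
    expect_lt(sqrt(sum((cent[nrow(cent), ] - cent[1, ])^2)), 0.05)
  }
})

test_that("a zero decision value is conservatively labelled noise", {
  degenerate <- structure(
    list(weights = c(0, 0), bias = 0, feature_means = c(0, 0),
         feature_sds = c(1, 1),
         feature_names = c("sd_position_m", "sd_turning_deg")),
    class = "moth_classifier")
  expect_identical(classify(make_traj(smooth_path(12)), degenerate), "noise")
})

test_that("the model serialises to JSON and back without loss", {
  m <- train_default_classifier(n_per_class = 30L, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, f)
  back <- load_classifier(f)
  expect_equal(back$weights, m$weights)
  expect_equal(back$bias, m$bias)
  expect_equal(back$feature_means, m$feature_means)
  expect_equal(back$feature_sds, m$feature_sds)
  tr <- make_traj(smooth_path(15))
  expect_identical(classify(tr, back), classify(tr, m))
})
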