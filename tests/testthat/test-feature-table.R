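test_that("read_session reports a missing dialect column by name", {
  sess <- simulate_session("P01", "infant", seed = 2L)
  dir <- withr::local_tempdir()
  paths <- write_session(sess$schedule, sess$frames, dir)
  tab <- utils::read.csv(paths$features[[1L]])
  tab$pose_Ry <- NULL
  utils::write.csv(tab, paths$features[[1L]], row.names = FALSE)
  expect_error(read_session(paths$features, paths$stimulus_log), "pose_Ry")
})

test_that("malformed rows are reported with line numbers and dropped", {
  sess <- simulate_session("P01", "infant", seed = 2L)
  dir <- withr::local_tempdir()
  paths <- write_session(sess$schedule, sess$frames, dir)
  lines <- readLines(paths$features[[1L]])
  lines[5L] <- gsub("^([^,]*,[^,]*,[^,]*),[^,]*", "\\1,not_a_number", lines[5L])
  writeLines(lines, paths$features[[1L]])
  expect_warning(out <- read_session(paths$features, paths$stimulus_log),
                 "line\\(s\\) 5")
  expect_equal(nrow(out$frames[["P01"]]), nrow(sess$frames) - 1L)
})

test_that("extract_trial_vector matches the nearest frame and flags misses", {
  trial <- data.frame(onset_time_s = 10)
  fr <- frames_with_yaw(c(11.0, 12.0, 12.4), c(0.1, 0.2, 0.3))
  hit <- extract_trial_vector(fr, trial, offset_s = 2, tol_s = 0.05)
  expect_true(hit$valid)
  expect_equal(unname(hit$values["pose_Ry"]), 0.2)

  miss <- extract_trial_vector(frames_with_yaw(c(11.0, 13.5), c(0.1, 0.2)),
                               trial, offset_s = 2, tol_s = 0.2)
  expect_false(miss$valid)
  expect_true(all(is.na(miss$values)))

  # two equidistant frames: the earlier one wins
  tie <- extract_trial_vector(frames_with_yaw(c(11.9, 12.1), c(0.7, -0.7)),
                              trial, offset_s = 2, tol_s = 0.2)
  expect_equal(unname(tie$values["pose_Ry"]), 0.7)
})

test_that("the count of valid plus invalid vectors equals the trial count", {
  p <- response_model_params("toddler", missing_frame_prob = 0.5)
  sess <- simulate_session("P05", "toddler", params = p, seed = 9L)
  tt <- build_trial_table(sess$frames, sess$schedule)
  expect_equal(sum(tt$valid) + sum(!tt$valid), nrow(sess$schedule))
  expect_true(all(is.na(as.matrix(tt[!tt$valid, openface_feature_columns()]))))
})

test_that("select_features is the documented pure projection", {
  v <- stats::setNames(stats::rnorm(n_features()), openface_feature_columns())
  v["pose_Ry"] <- 0.3; v["pose_Rx"] <- -0.1
  expect_equal(select_features(v, "head_rot"), c(0.3, -0.1))
  expect_equal(select_features(v, "gaze_left"),
               unname(v[c("gaze_0_x", "gaze_0_y")]))
  expect_equal(select_features(v, "gaze_angle"),
               unname(v[c("gaze_angle_x", "gaze_angle_y")]))
  # pure in the unrelated coordinates
  v2 <- v
  v2[grep("^AU", names(v2))] <- 99
  expect_equal(select_features(v2, "head_rot"), select_features(v, "head_rot"))
  expect_error(select_features(v, "pca2"), "PCA")
})

test_that("fit_pca agrees with an independent eigendecomposition oracle", {
  x <- withr::with_seed(11L, matrix(stats::rnorm(10 * n_features()), 10L))
  colnames(x) <- openface_feature_columns()
  pca <- fit_pca(x)
  # oracle: eigenvectors of the covariance of the z-scored matrix
  xs <- scale(x)
  e <- eigen(stats::cov(xs), symmetric = TRUE)
  for (k in 1:2) {
    got <- xs %*% pca$loadings[k, ]
    want <- xs %*% e$vectors[, k]
    expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-8)
  }
  expect_gte(pca$sdev[1L], pca$sdev[2L])
  # loading rows orthonormal; projected training data centred
  expect_equal(unname(tcrossprod(pca$loadings)), diag(2), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(project_pca(pca, x)))), 1e-8)
})

test_that("rank-2 data are perfectly reconstructed from two components", {
  withr::with_seed(3L, {
    basis <- qr.Q(qr(matrix(stats::rnorm(n_features() * 2L), ncol = 2L)))
    scores <- matrix(stats::rnorm(40L), 20L, 2L) %*% diag(c(3, 1))
    x <- scores %*% t(basis)
  })
  colnames(x) <- openface_feature_columns()
  pca <- fit_pca(x, scale. = FALSE)
  proj <- project_pca(pca, x)
  recon <- proj %*% pca$loadings
  resid <- scale(x, center = pca$center, scale = FALSE) - recon
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("a constant feature gets unit scale with a warning", {
  x <- withr::with_seed(4L, matrix(stats::rnorm(10 * n_features()), 10L))
  colnames(x) <- openface_feature_columns()
  x[, "AU01_r"] <- 5
  expect_warning(pca <- fit_pca(x), "constant")
  expect_equal(unname(pca$scale[colnames(x) == "AU01_r"]), 1)
})

test_that("PCA projection of the centering vector itself is the origin", {
  x <- withr::with_seed(5L, matrix(stats::rnorm(12 * n_features()), 12L))
  colnames(x) <- openface_feature_columns()
  pca <- fit_pca(x)
  expect_equal(drop(project_pca(pca, matrix(pca$center, nrow = 1L))), c(0, 0),
               tolerance = 1e-12)
})

test_that("the yaw timecourse reproduces a known single-trial bump exactly", {
  trial <- data.frame(participant_id = "P01", group = "toddler",
                      onset_time_s = 0)
  # one frame per 0.1-s bin, placed at the bin centres
  ts <- seq(-0.95, 4.95, by = 0.1)
  yaw <- 0.4 * sin(pmax(0, ts))
  tc <- mean_abs_yaw_timecourse(frames_with_yaw(ts, yaw), trial, bin_s = 0.1)
  expect_equal(tc$mean_abs_yaw, abs(yaw), tolerance = 1e-12)

  zero <- mean_abs_yaw_timecourse(frames_with_yaw(ts, 0 * ts), trial, bin_s = 0.1)
  expect_true(all(zero$mean_abs_yaw == 0))
})

test_that("a 58-participant cohort with 20 missing extraction frames yields 560 valid cases", {
  cfg <- pipeline_config(
    seed = 10L,
    infant_params = response_model_params("infant", missing_frame_prob = 0),
    toddler_params = response_model_params("toddler", missing_frame_prob = 0)
  )
  data <- latreact:::simulate_cohort(cfg)
  expect_equal(nrow(data$schedule), 580L)
  # remove the extraction frame of 20 deterministic trials
  drop <- data$schedule[seq(1L, 580L, by = 29L), ]
  for (i in seq_len(nrow(drop))) {
    pid <- drop$participant_id[i]
    ft <- data$frames[[pid]]
    target <- drop$onset_time_s[i] + 2
    data$frames[[pid]] <- ft[-which.min(abs(ft$timestamp - target)), ]
  }
  tt <- build_trial_table(data$frames, data$schedule)
  expect_equal(sum(tt$valid), 560L)
  expect_equal(sum(!tt$valid), 20L)
})
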