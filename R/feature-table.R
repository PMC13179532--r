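#' Read OpenFace-dialect feature tables and a stimulus log
#'
#' Parses one feature CSV per participant plus the session stimulus log.
#' Every required column of the dialect must be present; rows whose
#' feature values fail to parse as finite numbers are reported with their
#' file line numbers and dropped.
#'
#' @param features_csv Character vector of feature CSV paths, optionally
#'   named by participant id (otherwise ids are derived from file names
#'   by stripping an `_openface.csv` suffix).
#' @param stimulus_csv Path to the stimulus-log CSV (columns
#'   `participant_id`, `group`, `trial_index`, `stimulus`, `side`,
#'   `onset_time_s`).
#' @return List with `frames` (named list of per-participant frame
#'   tables) and `schedule` (stimulus schedule `data.frame`).
#' @export
read_session <- function(features_csv, stimulus_csv) {
  if (!file.exists(stimulus_csv)) stop_input("stimulus log not found: ", stimulus_csv)
  schedule <- utils::read.csv(stimulus_csv, stringsAsFactors = FALSE)
  req <- c("participant_id", "group", "trial_index", "stimulus", "side",
           "onset_time_s")
  miss <- setdiff(req, names(schedule))
  if (length(miss)) {
    stop_input("stimulus log missing required column(s): ",
               paste(miss, collapse = ", "))
  }
  schedule$participant_id <- as.character(schedule$participant_id)
  class(schedule) <- c("stimulus_schedule", "data.frame")

  ids <- names(features_csv)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- sub("_openface\\.csv$", "", basename(features_csv))
  }
  frames <- stats::setNames(lapply(seq_along(features_csv), function(i) {
    path <- features_csv[[i]]
    if (!file.exists(path)) stop_input("feature table not found: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(openface_columns(), names(tab))
    if (length(miss)) {
      stop_input("feature table ", basename(path),
                 " missing required column(s): ", paste(miss, collapse = ", "))
    }
    num <- openface_feature_columns()
    vals <- suppressWarnings(
      vapply(tab[num], function(x) as.numeric(x), numeric(nrow(tab)))
    )
    if (nrow(tab) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, num))
    bad <- !stats::complete.cases(vals) |
      !is.finite(suppressWarnings(as.numeric(tab$timestamp)))
    if (any(bad)) {
      warning(sprintf("%s: dropping %d malformed row(s) at line(s) %s",
                      basename(path), sum(bad),
                      paste(which(bad) + 1L, collapse = ", ")),
              call. = FALSE)
      tab <- tab[!bad, , drop = FALSE]
      vals <- vals[!bad, , drop = FALSE]
    }
    tab[num] <- as.data.frame(vals)
    tab$timestamp <- as.numeric(tab$timestamp)
    tab[order(tab$timestamp), , drop = FALSE]
  }), ids)
  list(frames = frames, schedule = schedule)
}

#' Extract the single analysis frame for one trial
#'
#' Selects the frame nearest `onset + offset_s` (the pipeline analyses a
#' single frame 2 s after stimulus onset). If no frame lies within
#' `tol_s` of the target time, the trial is marked invalid -- emulating
#' recordings where no face was tracked at the extraction point. When two
#' frames are equidistant the earlier one is chosen.
#'
#' @param frames Frame table for the trial's participant, sorted by
#'   timestamp.
#' @param trial One-row `data.frame` with at least `onset_time_s`.
#' @param offset_s Extraction delay after onset (default 2 s).
#' @param tol_s Matching tolerance; defaults to half the median frame
#'   interval of `frames`.
#' @return List of class `trial_feature_vector`: `trial`, `values`
#'   (named 55-vector, `NA` when invalid), `valid`.
#' @export
extract_trial_vector <- function(frames, trial, offset_s = 2, tol_s = NULL) {
  ts <- frames$timestamp
  if (is.unsorted(ts)) stop_input("'frames' must be sorted by timestamp")
  if (is.null(tol_s)) {
    tol_s <- if (length(ts) > 1L) stats::median(diff(ts)) / 2 else Inf
  }
  target <- trial$onset_time_s[1L] + offset_s
  feat <- openface_feature_columns()
  valid <- FALSE
  values <- stats::setNames(rep(NA_real_, n_features()), feat)
  if (length(ts)) {
    d <- abs(ts - target)
    i <- which.min(d)  # ties resolve to the earlier frame (sorted input)
    if (d[i] <= tol_s + 1e-12) {
      valid <- TRUE
      values <- stats::setNames(as.numeric(frames[i, feat]), feat)
    }
  }
  structure(list(trial = trial, values = values, valid = valid),
            class = "trial_feature_vector")
}

#' Build the per-trial feature table for a session or cohort
#'
#' Applies [extract_trial_vector()] to every scheduled trial and returns
#' one row per trial: participant metadata, validity flag, and the 55
#' feature values at the extraction frame.
#'
#' @param frames Named list of per-participant frame tables (as returned
#'   by [read_session()], or a single participant's table).
#' @param schedule Stimulus schedule covering the participants.
#' @param offset_s,tol_s Passed to [extract_trial_vector()].
#' @param flip_yaw If `TRUE`, negate the horizontal (left/right-encoding)
#'   coordinates (`pose_Ry`, gaze x components) to accommodate mirrored
#'   OpenFace output.
#' @return `data.frame` with columns `participant_id`, `group`,
#'   `trial_index`, `stimulus`, `side`, `valid`, then the 55 features.
#' @export
build_trial_table <- function(frames, schedule, offset_s = 2, tol_s = NULL,
                              flip_yaw = FALSE) {
  if (is.data.frame(frames)) {
    frames <- stats::setNames(list(frames), unique(schedule$participant_id)[1L])
  }
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    trial <- schedule[i, ]
    ft <- frames[[trial$participant_id]]
    if (is.null(ft)) stop_input("no frame table for participant ", trial$participant_id)
    v <- extract_trial_vector(ft, trial, offset_s = offset_s, tol_s = tol_s)
    c(list(valid = v$valid), as.list(v$values))
  })
  feat <- do.call(rbind, lapply(rows, as.data.frame))
  out <- cbind(
    schedule[, c("participant_id", "group", "trial_index", "stimulus", "side"),
             drop = FALSE],
    feat
  )
  rownames(out) <- NULL
  if (flip_yaw) {
    for (cn in horizontal_feature_columns()) out[[cn]] <- -out[[cn]]
  }
  out
}

#' The four 2-D feature sets
#'
#' The analysis reduces each trial's 55 features to two dimensions in
#' four ways: head rotation (yaw, pitch), left-eye gaze direction in
#' world coordinates (x, y), gaze angles averaged across both eyes
#' (horizontal, vertical), and the first two principal components of all
#' 55 features.
#'
#' @return Character vector of the feature-set codes.
#' @export
feature_sets <- function() {
  c("head_rot", "gaze_left", "gaze_angle", "pca2")
}

#' Project a trial feature vector onto a 2-D feature set
#'
#' @param values Named 55-feature vector (see
#'   [openface_feature_columns()]), or the `values` element of a
#'   [extract_trial_vector()] result.
#' @param feature_set One of [feature_sets()].
#' @param pca A [fit_pca()] projection; required iff
#'   `feature_set = "pca2"`.
#' @return Numeric length-2 vector (axis1, axis2); axis1 is the
#'   left/right-encoding coordinate for the three direct sets.
#' @export
select_features <- function(values, feature_set = feature_sets(), pca = NULL) {
  feature_set <- match.arg(feature_set)
  if (inherits(values, "trial_feature_vector")) values <- values$values
  switch(feature_set,
    head_rot  = unname(values[c("pose_Ry", "pose_Rx")]),
    gaze_left = unname(values[c("gaze_0_x", "gaze_0_y")]),
    gaze_angle = unname(values[c("gaze_angle_x", "gaze_angle_y")]),
    pca2 = {
      if (is.null(pca)) stop_input("feature set 'pca2' requires a fitted PCA projection")
      drop(project_pca(pca, matrix(values[openface_feature_columns()], nrow = 1L)))
    }
  )
}

#' Build the n x 2 point matrix for a feature set
#'
#' Vectorised companion of [select_features()] operating on the valid
#' rows of a [build_trial_table()] table.
#'
#' @param trial_table A [build_trial_table()] table (valid rows only are
#'   used by callers; invalid rows carry `NA` features).
#' @inheritParams select_features
#' @return Numeric matrix with one row per row of `trial_table`.
#' @export
select_feature_matrix <- function(trial_table, feature_set = feature_sets(),
                                  pca = NULL) {
  feature_set <- match.arg(feature_set)
  if (feature_set == "pca2") {
    if (is.null(pca)) stop_input("feature set 'pca2' requires a fitted PCA projection")
    return(project_pca(pca, as.matrix(trial_table[, openface_feature_columns()])))
  }
  cols <- switch(feature_set,
    head_rot  = c("pose_Ry", "pose_Rx"),
    gaze_left = c("gaze_0_x", "gaze_0_y"),
    gaze_angle = c("gaze_angle_x", "gaze_angle_y")
  )
  unname(as.matrix(trial_table[, cols]))
}

#' Fit a standardised 2-component PCA projection
#'
#' Features are z-scored (centred and scaled to unit variance) before the
#' principal axes are computed, since the 55 features mix radians,
#' millimetres and dimensionless action-unit activations; unscaled PCA
#' would be dominated by head position. A constant feature's scale is set
#' to 1 with a warning. The projection should be fitted on the training
#' split only and applied unchanged to validation data.
#'
#' @param x Numeric matrix (n x 55) of training feature vectors, or a
#'   [build_trial_table()] table (valid rows are used).
#' @param scale. If `FALSE`, skip the z-scoring (centering always
#'   applied).
#' @return Object of class `pca_projection`: `center`, `scale` (length
#'   55), `loadings` (2 x 55, orthonormal rows), `sdev` (length 2).
#' @export
fit_pca <- function(x, scale. = TRUE) {
  if (is.data.frame(x) && "valid" %in% names(x)) {
    x <- as.matrix(x[x$valid, openface_feature_columns()])
  }
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_input("PCA requires at least 3 training vectors")
  ctr <- colMeans(x)
  scl <- if (isTRUE(scale.)) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  if (any(scl == 0)) {
    warning(sprintf("%d constant feature(s); scale set to 1", sum(scl == 0)),
            call. = FALSE)
    scl[scl == 0] <- 1
  }
  xs <- scale(x, center = ctr, scale = scl)
  pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  structure(
    list(center = ctr, scale = scl,
         loadings = t(pr$rotation[, 1:2, drop = FALSE]),
         sdev = pr$sdev[1:2]),
    class = "pca_projection"
  )
}

#' @rdname fit_pca
#' @param pca A `pca_projection`.
#' @param newdata Numeric matrix (n x 55) to project.
#' @return `project_pca`: numeric matrix (n x 2) of PC scores.
#' @export
project_pca <- function(pca, newdata) {
  stopifnot(inherits(pca, "pca_projection"))
  newdata <- as.matrix(newdata)
  xs <- scale(newdata, center = pca$center, scale = pca$scale)
  unname(xs %*% t(pca$loadings))
}

#' Mean absolute head-yaw timecourse around stimulus onset
#'
#' For every trial, frames within `window` of the trial onset are binned
#' by time-from-onset; the curve is the across-trials mean of |yaw| per
#' bin, computed separately per group. This is the analysis used to
#' choose the single-frame extraction delay: the toddler curve rises from
#' a ~10 degree off-centre baseline to its maximum 2--3 s after onset.
#'
#' @param frames Named list of per-participant frame tables (or a single
#'   table).
#' @param schedule Stimulus schedule covering the trials.
#' @param window Length-2 numeric, seconds relative to onset.
#' @param bin_s Bin width in seconds.
#' @return `data.frame` with columns `group`, `time_s` (bin centre),
#'   `mean_abs_yaw`, `n_frames`; bins with no frames are absent.
#' @export
mean_abs_yaw_timecourse <- function(frames, schedule, window = c(-1, 5),
                                    bin_s = 0.1) {
  if (nrow(schedule) < 1L) stop_input("at least one trial is required")
  if (is.data.frame(frames)) {
    frames <- stats::setNames(list(frames), unique(schedule$participant_id)[1L])
  }
  pieces <- lapply(seq_len(nrow(schedule)), function(i) {
    trial <- schedule[i, ]
    ft <- frames[[trial$participant_id]]
    t_rel <- ft$timestamp - trial$onset_time_s
    keep <- t_rel >= window[1L] & t_rel <= window[2L]
    if (!any(keep)) return(NULL)
    data.frame(group = trial$group, t_rel = t_rel[keep],
               abs_yaw = abs(ft$pose_Ry[keep]))
  })
  all <- do.call(rbind, pieces)
  if (is.null(all)) stop_input("no frames fall inside the analysis window")
  all$bin <- floor((all$t_rel - window[1L]) / bin_s)
  agg <- stats::aggregate(abs_yaw ~ group + bin, data = all,
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(
    group = agg$group,
    time_s = window[1L] + (agg$bin + 0.5) * bin_s,
    mean_abs_yaw = agg$abs_yaw[, 1L],
    n_frames = as.integer(agg$abs_yaw[, 2L])
  )
  out[order(out$group, out$time_s), , drop = FALSE]
}
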