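#' OpenFace-dialect feature columns
#'
#' The pipeline consumes per-frame feature tables in the column dialect of
#' OpenFace 2.x: an index/bookkeeping prefix (`frame`, `timestamp`,
#' `success`) followed by 55 behavioural features per frame -- 8 gaze
#' features (unit gaze direction vectors for each eye in world coordinates,
#' plus horizontal/vertical gaze angles averaged across the two eyes, in
#' radians), 6 head-pose features (position in millimetres, rotation in
#' radians: `pose_Rx` pitch, `pose_Ry` yaw, `pose_Rz` roll), 6 rigid
#' head-shape parameters, and 35 facial action-unit activation estimates.
#'
#' `openface_feature_columns()` returns the 55 feature column names in
#' canonical order; `openface_columns()` prepends the bookkeeping columns.
#' This order defines the layout of every 55-vector in the package
#' (per-trial feature vectors, PCA loadings).
#'
#' @return Character vector of column names.
#' @examples
#' length(openface_feature_columns()) # 55
#' @export
openface_feature_columns <- function() {
  c(
    paste0("gaze_0_", c("x", "y", "z")),
    paste0("gaze_1_", c("x", "y", "z")),
    "gaze_angle_x", "gaze_angle_y",
    paste0("pose_", c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")),
    c("p_scale", "p_rx", "p_ry", "p_rz", "p_tx", "p_ty"),
    au_columns()
  )
}

#' @rdname openface_feature_columns
#' @export
openface_columns <- function() {
  c("frame", "timestamp", "success", openface_feature_columns())
}

# 35 AU activation columns, AU01_r .. AU34_r plus AU45_r (blink).
au_columns <- function() {
  sprintf("AU%02d_r", c(1:34, 45))
}

#' @rdname openface_feature_columns
#' @export
n_features <- function() 55L

# Indices (within the 55-feature vector) of the left/right-encoding
# horizontal coordinates, negated by the flip_yaw ingest option.
horizontal_feature_columns <- function() {
  c("gaze_0_x", "gaze_1_x", "gaze_angle_x", "pose_Ry")
}
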