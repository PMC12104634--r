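#' COCO-17 keypoint vocabulary
#'
#' The fixed set of 17 named body keypoints (COCO order) that every pose
#' detection row must use. Pose estimators for multi-person RGB video emit
#' these joints; the activity classifier only ever consults the wrists, the
#' shoulders and the five head points (nose, eyes, ears). Leg joints are
#' carried through unchanged but never enter any classification rule: under
#' surgical gowns and a ceiling camera they are unreliable.
#'
#' @return Character vector of the 17 keypoint names, in COCO order.
#' @export
#' @examples
#' coco_keypoints()
coco_keypoints <- function() {
  c(
    "nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle"
  )
}

#' Keypoint subsets used by the activity rules
#'
#' @return Character vector of keypoint names.
#' @export
head_keypoints <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear")
}

#' @rdname head_keypoints
#' @export
wrist_keypoints <- function() c("left_wrist", "right_wrist")

#' @rdname head_keypoints
#' @export
shoulder_keypoints <- function() c("left_shoulder", "right_shoulder")

# internal: validate a long pose tibble (frame, <id col>, keypoint, x, y,
# confidence). Coordinates are image pixels, origin top-left, y downward,
# frames 0-based.
validate_poses <- function(poses, id_col = "det", what = "detections") {
  assert_columns(poses, c("frame", id_col, "keypoint", "x", "y", "confidence"), what)
  bad_kp <- setdiff(unique(poses$keypoint), coco_keypoints())
  if (length(bad_kp) > 0L) {
    abort(sprintf(
      "%s contains unknown keypoint name(s): %s",
      what, paste(bad_kp, collapse = ", ")
    ))
  }
  if (nrow(poses) > 0L) {
    if (any(poses$frame < 0 | poses$frame != floor(poses$frame))) {
      abort(sprintf("%s: `frame` must contain non-negative integers", what))
    }
    if (any(!is.finite(poses$x)) || any(!is.finite(poses$y))) {
      abort(sprintf("%s: keypoint coordinates must be finite", what))
    }
    conf <- poses$confidence[!is.na(poses$confidence)]
    if (any(conf < 0 | conf > 1)) {
      abort(sprintf("%s: `confidence` must lie in [0, 1]", what))
    }
    dup <- poses %>%
      count(.data$frame, .data[[id_col]], .data$keypoint) %>%
      filter(n > 1L)
    if (nrow(dup) > 0L) {
      abort(sprintf(
        "%s: duplicated keypoint rows (first at frame %s, %s %s, keypoint %s)",
        what, dup$frame[1], id_col, dup[[id_col]][1], dup$keypoint[1]
      ))
    }
  }
  invisible(poses)
}
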