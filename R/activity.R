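#' Activity-classifier parameters
#'
#' A person is "active at the operating table" in a frame when both wrists
#' lie in the wrist (table) zone, both shoulders in the shoulder zone, the
#' head centroid in the head zone, AND the upper body is not translating:
#' if the shoulder/head displacement over the preceding `window` frames
#' exceeds `displacement_threshold` pixels the frame is vetoed as
#' walking-past. Wrist motion never enters the veto (wrists are expected to
#' move during activity) and leg keypoints never enter any rule.
#'
#' @param displacement_threshold Movement veto threshold in pixels over the
#'   window; the veto fires only when the displacement strictly exceeds it.
#'   Default 17.5 px over 5 frames.
#' @param window Displacement window in frames (endpoint-to-endpoint, not
#'   path length).
#' @param min_confidence Minimum keypoint confidence for a keypoint to
#'   count as present. The instrument-side rules treat lower-confidence
#'   keypoints as missing.
#' @param aggregate How the shoulder/head displacements are combined:
#'   `"mean"` (default, robust to single-point noise) or `"max"`.
#' @return An `activity_params` list.
#' @export
activity_params <- function(displacement_threshold = 17.5, window = 5L,
                            min_confidence = 0.3,
                            aggregate = c("mean", "max")) {
  assert_number(displacement_threshold, "displacement_threshold",
                lower = 0, strict_lower = TRUE)
  assert_count(window, "window", min = 1L)
  assert_number(min_confidence, "min_confidence", lower = 0, upper = 1)
  aggregate <- match.arg(aggregate)
  structure(
    list(displacement_threshold = displacement_threshold,
         window = as.integer(window), min_confidence = min_confidence,
         aggregate = aggregate),
    class = "activity_params"
  )
}

#' Head centroid of a pose
#'
#' Centroid of the present head keypoints (nose, both eyes, both ears) with
#' confidence at or above `min_confidence`.
#'
#' @param pose Long pose tibble (`keypoint`, `x`, `y`, `confidence`) or
#'   17 x 3 matrix.
#' @param min_confidence Presence threshold.
#' @return Named numeric `c(x, y)`, or `NULL` when no head keypoint is
#'   present.
#' @export
#' @examples
#' p <- tibble::tibble(keypoint = c("nose", "left_eye"),
#'                     x = c(50, 54), y = c(40, 36), confidence = 1)
#' head_point(p)
head_point <- function(pose, min_confidence = 0.3) {
  m <- as_pose_matrix(pose)
  hk <- m[head_keypoints(), , drop = FALSE]
  ok <- !is.na(hk[, "x"]) & !is.na(hk[, "y"]) &
    (!is.na(hk[, "confidence"]) & hk[, "confidence"] >= min_confidence)
  if (!any(ok)) return(NULL)
  c(x = mean(hk[ok, "x"]), y = mean(hk[ok, "y"]))
}

#' Three-zone membership test for one pose
#'
#' `"pass"` iff both wrists are inside the wrist zone, both shoulders
#' inside the shoulder zone and the head centroid inside the head zone;
#' `"undetermined"` when any required keypoint (either wrist, either
#' shoulder, or the head centroid) is absent; `"fail"` otherwise. Requiring
#' the shoulder and head subsets mitigates camera perspective: a wrist of
#' a passer-by reaching over the table does not pass on its own.
#'
#' @param pose Long pose tibble or 17 x 3 matrix.
#' @param zones A [zone_set()].
#' @param min_confidence Presence threshold.
#' @return `"pass"`, `"fail"` or `"undetermined"`.
#' @export
zone_test <- function(pose, zones, min_confidence = 0.3) {
  m <- as_pose_matrix(pose)
  present <- function(k) {
    !is.na(m[k, "x"]) && !is.na(m[k, "y"]) &&
      !is.na(m[k, "confidence"]) && m[k, "confidence"] >= min_confidence
  }
  req <- c(wrist_keypoints(), shoulder_keypoints())
  hp <- head_point(m, min_confidence)
  if (!all(vapply(req, present, logical(1))) || is.null(hp)) {
    return("undetermined")
  }
  wrists_in <- all(point_in_zone(m[wrist_keypoints(), "x"],
                                 m[wrist_keypoints(), "y"], zones$wrist_zone))
  shoulders_in <- all(point_in_zone(m[shoulder_keypoints(), "x"],
                                    m[shoulder_keypoints(), "y"], zones$shoulder_zone))
  head_in <- point_in_zone(hp["x"], hp["y"], zones$head_zone)
  if (wrists_in && shoulders_in && head_in) "pass" else "fail"
}

#' Windowed upper-body displacement
#'
#' Displacement of the upper body between frame `t - window` and frame `t`:
#' the mean (or max) over left shoulder, right shoulder and head centroid
#' of the endpoint-to-endpoint Euclidean distance. Endpoint-to-endpoint
#' rather than path length: a windowed offset does not double-count
#' detector jitter.
#'
#' @param track_poses Long pose tibble of ONE track (`frame`, `keypoint`,
#'   `x`, `y`, `confidence`).
#' @param t Frame index at which to evaluate.
#' @param params An [activity_params()].
#' @return Displacement in pixels, or `NA` when either endpoint pose or any
#'   of the three upper-body points is unavailable (including the warm-up
#'   `t < window`).
#' @export
pose_displacement <- function(track_poses, t, params = activity_params()) {
  w <- params$window
  if (t < w) return(NA_real_)
  p1 <- track_poses %>% filter(.data$frame == t - w)
  p2 <- track_poses %>% filter(.data$frame == t)
  if (nrow(p1) == 0L || nrow(p2) == 0L) return(NA_real_)
  upper_body_displacement(
    as_pose_matrix(p1[, c("keypoint", "x", "y", "confidence")]),
    as_pose_matrix(p2[, c("keypoint", "x", "y", "confidence")]),
    params
  )
}

upper_body_displacement <- function(m1, m2, params) {
  h1 <- head_point(m1, params$min_confidence)
  h2 <- head_point(m2, params$min_confidence)
  sh <- shoulder_keypoints()
  ok <- function(m, k) {
    !is.na(m[k, "x"]) && !is.na(m[k, "confidence"]) &&
      m[k, "confidence"] >= params$min_confidence
  }
  if (is.null(h1) || is.null(h2) ||
      !all(vapply(sh, function(k) ok(m1, k) && ok(m2, k), logical(1)))) {
    return(NA_real_)
  }
  d <- c(
    euclid(m1["left_shoulder", "x"], m1["left_shoulder", "y"],
           m2["left_shoulder", "x"], m2["left_shoulder", "y"]),
    euclid(m1["right_shoulder", "x"], m1["right_shoulder", "y"],
           m2["right_shoulder", "x"], m2["right_shoulder", "y"]),
    euclid(h1["x"], h1["y"], h2["x"], h2["y"])
  )
  if (params$aggregate == "mean") mean(d) else max(d)
}

#' Classify per-frame table activity for tracked poses
#'
#' Vectorised frame-by-frame classification of every track:
#' \itemize{
#'   \item `active`: zone test passes AND displacement does not exceed the
#'     threshold (boundary equality counts as active — the veto fires only
#'     when the threshold is strictly exceeded);
#'   \item `inactive`: zone test fails, or displacement strictly exceeds
#'     the threshold (a definite rule fires even if the other test is
#'     unavailable);
#'   \item `undetermined`: otherwise — a required keypoint is missing or
#'     the displacement is unavailable (warm-up or a gap in the track).
#' }
#'
#' @param poses Long pose tibble with columns `track_id`, `frame`,
#'   `keypoint`, `x`, `y`, `confidence` (e.g. `build_tracks()$poses`, or
#'   ground-truth tracks with `person` renamed to `track_id`).
#' @param zones A [zone_set()].
#' @param params An [activity_params()].
#' @return An `activity_series` tibble: `track_id`, `frame`, `status`
#'   (`"active"`/`"inactive"`/`"undetermined"`), `zone` (pass/fail/
#'   undetermined), `displacement` (px, `NA` when unavailable).
#' @export
classify_activity <- function(poses, zones, params = activity_params()) {
  validate_poses(poses, id_col = "track_id", what = "poses")
  stopifnot(inherits(zones, "zone_set"))
  empty <- structure(
    tibble(track_id = integer(), frame = integer(),
           status = character(), zone = character(), displacement = double()),
    class = c("activity_series", "tbl_df", "tbl", "data.frame")
  )
  if (nrow(poses) == 0L) return(empty)

  present <- poses %>%
    filter(!is.na(.data$confidence) & .data$confidence >= params$min_confidence)

  # wide per (track, frame): required points + head centroid
  need <- c(wrist_keypoints(), shoulder_keypoints())
  wide <- present %>%
    filter(.data$keypoint %in% need) %>%
    select("track_id", "frame", "keypoint", "x", "y") %>%
    tidyr::pivot_wider(names_from = "keypoint", values_from = c("x", "y"))
  for (k in need) {
    for (ax in c("x", "y")) {
      cc <- paste0(ax, "_", k)
      if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
    }
  }
  heads <- present %>%
    filter(.data$keypoint %in% head_keypoints()) %>%
    group_by(.data$track_id, .data$frame) %>%
    summarise(head_x = mean(.data$x), head_y = mean(.data$y), .groups = "drop")
  all_frames <- poses %>% distinct(.data$track_id, .data$frame)
  wide <- all_frames %>%
    left_join(wide, by = c("track_id", "frame")) %>%
    left_join(heads, by = c("track_id", "frame"))

  # zone membership (boundary counts as inside)
  in_zone <- function(xs, ys, poly) {
    out <- rep(NA, length(xs))
    ok <- !is.na(xs) & !is.na(ys)
    if (any(ok)) out[ok] <- point_in_zone(xs[ok], ys[ok], poly)
    out
  }
  wide <- wide %>% mutate(
    lw_in = in_zone(.data$x_left_wrist, .data$y_left_wrist, zones$wrist_zone),
    rw_in = in_zone(.data$x_right_wrist, .data$y_right_wrist, zones$wrist_zone),
    ls_in = in_zone(.data$x_left_shoulder, .data$y_left_shoulder, zones$shoulder_zone),
    rs_in = in_zone(.data$x_right_shoulder, .data$y_right_shoulder, zones$shoulder_zone),
    hd_in = in_zone(.data$head_x, .data$head_y, zones$head_zone),
    required_present = !is.na(.data$lw_in) & !is.na(.data$rw_in) &
      !is.na(.data$ls_in) & !is.na(.data$rs_in) & !is.na(.data$hd_in),
    zone = case_when(
      !.data$required_present ~ "undetermined",
      .data$lw_in & .data$rw_in & .data$ls_in & .data$rs_in & .data$hd_in ~ "pass",
      TRUE ~ "fail"
    )
  )

  # displacement: join each (track, frame) with (track, frame - window)
  disp_pts <- wide %>%
    mutate(disp_ok = !is.na(.data$x_left_shoulder) & !is.na(.data$x_right_shoulder) &
             !is.na(.data$head_x)) %>%
    select("track_id", "frame", "disp_ok",
           "x_left_shoulder", "y_left_shoulder",
           "x_right_shoulder", "y_right_shoulder", "head_x", "head_y")
  prev <- disp_pts %>%
    mutate(frame = .data$frame + params$window) %>%
    rename(p_ok = "disp_ok", px_ls = "x_left_shoulder", py_ls = "y_left_shoulder",
           px_rs = "x_right_shoulder", py_rs = "y_right_shoulder",
           px_h = "head_x", py_h = "head_y")
  disp <- disp_pts %>%
    left_join(prev, by = c("track_id", "frame")) %>%
    mutate(
      d_ls = euclid(.data$x_left_shoulder, .data$y_left_shoulder, .data$px_ls, .data$py_ls),
      d_rs = euclid(.data$x_right_shoulder, .data$y_right_shoulder, .data$px_rs, .data$py_rs),
      d_h = euclid(.data$head_x, .data$head_y, .data$px_h, .data$py_h),
      displacement = dplyr::if_else(
        .data$disp_ok & !is.na(.data$p_ok) & .data$p_ok,
        if (params$aggregate == "mean") {
          (.data$d_ls + .data$d_rs + .data$d_h) / 3
        } else {
          pmax(.data$d_ls, .data$d_rs, .data$d_h)
        },
        NA_real_
      )
    ) %>%
    select("track_id", "frame", "displacement")

  out <- wide %>%
    left_join(disp, by = c("track_id", "frame")) %>%
    mutate(status = case_when(
      .data$zone == "fail" ~ "inactive",
      !is.na(.data$displacement) &
        .data$displacement > params$displacement_threshold ~ "inactive",
      .data$zone == "pass" & !is.na(.data$displacement) ~ "active",
      TRUE ~ "undetermined"
    )) %>%
    select("track_id", "frame", "status", "zone", "displacement") %>%
    arrange(.data$track_id, .data$frame)
  structure(out, class = c("activity_series", class(tibble())))
}

#' Intervals of consecutive active frames
#'
#' @param activity An `activity_series` tibble from [classify_activity()].
#' @return Tibble `track_id`, `start`, `end` (inclusive frame range),
#'   `n_frames`; the intervals exactly cover the active frames.
#' @export
activity_intervals <- function(activity) {
  assert_columns(activity, c("track_id", "frame", "status"), "activity")
  act <- activity %>% filter(.data$status == "active") %>%
    arrange(.data$track_id, .data$frame)
  if (nrow(act) == 0L) {
    return(tibble(track_id = integer(), start = integer(),
                  end = integer(), n_frames = integer()))
  }
  act %>%
    group_by(.data$track_id) %>%
    mutate(run = cumsum(c(1L, diff(.data$frame) != 1L))) %>%
    group_by(.data$track_id, .data$run) %>%
    summarise(start = min(.data$frame), end = max(.data$frame),
              n_frames = dplyr::n(), .groups = "drop") %>%
    select("track_id", "start", "end", "n_frames")
}
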