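#' Tracker parameters
#'
#' Two-stage, confidence-split association in the style of BYTE: detections
#' with score at or above `high_conf` are matched to existing tracks first
#' by optimal one-to-one assignment on pose similarity; remaining tracks are
#' then offered the low-confidence detections (score in
#' `[low_conf, high_conf)`), which recovers partially occluded staff without
#' letting weak detections spawn tracks. Defaults follow the conventions of
#' the published tracking method; none are dictated by the analysis itself
#' and all are exposed here.
#'
#' @param high_conf,low_conf Confidence split thresholds
#'   (`low_conf < high_conf`).
#' @param match_threshold Minimum pose similarity for an accepted match.
#' @param max_age Frames a track may remain unmatched before it is lost.
#' @param min_hits Matched frames before a tentative track is confirmed.
#' @param lambda Weight of the box-overlap term in [pose_similarity()].
#' @param bbox_margin Bounding-box expansion fraction used when matching.
#' @return A `tracker_params` list.
#' @export
tracker_params <- function(high_conf = 0.5, low_conf = 0.1,
                           match_threshold = 0.3, max_age = 30L,
                           min_hits = 3L, lambda = 0.5, bbox_margin = 0.1) {
  assert_number(high_conf, "high_conf", lower = 0, upper = 1)
  assert_number(low_conf, "low_conf", lower = 0, upper = 1)
  if (!(low_conf < high_conf)) abort("`low_conf` must be < `high_conf`")
  assert_number(match_threshold, "match_threshold", lower = 0, upper = 1)
  assert_count(max_age, "max_age", min = 1L)
  assert_count(min_hits, "min_hits", min = 1L)
  assert_number(lambda, "lambda", lower = 0, upper = 1)
  assert_number(bbox_margin, "bbox_margin", lower = 0)
  structure(
    list(high_conf = high_conf, low_conf = low_conf,
         match_threshold = match_threshold, max_age = as.integer(max_age),
         min_hits = as.integer(min_hits), lambda = lambda,
         bbox_margin = bbox_margin),
    class = "tracker_params"
  )
}

# internal canonical pose: 17 x 3 matrix (x, y, confidence), rownames =
# coco keypoints, NA x/y = keypoint absent
as_pose_matrix <- function(pose) {
  if (is.matrix(pose)) return(pose)
  assert_columns(pose, c("keypoint", "x", "y"), "pose")
  m <- matrix(NA_real_, nrow = 17L, ncol = 3L,
              dimnames = list(coco_keypoints(), c("x", "y", "confidence")))
  idx <- match(pose$keypoint, coco_keypoints())
  if (anyNA(idx)) abort("pose contains unknown keypoint names")
  m[idx, "x"] <- pose$x
  m[idx, "y"] <- pose$y
  m[idx, "confidence"] <- if ("confidence" %in% names(pose)) pose$confidence else NA_real_
  m
}

pose_score <- function(m) {
  conf <- m[!is.na(m[, "x"]), "confidence"]
  conf <- conf[!is.na(conf)]
  if (length(conf) == 0L) 0 else mean(conf)
}

#' Bounding box of a pose
#'
#' Tight axis-aligned box over the present keypoints, expanded on each side
#' by `margin` times the box extent in that dimension.
#'
#' @param pose A pose: long tibble (`keypoint`, `x`, `y`, `confidence`) or
#'   17 x 3 matrix.
#' @param margin Expansion fraction per side.
#' @return Named numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
#' @examples
#' p <- tibble::tibble(keypoint = c("nose", "left_wrist"),
#'                     x = c(0, 10), y = c(0, 20), confidence = 1)
#' pose_bbox(p)
pose_bbox <- function(pose, margin = 0) {
  m <- as_pose_matrix(pose)
  ok <- !is.na(m[, "x"]) & !is.na(m[, "y"])
  if (sum(ok) < 2L) abort("pose_bbox: need at least 2 present keypoints")
  x <- m[ok, "x"]; y <- m[ok, "y"]
  w <- diff(range(x)); h <- diff(range(y))
  c(xmin = min(x) - margin * w, ymin = min(y) - margin * h,
    xmax = max(x) + margin * w, ymax = max(y) + margin * h)
}

bbox_iou <- function(a, b) {
  ix <- max(0, min(a["xmax"], b["xmax"]) - max(a["xmin"], b["xmin"]))
  iy <- max(0, min(a["ymax"], b["ymax"]) - max(a["ymin"], b["ymin"]))
  inter <- ix * iy
  area_a <- (a["xmax"] - a["xmin"]) * (a["ymax"] - a["ymin"])
  area_b <- (b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"])
  denom <- area_a + area_b - inter
  unname(if (denom <= 0) 0 else inter / denom)
}

#' Pose-to-pose similarity
#'
#' Convex blend of box overlap and a keypoint-distance term in the style of
#' object keypoint similarity:
#' `lambda * IoU + (1 - lambda) * exp(-msd / (2 s^2))`, where `msd` is the
#' mean squared distance over keypoints present in both poses and `s` is
#' the mean bounding-box diagonal of the two poses. Symmetric; 1 for
#' identical poses; 0 when either pose has fewer than 2 present keypoints.
#'
#' @param a,b Poses (long tibble or 17 x 3 matrix).
#' @param lambda Box-overlap weight in [0, 1].
#' @param margin Bounding-box expansion fraction.
#' @return Similarity in [0, 1].
#' @export
pose_similarity <- function(a, b, lambda = 0.5, margin = 0) {
  a <- as_pose_matrix(a)
  b <- as_pose_matrix(b)
  ok_a <- !is.na(a[, "x"])
  ok_b <- !is.na(b[, "x"])
  if (sum(ok_a) < 2L || sum(ok_b) < 2L) return(0)
  box_a <- pose_bbox(a, margin)
  box_b <- pose_bbox(b, margin)
  iou <- bbox_iou(box_a, box_b)
  shared <- ok_a & ok_b
  if (!any(shared)) {
    kp_term <- 0
  } else {
    msd <- mean((a[shared, "x"] - b[shared, "x"])^2 +
                  (a[shared, "y"] - b[shared, "y"])^2)
    diag_a <- euclid(box_a["xmin"], box_a["ymin"], box_a["xmax"], box_a["ymax"])
    diag_b <- euclid(box_b["xmin"], box_b["ymin"], box_b["xmax"], box_b["ymax"])
    s <- (diag_a + diag_b) / 2
    kp_term <- if (s <= 0) as.numeric(msd == 0) else exp(-msd / (2 * s^2))
  }
  unname(lambda * iou + (1 - lambda) * kp_term)
}

# optimal one-to-one assignment maximizing total similarity, restricted to
# pairs at or above the match threshold; ties broken toward lower track
# index, then lower detection index, via an infinitesimal preference
solve_matching <- function(sim, threshold) {
  nr <- nrow(sim); nc <- ncol(sim)
  if (nr == 0L || nc == 0L) {
    return(tibble(row = integer(), col = integer(), similarity = double()))
  }
  eps <- 1e-9
  pref <- outer(seq_len(nr), seq_len(nc),
                function(i, j) (nr - i) / nr + (nc - j) / (nc * nr))
  adj <- ifelse(sim >= threshold, sim + eps * pref, 0)
  # pad to square for the LSAP solver
  n <- max(nr, nc)
  pad <- matrix(0, n, n)
  pad[seq_len(nr), seq_len(nc)] <- adj
  sol <- clue::solve_LSAP(pad, maximum = TRUE)
  rows <- seq_len(nr)
  cols <- as.integer(sol)[seq_len(nr)]
  keep <- cols <= nc & sim[cbind(rows, pmin(cols, nc))] >= threshold &
    adj[cbind(rows, pmin(cols, nc))] > 0
  tibble(row = rows[keep], col = cols[keep],
         similarity = sim[cbind(rows[keep], cols[keep])])
}

#' One frame of two-stage association
#'
#' @param track_poses Named list of last-observed poses of the active
#'   tracks (names = track ids).
#' @param det_poses List of detection poses from ONE frame.
#' @param params A [tracker_params()].
#' @return List with `matches` (tibble `track_id`, `det`, `similarity`,
#'   `stage`), `births` (indices of unmatched high-confidence detections)
#'   and `misses` (ids of unmatched tracks).
#' @export
associate <- function(track_poses, det_poses, params = tracker_params()) {
  track_poses <- purrr::map(track_poses, as_pose_matrix)
  det_poses <- purrr::map(det_poses, as_pose_matrix)
  scores <- purrr::map_dbl(det_poses, pose_score)
  high <- which(scores >= params$high_conf)
  low <- which(scores >= params$low_conf & scores < params$high_conf)
  track_ids <- names(track_poses) %||% as.character(seq_along(track_poses))

  sim_block <- function(tr_idx, det_idx) {
    outer_sim <- matrix(0, length(tr_idx), length(det_idx))
    for (i in seq_along(tr_idx)) {
      for (j in seq_along(det_idx)) {
        outer_sim[i, j] <- pose_similarity(
          track_poses[[tr_idx[i]]], det_poses[[det_idx[j]]],
          lambda = params$lambda, margin = params$bbox_margin
        )
      }
    }
    outer_sim
  }

  matches <- tibble(track_id = character(), det = integer(),
                    similarity = double(), stage = integer())
  remaining_tracks <- seq_along(track_poses)

  # stage 1: active tracks vs high-confidence detections
  if (length(remaining_tracks) > 0L && length(high) > 0L) {
    s1 <- sim_block(remaining_tracks, high)
    m1 <- solve_matching(s1, params$match_threshold)
    if (nrow(m1) > 0L) {
      matches <- bind_rows(matches, tibble(
        track_id = track_ids[remaining_tracks[m1$row]],
        det = high[m1$col], similarity = m1$similarity, stage = 1L
      ))
      remaining_tracks <- remaining_tracks[-m1$row]
      high_matched <- high[m1$col]
    } else {
      high_matched <- integer()
    }
  } else {
    high_matched <- integer()
  }

  # stage 2: still-unmatched tracks vs low-confidence detections
  if (length(remaining_tracks) > 0L && length(low) > 0L) {
    s2 <- sim_block(remaining_tracks, low)
    m2 <- solve_matching(s2, params$match_threshold)
    if (nrow(m2) > 0L) {
      matches <- bind_rows(matches, tibble(
        track_id = track_ids[remaining_tracks[m2$row]],
        det = low[m2$col], similarity = m2$similarity, stage = 2L
      ))
      remaining_tracks <- remaining_tracks[-m2$row]
    }
  }

  list(
    matches = matches,
    births = setdiff(high, high_matched),
    misses = track_ids[remaining_tracks]
  )
}

#' Build identity-stable tracks from a detection stream
#'
#' Runs the two-stage association frame by frame over a long detections
#' tibble. Unmatched high-confidence detections spawn tentative tracks; a
#' tentative track is confirmed after `min_hits` matched frames; a track
#' unseen for more than `max_age` frames is lost and no longer offered
#' detections. The last observed pose represents a track (no motion
#' prediction): operating-room staff move slowly relative to the frame
#' rate. Deterministic for a given input.
#'
#' @param detections Long detections tibble (`frame`, `det`, `keypoint`,
#'   `x`, `y`, `confidence`).
#' @param params A [tracker_params()].
#' @return An `or_tracks` object: list with
#'   \describe{
#'     \item{poses}{long tibble `track_id`, `frame`, `det`, `keypoint`,
#'       `x`, `y`, `confidence` of every assigned detection}
#'     \item{states}{per-track tibble: `track_id`, `state`
#'       (tentative/confirmed/lost), `n_hits`, `first_frame`, `last_frame`}
#'     \item{log}{per-frame association log (`frame`, `stage`, `track_id`,
#'       `det`, `similarity`)}
#'   }
#' @export
build_tracks <- function(detections, params = tracker_params()) {
  validate_poses(detections, id_col = "det", what = "detections")
  empty <- structure(list(
    poses = tibble(track_id = integer(), frame = integer(), det = integer(),
                   keypoint = character(), x = double(), y = double(),
                   confidence = double()),
    states = tibble(track_id = integer(), state = character(),
                    n_hits = integer(), first_frame = integer(),
                    last_frame = integer()),
    log = tibble(frame = integer(), stage = integer(), track_id = integer(),
                 det = integer(), similarity = double())
  ), class = "or_tracks")
  if (nrow(detections) == 0L) return(empty)

  frames <- sort(unique(detections$frame))
  det_by_frame <- split(detections, detections$frame)
  tracks <- list() # id -> list(pose, last_seen, hits, first_frame, confirmed, lost)
  next_id <- 1L
  assign_rows <- vector("list", length(frames))
  log_rows <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    df <- det_by_frame[[as.character(f)]]
    det_ids <- sort(unique(df$det))
    det_poses <- purrr::map(det_ids, function(d) {
      as_pose_matrix(df[df$det == d, c("keypoint", "x", "y", "confidence")])
    })

    active <- names(tracks)[!purrr::map_lgl(tracks, "lost")]
    track_poses <- purrr::map(tracks[active], "pose")
    res <- associate(track_poses, det_poses, params)

    if (nrow(res$matches) > 0L) {
      for (r in seq_len(nrow(res$matches))) {
        tid <- res$matches$track_id[r]
        di <- res$matches$det[r]
        tracks[[tid]]$pose <- det_poses[[di]]
        tracks[[tid]]$last_seen <- f
        tracks[[tid]]$hits <- tracks[[tid]]$hits + 1L
        if (tracks[[tid]]$hits >= params$min_hits) tracks[[tid]]$confirmed <- TRUE
      }
      assign_rows[[fi]] <- tibble(
        frame = f, det = det_ids[res$matches$det],
        track_id = as.integer(res$matches$track_id)
      )
      log_rows[[fi]] <- tibble(
        frame = f, stage = res$matches$stage,
        track_id = as.integer(res$matches$track_id),
        det = det_ids[res$matches$det], similarity = res$matches$similarity
      )
    }

    if (length(res$births) > 0L) {
      birth_rows <- tibble(frame = f, det = det_ids[res$births],
                           track_id = next_id + seq_along(res$births) - 1L)
      for (b in seq_along(res$births)) {
        tracks[[as.character(next_id)]] <- list(
          pose = det_poses[[res$births[b]]], last_seen = f, hits = 1L,
          first_frame = f, confirmed = params$min_hits <= 1L, lost = FALSE
        )
        next_id <- next_id + 1L
      }
      assign_rows[[fi]] <- bind_rows(assign_rows[[fi]], birth_rows)
    }

    for (tid in names(tracks)) {
      if (!tracks[[tid]]$lost && f - tracks[[tid]]$last_seen > params$max_age) {
        tracks[[tid]]$lost <- TRUE
      }
    }
  }

  assignment <- bind_rows(assign_rows)
  poses <- detections %>%
    inner_join(assignment, by = c("frame", "det")) %>%
    select("track_id", "frame", "det", "keypoint", "x", "y", "confidence") %>%
    arrange(.data$track_id, .data$frame)
  states <- tibble(
    track_id = as.integer(names(tracks)),
    state = purrr::map_chr(tracks, function(t) {
      if (t$confirmed && !t$lost) "confirmed"
      else if (t$lost && t$confirmed) "lost"
      else if (t$lost) "lost"
      else "tentative"
    }),
    ever_confirmed = purrr::map_lgl(tracks, "confirmed"),
    n_hits = purrr::map_int(tracks, "hits"),
    first_frame = purrr::map_int(tracks, "first_frame"),
    last_frame = purrr::map_int(tracks, "last_seen")
  ) %>% arrange(.data$track_id)
  structure(list(poses = poses, states = states, log = bind_rows(log_rows)),
            class = "or_tracks")
}

#' @export
print.or_tracks <- function(x, ...) {
  cat(sprintf(
    "<or_tracks> %d tracks (%d confirmed), %d assigned detections\n",
    nrow(x$states), sum(x$states$ever_confirmed),
    nrow(dplyr::distinct(x$poses, .data$frame, .data$det))
  ))
  invisible(x)
}
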