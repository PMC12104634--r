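#' Configure a synthetic operating-room scene
#'
#' The scene simulator emulates the single annotated ceiling-camera view of
#' an operating room: `n_staff` persons move between a home position at the
#' image border and standing slots around the operating table, where the
#' three zone polygons are annotated. Each person follows an activity
#' schedule of bouts; during a bout the wrists reach into the wrist (table)
#' zone, the shoulders stand in the shoulder zone, the head points lie in
#' the head zone, and the upper body is stationary. Outside bouts the person
#' either walks (with a per-frame step large enough that the windowed
#' displacement exceeds the movement threshold by a safety margin) or idles
#' with the arms down, so the zone test fails. Persons arrive at their slot
#' `warmup` frames before a bout starts; shoulders and head are therefore
#' already stationary when the bout begins and, on noiseless input, the
#' activity classifier reproduces the scheduled activity exactly beyond the
#' displacement warm-up.
#'
#' Detections are the noiseless ground truth plus isotropic Gaussian jitter
#' (`jitter_sd`) and per-keypoint dropout (`dropout_rate`); detection order
#' within a frame is shuffled so downstream tracking cannot exploit it.
#'
#' @param n_staff Number of staff members (>= 0).
#' @param fps Frames per second (> 0). Default 25, a common PAL camera rate;
#'   configurable because the recording rate is a property of the camera,
#'   not of the method.
#' @param phase_durations Numeric length-3, seconds per clinical phase
#'   (all > 0).
#' @param zone_set A [zone_set()]; default [default_zone_set()].
#' @param activity_schedule Tibble with columns `person`, `phase`,
#'   `start_frac`, `end_frac` (0 <= start < end <= 1): scheduled active
#'   bouts as fractions of the phase. `NULL` auto-generates one bout per
#'   person in a random phase.
#' @param jitter_sd Isotropic keypoint jitter SD in pixels (>= 0).
#' @param dropout_rate Probability that a keypoint is missing in a frame
#'   (0 <= rate < 1).
#' @param surgery_type Surgery type label for the simulated procedure.
#' @param procedure_id Procedure label.
#' @param detection_conf Confidence attached to simulated keypoints.
#' @param speed_margin Walking step is `threshold / window * (1 + margin)`
#'   so walking displacement clears the movement threshold sharply.
#' @param seed Integer seed; all randomness is derived from it.
#' @return A validated `scene_config` list.
#' @seealso [simulate_scene()]
#' @export
scene_config <- function(n_staff,
                         fps = 25,
                         phase_durations = c(40, 80, 40),
                         zone_set = default_zone_set(),
                         activity_schedule = NULL,
                         jitter_sd = 0,
                         dropout_rate = 0,
                         surgery_type = "MIS",
                         procedure_id = "sim",
                         detection_conf = 0.9,
                         speed_margin = 0.3,
                         seed = 1L) {
  assert_count(n_staff, "n_staff")
  assert_number(fps, "fps", lower = 0, strict_lower = TRUE)
  if (length(phase_durations) != 3L || any(!is.finite(phase_durations)) ||
      any(phase_durations <= 0)) {
    abort("`phase_durations` must be 3 positive durations in seconds")
  }
  stopifnot(inherits(zone_set, "zone_set"))
  assert_number(jitter_sd, "jitter_sd", lower = 0)
  assert_number(dropout_rate, "dropout_rate", lower = 0, upper = 1, strict_upper = TRUE)
  assert_number(detection_conf, "detection_conf", lower = 0, upper = 1)
  assert_number(speed_margin, "speed_margin", lower = 0)
  assert_count(seed, "seed", min = -.Machine$integer.max)
  surgery_type <- match.arg(surgery_type, surgery_types())
  if (!is.null(activity_schedule)) {
    assert_columns(activity_schedule, c("person", "phase", "start_frac", "end_frac"),
                   "activity_schedule")
    with(activity_schedule, {
      if (any(start_frac < 0 | start_frac >= end_frac | end_frac > 1)) {
        abort("activity_schedule: need 0 <= start_frac < end_frac <= 1")
      }
      if (any(!phase %in% 1:3)) abort("activity_schedule: phase must be 1, 2 or 3")
      if (any(!person %in% seq_len(n_staff))) {
        abort("activity_schedule: person must be in 1..n_staff")
      }
    })
    activity_schedule <- as_tibble(activity_schedule)
  }
  structure(
    list(
      n_staff = as.integer(n_staff), fps = fps,
      phase_durations = phase_durations, zone_set = zone_set,
      activity_schedule = activity_schedule,
      jitter_sd = jitter_sd, dropout_rate = dropout_rate,
      surgery_type = surgery_type, procedure_id = procedure_id,
      detection_conf = detection_conf, speed_margin = speed_margin,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

# rigid body template: keypoint offsets (px) from the body centre as seen
# from a ceiling camera; legs are carried for completeness only.
body_template <- function() {
  tibble(
    keypoint = coco_keypoints(),
    dx = c(0, -4, 4, -8, 8, -18, 18, -24, 24, -20, 20, -12, 12, -12, 12, -12, 12),
    dy = c(-6, -9, -9, -10, -10, 0, 0, 12, 12, 24, 24, 30, 30, 52, 52, 74, 74)
  )
}

# standing slots around the default table; each slot: shoulder-centre
# position plus the two wrist target points inside the wrist zone
table_slots <- function() {
  tibble(
    slot = 1:8,
    sx = c(570, 710, 640, 570, 710, 640, 500, 780),
    sy = c(470, 470, 470, 250, 250, 250, 360, 360),
    wlx = c(555, 695, 625, 555, 695, 625, 560, 720),
    wly = c(420, 420, 420, 300, 300, 300, 345, 345),
    wrx = c(585, 725, 655, 585, 725, 655, 560, 720),
    wry = c(420, 420, 420, 300, 300, 300, 375, 375)
  )
}

#' Simulate an operating-room scene with known ground truth
#'
#' @param config A [scene_config()].
#' @param window,threshold Movement-veto window (frames) and displacement
#'   threshold (px) the scene is constructed against; defaults match
#'   [activity_params()].
#' @return A list of class `or_scene` with elements
#'   \describe{
#'     \item{detections}{long tibble `frame`, `det`, `keypoint`, `x`, `y`,
#'       `confidence` (noisy, order-shuffled within frame)}
#'     \item{truth}{list: `true_tracks` (noiseless `person`-keyed pose
#'       tibble), `true_activity` (`person`, `frame`, `active`), `det_map`
#'       (`frame`, `det`, `person`)}
#'     \item{timeline}{the procedure [phase_timeline()]}
#'     \item{zones}{the [zone_set()]}
#'     \item{config}{the input config}
#'   }
#' @export
#' @examples
#' sc <- simulate_scene(scene_config(n_staff = 1, phase_durations = c(4, 8, 4),
#'                                   seed = 7))
#' head(sc$detections)
simulate_scene <- function(config, window = 5L, threshold = 17.5) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, simulate_scene_impl(config, window, threshold))
}

simulate_scene_impl <- function(config, window, threshold) {
  n_frames_phase <- round(config$phase_durations * config$fps)
  bounds <- cumsum(c(0, n_frames_phase))
  total <- bounds[4]
  timeline <- phase_timeline(
    config$procedure_id, config$surgery_type,
    bounds[1], bounds[2], bounds[3], bounds[4], fps = config$fps
  )

  empty_poses <- tibble(
    frame = integer(), det = integer(), keypoint = character(),
    x = double(), y = double(), confidence = double()
  )
  empty_truth <- list(
    true_tracks = tibble(
      person = integer(), frame = integer(), keypoint = character(),
      x = double(), y = double()
    ),
    true_activity = tibble(person = integer(), frame = integer(), active = logical()),
    det_map = tibble(frame = integer(), det = integer(), person = integer())
  )
  if (config$n_staff == 0L) {
    return(structure(
      list(detections = empty_poses, truth = empty_truth,
           timeline = timeline, zones = config$zone_set, config = config),
      class = "or_scene"
    ))
  }

  schedule <- config$activity_schedule %||% random_schedule(config$n_staff, total, bounds, window)
  slots <- table_slots()
  step <- threshold / window * (1 + config$speed_margin)

  persons <- purrr::map(seq_len(config$n_staff), function(p) {
    slot <- slots[((p - 1L) %% nrow(slots)) + 1L, ]
    home <- c(120 + ((p - 1L) %% 10L) * 95, 640)
    sched_p <- schedule %>% filter(.data$person == p) %>% arrange(.data$phase, .data$start_frac)
    bouts <- bout_frames(sched_p, bounds)
    traj <- person_trajectory(total, bouts, home, c(slot$sx, slot$sy), step, window)
    active <- rep(FALSE, total)
    for (i in seq_len(nrow(bouts))) active[(bouts$bs[i]:bouts$be[i]) + 1L] <- TRUE
    list(p = p, traj = traj, active = active, slot = slot)
  })

  tmpl <- body_template()
  true_tracks <- purrr::map(persons, function(pr) {
    kp_long <- tidyr::expand_grid(frame = 0:(total - 1L), keypoint = tmpl$keypoint) %>%
      left_join(tmpl, by = "keypoint") %>%
      mutate(
        x = pr$traj$x[.data$frame + 1L] + .data$dx,
        y = pr$traj$y[.data$frame + 1L] + .data$dy,
        person = pr$p
      )
    act <- pr$active[kp_long$frame + 1L]
    lw <- kp_long$keypoint == "left_wrist" & act
    rw <- kp_long$keypoint == "right_wrist" & act
    kp_long$x[lw] <- pr$slot$wlx
    kp_long$y[lw] <- pr$slot$wly
    kp_long$x[rw] <- pr$slot$wrx
    kp_long$y[rw] <- pr$slot$wry
    kp_long %>% select("person", "frame", "keypoint", "x", "y")
  }) %>% bind_rows()

  true_activity <- purrr::map(persons, function(pr) {
    tibble(person = pr$p, frame = 0:(total - 1L), active = pr$active)
  }) %>% bind_rows()

  # observation model: jitter + dropout
  det <- true_tracks
  if (config$jitter_sd > 0) {
    det$x <- det$x + rnorm(nrow(det), 0, config$jitter_sd)
    det$y <- det$y + rnorm(nrow(det), 0, config$jitter_sd)
  }
  if (config$dropout_rate > 0) {
    det <- det[runif(nrow(det)) >= config$dropout_rate, , drop = FALSE]
  }
  det$confidence <- config$detection_conf

  # shuffle detection indices within each frame
  pf <- det %>% distinct(.data$frame, .data$person)
  pf <- pf %>%
    group_by(.data$frame) %>%
    mutate(det = sample.int(n())) %>%
    ungroup()
  det <- det %>%
    left_join(pf, by = c("frame", "person")) %>%
    arrange(.data$frame, .data$det, match(.data$keypoint, coco_keypoints()))
  det_map <- pf %>% select("frame", "det", "person") %>% arrange(.data$frame, .data$det)
  detections <- det %>% select("frame", "det", "keypoint", "x", "y", "confidence")

  structure(
    list(
      detections = detections,
      truth = list(true_tracks = true_tracks, true_activity = true_activity,
                   det_map = det_map),
      timeline = timeline, zones = config$zone_set, config = config
    ),
    class = "or_scene"
  )
}

#' @export
print.or_scene <- function(x, ...) {
  cat(sprintf(
    "<or_scene> %d staff, %d frames (%.1f s), %d detections\n",
    x$config$n_staff, x$timeline$patient_exit,
    x$timeline$patient_exit / x$timeline$fps,
    nrow(dplyr::distinct(x$detections, .data$frame, .data$det))
  ))
  invisible(x)
}

# one bout per person in a random phase; the start fraction leaves room for
# the walk from home plus the displacement warm-up where the phase is long
# enough, so scheduled activity stays recoverable on noiseless scenes
random_schedule <- function(n_staff, total, bounds, window) {
  purrr::map(seq_len(n_staff), function(p) {
    phase <- sample(1:3, 1L)
    len <- bounds[phase + 1L] - bounds[phase]
    lead <- min(0.85, (160 + window) / len + 0.02)
    s <- runif(1, min = lead, max = 0.9)
    e <- runif(1, min = s + 0.05, max = 1)
    tibble(person = p, phase = phase, start_frac = s, end_frac = e)
  }) %>% bind_rows()
}

bout_frames <- function(sched_p, bounds) {
  if (nrow(sched_p) == 0L) {
    return(tibble(bs = integer(), be = integer()))
  }
  out <- sched_p %>%
    mutate(
      p0 = bounds[.data$phase],
      len = bounds[.data$phase + 1L] - bounds[.data$phase],
      bs = .data$p0 + floor(.data$start_frac * .data$len),
      be = .data$p0 + ceiling(.data$end_frac * .data$len) - 1L
    ) %>%
    filter(.data$be >= .data$bs) %>%
    arrange(.data$bs) %>%
    select("bs", "be")
  if (nrow(out) > 1L && any(out$bs[-1L] <= out$be[-nrow(out)])) {
    abort("activity_schedule: bouts overlap for one person")
  }
  out
}

# body-centre trajectory: home <-> slot walks timed so the person is
# stationary at the slot from `window` frames before each bout; if a gap is
# too short to walk home and back, the person idles at the slot (arms down)
person_trajectory <- function(total, bouts, home, slot, step, window) {
  x <- rep(home[1], total)
  y <- rep(home[2], total)
  if (nrow(bouts) == 0L) {
    return(list(x = x, y = y))
  }
  dist_hs <- euclid(home[1], home[2], slot[1], slot[2])
  travel <- max(1L, ceiling(dist_hs / step))

  fill <- function(from, to, p) {
    if (to >= from) {
      idx <- (from:to) + 1L
      x[idx] <<- p[1]
      y[idx] <<- p[2]
    }
  }
  walk <- function(from, to, p0, p1) {
    idx <- (from:to) + 1L
    tt <- if (to > from) (seq_along(idx) - 1L) / (to - from) else 1
    x[idx] <<- p0[1] + tt * (p1[1] - p0[1])
    y[idx] <<- p0[2] + tt * (p1[2] - p0[2])
  }

  pos <- home
  t_free <- 0L # first frame not yet laid out
  for (i in seq_len(nrow(bouts))) {
    arrive <- bouts$bs[i] - window
    if (arrive <= t_free) {
      # no room to travel: the person is already (or starts) at the slot
      if (i == 1L) fill(0L, total - 1L, slot)
      pos <- slot
    } else {
      depart <- max(t_free, arrive - travel)
      fill(t_free, depart - 1L, pos)
      walk(depart, arrive, pos, slot)
      pos <- slot
    }
    fill(max(0L, arrive), bouts$be[i], slot)
    t_free <- bouts$be[i] + 1L

    if (i < nrow(bouts)) {
      next_arrive <- bouts$bs[i + 1L] - window
      if (next_arrive - t_free >= 2L * travel + 2L) {
        walk(t_free, t_free + travel, slot, home)
        pos <- home
        t_free <- t_free + travel + 1L
        # frames up to the next departure keep the initial home fill
      } else {
        fill(t_free, max(t_free, next_arrive - 1L), slot)
        pos <- slot
        t_free <- max(t_free, next_arrive)
      }
    } else if (t_free < total) {
      if (total - t_free >= travel + 1L) {
        walk(t_free, t_free + travel, slot, home)
        # remaining frames keep the initial home fill
      } else {
        fill(t_free, total - 1L, slot)
      }
    }
  }
  list(x = x, y = y)
}

#' Simulate straight-line walking staff
#'
#' Constant-velocity walkers with full-body pose templates, used to exercise
#' the tracker: each walker starts at `starts[i, ]` and moves with velocity
#' `velocities[i, ]` (px/frame) for `n_frames` frames. Observation noise is
#' the same jitter + dropout model as [simulate_scene()].
#'
#' @param n_frames Number of frames.
#' @param starts,velocities Matrices with one row per walker and columns
#'   x, y; defaults place walkers on well-separated parallel tracks.
#' @param n_walkers Number of walkers (used only when `starts` is NULL).
#' @param separation Vertical spacing (px) of the default parallel tracks.
#' @param speed Default horizontal speed (px/frame).
#' @param jitter_sd,dropout_rate,detection_conf Observation model.
#' @param seed Integer seed.
#' @return List with `detections` (long tibble) and `det_map`
#'   (`frame`, `det`, `person`).
#' @export
simulate_walkers <- function(n_frames, n_walkers = 2L,
                             starts = NULL, velocities = NULL,
                             separation = 250, speed = 3,
                             jitter_sd = 0, dropout_rate = 0,
                             detection_conf = 0.9, seed = 1L) {
  assert_count(n_frames, "n_frames", min = 1L)
  if (is.null(starts)) {
    starts <- cbind(100, 150 + (seq_len(n_walkers) - 1L) * separation)
  }
  starts <- as.matrix(starts)
  n_walkers <- nrow(starts)
  if (is.null(velocities)) velocities <- cbind(rep(speed, n_walkers), 0)
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == n_walkers, ncol(starts) == 2L, ncol(velocities) == 2L)
  assert_number(jitter_sd, "jitter_sd", lower = 0)
  assert_number(dropout_rate, "dropout_rate", lower = 0, upper = 1, strict_upper = TRUE)

  withr::with_seed(seed, {
    tmpl <- body_template()
    det <- purrr::map(seq_len(n_walkers), function(p) {
      tidyr::expand_grid(frame = 0:(n_frames - 1L), keypoint = tmpl$keypoint) %>%
        left_join(tmpl, by = "keypoint") %>%
        mutate(
          person = p,
          x = starts[p, 1] + velocities[p, 1] * .data$frame + .data$dx,
          y = starts[p, 2] + velocities[p, 2] * .data$frame + .data$dy
        ) %>%
        select("person", "frame", "keypoint", "x", "y")
    }) %>% bind_rows()
    if (jitter_sd > 0) {
      det$x <- det$x + rnorm(nrow(det), 0, jitter_sd)
      det$y <- det$y + rnorm(nrow(det), 0, jitter_sd)
    }
    if (dropout_rate > 0) det <- det[runif(nrow(det)) >= dropout_rate, , drop = FALSE]
    det$confidence <- detection_conf
    pf <- det %>% distinct(.data$frame, .data$person) %>%
      group_by(.data$frame) %>% mutate(det = sample.int(n())) %>% ungroup()
    det <- det %>%
      left_join(pf, by = c("frame", "person")) %>%
      arrange(.data$frame, .data$det, match(.data$keypoint, coco_keypoints()))
    list(
      detections = det %>% select("frame", "det", "keypoint", "x", "y", "confidence"),
      det_map = pf %>% select("frame", "det", "person") %>% arrange(.data$frame, .data$det)
    )
  })
}
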