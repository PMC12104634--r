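test_that("head point is the centroid of sufficiently confident head keypoints", {
  expect_equal(head_point(mk_pose(nose = c(50, 40))), c(x = 50, y = 40))
  expect_equal(head_point(mk_pose(nose = c(50, 40), left_eye = c(54, 36))),
               c(x = 52, y = 38))
  low <- mk_pose(nose = c(50, 40, 0.1), left_eye = c(54, 36, 0.2))
  expect_null(head_point(low, min_confidence = 0.3))
})

test_that("zone test requires every pose subset in its area", {
  zs <- square_zones()
  ok <- mk_pose(
    left_wrist = c(30, 30), right_wrist = c(70, 30),
    left_shoulder = c(30, 120), right_shoulder = c(70, 120),
    nose = c(50, 130)
  )
  expect_equal(zone_test(ok, zs), "pass")

  one_out <- ok
  one_out$x[one_out$keypoint == "left_wrist"] <- -1 # 1 px outside
  expect_equal(zone_test(one_out, zs), "fail")

  # passer-by: wrist reaches over the table but shoulders are elsewhere
  passer <- ok
  passer$x[passer$keypoint %in% shoulder_keypoints()] <- 300
  expect_equal(zone_test(passer, zs), "fail")

  missing_wrist <- ok[ok$keypoint != "right_wrist", ]
  expect_equal(zone_test(missing_wrist, zs), "undetermined")
})

test_that("windowed displacement averages shoulder and head travel", {
  base <- mk_pose(
    left_shoulder = c(100, 100), right_shoulder = c(140, 100), nose = c(120, 90)
  )
  mk_track <- function(shift_s, shift_h) {
    moved <- base
    moved$x[moved$keypoint %in% shoulder_keypoints()] <-
      moved$x[moved$keypoint %in% shoulder_keypoints()] + shift_s[1]
    moved$y[moved$keypoint %in% shoulder_keypoints()] <-
      moved$y[moved$keypoint %in% shoulder_keypoints()] + shift_s[2]
    moved$x[moved$keypoint == "nose"] <- moved$x[moved$keypoint == "nose"] + shift_h[1]
    moved$y[moved$keypoint == "nose"] <- moved$y[moved$keypoint == "nose"] + shift_h[2]
    dplyr::bind_rows(
      base %>% dplyr::mutate(frame = 0L),
      moved %>% dplyr::mutate(frame = 5L)
    )
  }
  expect_equal(pose_displacement(mk_track(c(0, 0), c(0, 0)), 5), 0)
  expect_equal(pose_displacement(mk_track(c(3, 4), c(3, 4)), 5), 5)
  # shoulders 10 px, head 25 px: mean (10 + 10 + 25) / 3 = 15
  expect_equal(pose_displacement(mk_track(c(10, 0), c(25, 0)), 5), 15)
  expect_true(is.na(pose_displacement(mk_track(c(0, 0), c(0, 0)), 3))) # warm-up
})

test_that("the movement veto fires only when the threshold is strictly exceeded", {
  zs <- square_zones()
  in_zone_pose <- function(frame, shift) {
    dplyr::bind_rows(
      mk_pose(
        left_wrist = c(30 + shift, 30), right_wrist = c(70 + shift, 30),
        left_shoulder = c(30 + shift, 120), right_shoulder = c(70 + shift, 120),
        nose = c(50 + shift, 130)
      ) %>% dplyr::mutate(frame = frame, track_id = 1L)
    )
  }
  series <- function(shift) {
    poses <- dplyr::bind_rows(in_zone_pose(0L, 0), in_zone_pose(5L, shift))
    classify_activity(poses, zs)
  }
  # wrists are inside the 0-100 square for shifts below ~30, zones pass
  s0 <- series(0)
  expect_equal(s0$status[s0$frame == 5], "active")
  s_at <- series(17.5)
  expect_equal(s_at$status[s_at$frame == 5], "active") # boundary equality
  s_over <- series(17.6)
  expect_equal(s_over$status[s_over$frame == 5], "inactive")
  # frame 0 has no displacement window yet
  expect_equal(s0$status[s0$frame == 0], "undetermined")
})

test_that("scheduled activity is recovered exactly on noiseless scenes", {
  sched <- tibble::tibble(person = 1, phase = 2, start_frac = 0.2, end_frac = 0.7)
  sc <- simulate_scene(scene_config(
    n_staff = 1, phase_durations = c(10, 10, 4), activity_schedule = sched,
    jitter_sd = 0, dropout_rate = 0, seed = 17
  ))
  act <- classify_scene_truthid(sc)
  cmp <- dplyr::inner_join(
    act, sc$truth$true_activity,
    by = c(track_id = "person", frame = "frame")
  ) %>% dplyr::filter(frame >= 5)
  expect_true(all((cmp$status == "active") == cmp$active))

  iv <- activity_intervals(act)
  expect_equal(nrow(iv), 1L)
  expect_equal(sum(iv$n_frames), sum(cmp$active))
})

test_that("dropping required keypoints turns frames undetermined, never active", {
  sched <- tibble::tibble(person = 1, phase = 2, start_frac = 0.2, end_frac = 0.9)
  sc <- simulate_scene(scene_config(
    n_staff = 1, phase_durations = c(8, 8, 4), activity_schedule = sched, seed = 23
  ))
  poses <- dplyr::inner_join(sc$detections, sc$truth$det_map, by = c("frame", "det")) %>%
    dplyr::select(track_id = person, frame, keypoint, x, y, confidence)
  full <- classify_activity(poses, sc$zones)

  withr::with_seed(99, keep <- runif(nrow(poses)) >= 0.2)
  dropped <- classify_activity(poses[keep, ], sc$zones)
  cmp <- dplyr::inner_join(full, dropped, by = c("track_id", "frame"),
                           suffix = c("_full", "_drop"))
  expect_lte(sum(cmp$status_drop == "active"), sum(cmp$status_full == "active"))
  flipped <- cmp$status_full != cmp$status_drop
  expect_true(all(cmp$status_drop[flipped] == "undetermined"))
})

test_that("raising the displacement threshold never decreases active frames", {
  sc <- simulate_scene(random_scene(5))
  counts <- vapply(c(5, 17.5, 50), function(thr) {
    act <- classify_scene_truthid(sc, activity_params(displacement_threshold = thr))
    sum(act$status == "active")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("shrinking a zone never increases active frames", {
  sched <- tibble::tibble(person = 1:2, phase = 2, start_frac = c(0.2, 0.3),
                          end_frac = c(0.8, 0.9))
  sc <- simulate_scene(scene_config(
    n_staff = 2, phase_durations = c(10, 10, 4), activity_schedule = sched,
    jitter_sd = 2, seed = 29
  ))
  act_full <- classify_scene_truthid(sc)

  shrink <- function(poly, f) {
    cx <- mean(poly$x); cy <- mean(poly$y)
    tibble::tibble(x = cx + f * (poly$x - cx), y = cy + f * (poly$y - cy))
  }
  zs2 <- zone_set(shrink(sc$zones$wrist_zone, 0.6), sc$zones$shoulder_zone,
                  sc$zones$head_zone)
  poses <- dplyr::inner_join(sc$detections, sc$truth$det_map, by = c("frame", "det")) %>%
    dplyr::select(track_id = person, frame, keypoint, x, y, confidence)
  act_shrunk <- classify_activity(poses, zs2)
  expect_lte(sum(act_shrunk$status == "active"), sum(act_full$status == "active"))
})

test_that("the classifier agrees with a brute-force oracle on random scenes", {
  for (seed in c(2, 9)) {
    sc <- simulate_scene(random_scene(seed))
    if (nrow(sc$detections) == 0) next
    poses <- dplyr::inner_join(sc$detections, sc$truth$det_map,
                               by = c("frame", "det")) %>%
      dplyr::select(track_id = person, frame, keypoint, x, y, confidence)
    got <- classify_activity(poses, sc$zones)
    want <- oracle_classify(poses, sc$zones)
    cmp <- dplyr::inner_join(got, tibble::as_tibble(want),
                             by = c("track_id", "frame"), suffix = c("", "_oracle"))
    expect_equal(nrow(cmp), nrow(got))
    expect_equal(cmp$status, cmp$status_oracle)
  }
})
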