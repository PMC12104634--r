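test_that("pose_bbox is tight over present keypoints and expands by the margin", {
  p <- mk_pose(nose = c(0, 0), left_wrist = c(10, 20))
  expect_equal(pose_bbox(p), c(xmin = 0, ymin = 0, xmax = 10, ymax = 20))
  expect_error(pose_bbox(mk_pose(nose = c(5, 5))), "2 present keypoints")
  b <- pose_bbox(mk_pose(nose = c(0, 0), left_wrist = c(10, 20)), margin = 0.1)
  expect_equal(unname(b["xmax"] - b["xmin"]), 12) # width 10 + 10% each side
  expect_equal(unname(b["ymax"] - b["ymin"]), 24)
})

test_that("pose similarity is 1 on identity, symmetric, and reduces to IoU at lambda 1", {
  p <- full_pose_rows(1, 0, 300, 300)[, c("keypoint", "x", "y", "confidence")]
  expect_equal(pose_similarity(p, p), 1)

  q <- p
  q$x <- q$x + 30
  expect_equal(pose_similarity(p, q), pose_similarity(q, p))

  # boxes (0,0,10,10) and (5,0,15,10): IoU = 50 / 150 = 1/3
  a <- mk_pose(left_shoulder = c(0, 0), right_shoulder = c(10, 10))
  b <- mk_pose(left_shoulder = c(5, 0), right_shoulder = c(15, 10))
  expect_equal(pose_similarity(a, b, lambda = 1), 1 / 3)

  far <- p
  far$x <- far$x + 1e5
  expect_lt(pose_similarity(p, far), 1e-6)
})

test_that("association spawns, matches and misses per the two-stage rules", {
  params <- tracker_params()
  dets <- purrr::map(c(100, 400, 700), function(cx) {
    as.data.frame(full_pose_rows(1, 0, cx, 300)[, c("keypoint", "x", "y", "confidence")])
  })
  res <- associate(list(), dets, params)
  expect_equal(res$births, 1:3)
  expect_equal(nrow(res$matches), 0L)

  track <- dets[[1]]
  far_det <- dets[[1]]
  far_det$x <- far_det$x + 5000
  res2 <- associate(list(`1` = track), list(far_det), params)
  expect_equal(nrow(res2$matches), 0L)
  expect_equal(res2$misses, "1")
  expect_equal(res2$births, 1L)
})

test_that("an isolated constant-velocity person yields one confirmed full-length track", {
  expect_equal(nrow(build_tracks(
    tibble::tibble(frame = integer(), det = integer(), keypoint = character(),
                   x = double(), y = double(), confidence = double())
  )$states), 0L)

  w <- simulate_walkers(50, n_walkers = 1, seed = 2)
  tr <- build_tracks(w$detections)
  expect_equal(nrow(tr$states), 1L)
  expect_true(all(tr$states$ever_confirmed))
  expect_equal(dplyr::n_distinct(tr$poses$frame), 50L)
})

test_that("well-separated walkers keep their identities", {
  w <- simulate_walkers(100, n_walkers = 2, separation = 250, seed = 8)
  tr <- build_tracks(w$detections)
  confirmed <- tr$states$track_id[tr$states$ever_confirmed]
  expect_equal(length(confirmed), 2L)
  expect_equal(count_id_switches(tr, w$det_map), 0L)
})

test_that("crossing walkers with low box overlap keep identities", {
  # parallel in x, separated in y by ~80 px so boxes barely overlap when the
  # walkers pass each other
  w <- simulate_walkers(
    100,
    starts = rbind(c(100, 200), c(700, 280)),
    velocities = rbind(c(5, 0), c(-5, 0)),
    seed = 31
  )
  tr <- build_tracks(w$detections)
  expect_equal(sum(tr$states$ever_confirmed), 2L)
  expect_equal(count_id_switches(tr, w$det_map), 0L)
})

test_that("tracking is one-to-one and deterministic", {
  w <- simulate_walkers(60, n_walkers = 3, separation = 150,
                        jitter_sd = 2, dropout_rate = 0.05, seed = 12)
  t1 <- build_tracks(w$detections)
  t2 <- build_tracks(w$detections)
  expect_identical(t1$poses, t2$poses)

  assignments <- dplyr::distinct(t1$poses, frame, det, track_id)
  expect_equal(anyDuplicated(assignments[, c("frame", "det")]), 0L)
  expect_equal(anyDuplicated(assignments[, c("frame", "track_id")]), 0L)
})

test_that("per-frame assignments achieve the exhaustive-enumeration optimum", {
  params <- tracker_params()
  for (seed in c(3, 14, 27)) {
    w <- simulate_walkers(25, n_walkers = 3, separation = 120,
                          jitter_sd = 3, dropout_rate = 0.1, seed = seed)
    tr <- build_tracks(w$detections, params)
    # replay: at each frame, compare achieved total similarity of matched
    # pairs with the exhaustive optimum over active tracks x detections
    frames <- sort(unique(w$detections$frame))
    state <- list() # track_id -> last pose (long df)
    last_seen <- c()
    for (f in frames) {
      df <- w$detections[w$detections$frame == f, ]
      det_ids <- sort(unique(df$det))
      active <- names(state)[f - last_seen[names(state)] <= params$max_age]
      if (length(active) > 0 && length(det_ids) > 0) {
        sim <- matrix(0, length(active), length(det_ids))
        for (i in seq_along(active)) {
          for (j in seq_along(det_ids)) {
            sim[i, j] <- pose_similarity(
              state[[active[i]]], df[df$det == det_ids[j],
                                     c("keypoint", "x", "y", "confidence")],
              lambda = params$lambda, margin = params$bbox_margin
            )
          }
        }
        opt <- oracle_best_matching(sim, params$match_threshold)
        got <- tr$log[tr$log$frame == f, ]
        expect_equal(sum(got$similarity), opt, tolerance = 1e-8)
      }
      # advance the replayed state from the tracker's own assignments
      af <- tr$poses[tr$poses$frame == f, ]
      for (id in unique(af$track_id)) {
        state[[as.character(id)]] <-
          af[af$track_id == id, c("keypoint", "x", "y", "confidence")]
        last_seen[as.character(id)] <- f
      }
    }
  }
})
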