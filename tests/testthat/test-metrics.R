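# hand-built activity series: status per (track, frame) over a 3-phase
# timeline of 100 + 200 + 100 frames at 25 fps
mk_timeline <- function(type = "MIS") phase_timeline("P1", type, 0, 100, 300, 400)

mk_series <- function(...) {
  tracks <- list(...)
  dplyr::bind_rows(purrr::imap(tracks, function(status_fn, i) {
    status <- status_fn(0:399)
    tibble::tibble(
      track_id = as.integer(i), frame = 0:399, status = status,
      zone = dplyr::case_when(status == "active" ~ "pass",
                              status == "inactive" ~ "fail",
                              TRUE ~ "undetermined"),
      displacement = ifelse(status == "undetermined", NA_real_, 1)
    )
  }))
}

test_that("activity percentage matches its definition, including > 100%", {
  tl <- mk_timeline()
  idle <- mk_series(function(f) rep("inactive", length(f)))
  expect_equal(activity_percentage(idle, tl)$activity_pct, c(0, 0, 0))

  # two persons active for all of phase 2, denominator = own duration
  both <- mk_series(
    function(f) ifelse(f >= 100 & f < 300, "active", "inactive"),
    function(f) ifelse(f >= 100 & f < 300, "active", "inactive")
  )
  expect_equal(activity_percentage(both, tl)$activity_pct[2], 200)

  # one person active half of phase 2
  half <- mk_series(function(f) ifelse(f >= 100 & f < 200, "active", "inactive"))
  expect_equal(activity_percentage(half, tl)$activity_pct[2], 50)

  # denominator is the type-mean duration: same series, mean phase-2
  # duration twice this procedure's -> percentage halves
  expect_equal(
    activity_percentage(half, tl, mean_phase_durations = c(4, 16, 4))$activity_pct[2],
    25
  )
  expect_error(activity_percentage(half, tl, mean_phase_durations = c(4, 0, 4)),
               "positive")
})

test_that("activity percentage is additive across persons", {
  tl <- mk_timeline()
  s1 <- mk_series(function(f) ifelse(f >= 100 & f < 180, "active", "inactive"))
  s2 <- mk_series(function(f) ifelse(f >= 150 & f < 300, "active", "inactive"))
  s2$track_id <- 2L
  combined <- dplyr::bind_rows(s1, s2)
  expect_equal(
    activity_percentage(combined, tl)$activity_pct,
    activity_percentage(s1, tl)$activity_pct + activity_percentage(s2, tl)$activity_pct
  )
})

test_that("undetermined frames are excluded from both sides of the ratio", {
  tl <- mk_timeline()
  # active half of the determined phase-2 frames, the rest undetermined
  s <- mk_series(function(f) dplyr::case_when(
    f >= 100 & f < 200 ~ "active",
    f >= 200 & f < 250 ~ "inactive",
    f >= 250 & f < 300 ~ "undetermined",
    TRUE ~ "inactive"
  ))
  # determined in phase 2: 150 frames, 100 active -> fraction 2/3
  expect_equal(interaction_percentage(s, tl)$interaction_pct[2], 100 * 100 / 150)
})

test_that("interaction percentage reflects combined occupancy", {
  tl <- mk_timeline()
  empty <- mk_series(function(f) rep("inactive", length(f)))[0, ]
  expect_equal(interaction_percentage(empty, tl)$interaction_pct, c(0, 0, 0))

  full <- mk_series(function(f) ifelse(f >= 100 & f < 300, "active", "inactive"))
  expect_equal(interaction_percentage(full, tl)$interaction_pct[2], 100)
})

test_that("movement percentage counts threshold exceedances among determined frames", {
  par <- activity_params()
  still <- tibble::tibble(track_id = 1L, frame = 0:99, status = "inactive",
                          zone = "fail", displacement = rep(c(NA, 3), 50))
  expect_equal(movement_percentage(still, par), 0)

  # 10% of determined frames above threshold
  moving <- tibble::tibble(
    track_id = 1L, frame = 0:99, status = "inactive", zone = "fail",
    displacement = c(rep(50, 10), rep(1, 90))
  )
  expect_equal(movement_percentage(moving, par), 10)

  none <- dplyr::mutate(still, displacement = NA_real_)
  expect_true(is.na(movement_percentage(none, par)))

  # per-person vs pooled differ when persons have unequal frame counts
  a <- tibble::tibble(track_id = 1L, frame = 0:9, status = "x", zone = "x",
                      displacement = rep(50, 10))
  b <- tibble::tibble(track_id = 2L, frame = 0:89, status = "x", zone = "x",
                      displacement = rep(1, 90))
  ab <- dplyr::bind_rows(a, b)
  expect_equal(movement_percentage(ab, par, mode = "per_person"), 50)
  expect_equal(movement_percentage(ab, par, mode = "pooled"), 10)
})

test_that("uniform rescaling preserves zone tests but NOT the movement veto", {
  zs <- square_zones()
  pose_seq <- dplyr::bind_rows(
    full_pose_rows(1, 0, 50, 60, wrist_xy = c(30, 30, 70, 30)),
    full_pose_rows(1, 5, 60, 60, wrist_xy = c(40, 30, 80, 30)) # 10 px shift
  )
  act <- classify_activity(pose_seq, zs)
  expect_equal(act$status[act$frame == 5], "active") # 10 <= 17.5

  scale2 <- function(df) dplyr::mutate(df, x = 2 * x, y = 2 * y)
  zs2 <- zone_set(
    scale2(zs$wrist_zone), scale2(zs$shoulder_zone), scale2(zs$head_zone)
  )
  act2 <- classify_activity(scale2(pose_seq), zs2)
  expect_equal(act2$zone, act$zone) # geometry tests unchanged
  expect_equal(act2$status[act2$frame == 5], "inactive") # 20 > 17.5 px
})

test_that("summaries average phase metrics within surgery type", {
  expect_error(summarize_phase_metrics(
    tibble::tibble(procedure_id = character(), surgery_type = character(),
                   phase = integer(), activity_pct = double(),
                   interaction_pct = double(), movement_pct = double())
  ), "no procedures")

  one <- tibble::tibble(
    procedure_id = "a", surgery_type = "OS", phase = 1:3,
    activity_pct = c(10, 20, 30), interaction_pct = c(5, 10, 15),
    movement_pct = c(1, 2, 3)
  )
  expect_equal(summarize_phase_metrics(one)$activity_pct, c(10, 20, 30))

  two <- dplyr::bind_rows(one, dplyr::mutate(one, procedure_id = "b",
                                             activity_pct = c(30, 40, 50)))
  s <- summarize_phase_metrics(two)
  expect_equal(s$activity_pct, c(20, 30, 40))
  expect_equal(s$n_procedures, c(2L, 2L, 2L))
})

test_that("phase metrics plots build", {
  one <- tibble::tibble(
    procedure_id = "a", surgery_type = "OS", phase = 1:3,
    activity_pct = c(10, 20, 30), interaction_pct = c(5, 10, 15),
    movement_pct = c(1, 2, 3)
  )
  p <- plot_phase_metrics(one)
  expect_s3_class(p, "ggplot")
})
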