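#' Phase-level activity percentage
#'
#' Combined staff activity per clinical phase, expressed relative to the
#' average total duration of that phase across procedures of the same
#' surgery type: `100 * sum over persons of determined-active time /
#' mean phase duration`. Because every active person contributes, the
#' percentage may exceed 100 when two or more staff are active
#' simultaneously. Each person's active fraction is computed over fully
#' determined frames only (zone test determined and displacement
#' available); frames without a full classification basis are excluded
#' from numerator and denominator alike, so detector dropout does not bias
#' occupancy — the chance that a frame is fully determined does not depend
#' on what the person is doing.
#'
#' @param activity An `activity_series` tibble from [classify_activity()].
#' @param timeline The procedure's [phase_timeline()].
#' @param mean_phase_durations Numeric length-3: mean duration in seconds
#'   of each phase across the analysed procedures of this surgery type
#'   (the denominator). `NULL` uses this procedure's own phase durations.
#' @return Tibble `phase`, `activity_pct`, `n_tracks`.
#' @export
activity_percentage <- function(activity, timeline, mean_phase_durations = NULL) {
  pf <- phase_frames(timeline)
  if (is.null(mean_phase_durations)) mean_phase_durations <- pf$duration_s
  if (length(mean_phase_durations) != 3L || any(!is.finite(mean_phase_durations)) ||
      any(mean_phase_durations <= 0)) {
    abort("`mean_phase_durations` must be 3 positive durations in seconds")
  }
  frac <- active_fractions(activity, timeline)
  frac %>%
    left_join(pf, by = "phase") %>%
    group_by(.data$phase) %>%
    summarise(
      activity_pct = 100 * sum(.data$frac * .data$duration_s) /
        mean_phase_durations[.data$phase[1]],
      n_tracks = dplyr::n(), .groups = "drop"
    ) %>%
    tidyr::complete(phase = 1:3, fill = list(activity_pct = 0, n_tracks = 0L))
}

#' Phase-level interaction percentage
#'
#' Share of the phase during which staff are actively engaged at the table
#' area, combined across persons: each person contributes their
#' determined-active fraction of the phase, and fractions are summed, so
#' values may exceed 100 with several simultaneously active staff.
#'
#' @inheritParams activity_percentage
#' @return Tibble `phase`, `interaction_pct`, `n_tracks`.
#' @export
interaction_percentage <- function(activity, timeline) {
  pf <- phase_frames(timeline)
  if (any(pf$n_frames <= 0)) abort("zero-length phase in timeline")
  active_fractions(activity, timeline) %>%
    group_by(.data$phase) %>%
    summarise(interaction_pct = 100 * sum(.data$frac),
              n_tracks = dplyr::n(), .groups = "drop") %>%
    tidyr::complete(phase = 1:3, fill = list(interaction_pct = 0, n_tracks = 0L))
}

# per (track, phase) active fraction among FULLY determined frames: both the
# zone test and the displacement must be available. Frames classified from
# partial information (e.g. the movement veto firing while a wrist is
# missing) are excluded too: under independent keypoint dropout the
# probability that a frame is fully determined does not depend on the
# person's activity state, so the fraction stays unbiased, whereas mixing
# partially determined frames in would over-represent inactive states.
active_fractions <- function(activity, timeline) {
  assert_columns(activity, c("track_id", "frame", "status", "zone",
                             "displacement"), "activity")
  activity %>%
    mutate(phase = phase_of_frame(timeline, .data$frame)) %>%
    filter(!is.na(.data$phase), .data$zone != "undetermined",
           !is.na(.data$displacement)) %>%
    group_by(.data$track_id, .data$phase) %>%
    summarise(frac = mean(.data$status == "active"), .groups = "drop")
}

#' Movement percentage
#'
#' Proportion of time staff spend moving: the share of frames whose
#' windowed upper-body displacement strictly exceeds the activity
#' threshold, among frames with a determined displacement. Averaged per
#' person first and then across persons (default), or pooled over all
#' person-frames.
#'
#' @param activity An `activity_series` tibble (its `displacement` column
#'   is used).
#' @param params The [activity_params()] the series was classified with.
#' @param timeline Optional [phase_timeline()]; when supplied the
#'   percentage is computed per phase.
#' @param mode `"per_person"` (mean of per-person percentages) or
#'   `"pooled"` (all person-frames pooled).
#' @return Without a timeline: a single percentage (`NA` if no frame has a
#'   determined displacement). With a timeline: tibble `phase`,
#'   `movement_pct`.
#' @export
movement_percentage <- function(activity, params = activity_params(),
                                timeline = NULL,
                                mode = c("per_person", "pooled")) {
  mode <- match.arg(mode)
  assert_columns(activity, c("track_id", "frame", "displacement"), "activity")
  det <- activity %>% filter(!is.na(.data$displacement))
  thr <- params$displacement_threshold
  if (is.null(timeline)) {
    if (nrow(det) == 0L) return(NA_real_)
    if (mode == "pooled") return(100 * mean(det$displacement > thr))
    det %>%
      group_by(.data$track_id) %>%
      summarise(p = mean(.data$displacement > thr), .groups = "drop") %>%
      pull(.data$p) %>% mean() * 100
  } else {
    det <- det %>%
      mutate(phase = phase_of_frame(timeline, .data$frame)) %>%
      filter(!is.na(.data$phase))
    per <- if (mode == "pooled") {
      det %>% group_by(.data$phase) %>%
        summarise(movement_pct = 100 * mean(.data$displacement > thr),
                  .groups = "drop")
    } else {
      det %>% group_by(.data$phase, .data$track_id) %>%
        summarise(p = mean(.data$displacement > thr), .groups = "drop") %>%
        group_by(.data$phase) %>%
        summarise(movement_pct = 100 * mean(.data$p), .groups = "drop")
    }
    tidyr::complete(per, phase = 1:3, fill = list(movement_pct = NA_real_))
  }
}

#' Per-procedure phase metrics
#'
#' Convenience wrapper computing the three phase-level percentages of one
#' procedure from its classified activity series.
#'
#' @inheritParams activity_percentage
#' @param params The [activity_params()] used for classification.
#' @return Tibble `procedure_id`, `surgery_type`, `phase`, `activity_pct`,
#'   `interaction_pct`, `movement_pct`, `n_tracks`.
#' @export
phase_metrics <- function(activity, timeline, params = activity_params(),
                          mean_phase_durations = NULL) {
  a <- activity_percentage(activity, timeline, mean_phase_durations)
  i <- interaction_percentage(activity, timeline)
  m <- movement_percentage(activity, params, timeline)
  tibble(
    procedure_id = timeline$procedure_id,
    surgery_type = timeline$surgery_type,
    phase = 1:3
  ) %>%
    left_join(a, by = "phase") %>%
    left_join(i %>% select("phase", "interaction_pct"), by = "phase") %>%
    left_join(m, by = "phase") %>%
    select("procedure_id", "surgery_type", "phase", "activity_pct",
           "interaction_pct", "movement_pct", "n_tracks")
}

#' Summarise phase metrics across procedures
#'
#' Means of the phase-level percentages within surgery type, the shape of
#' the published per-type/per-phase activity and interaction summaries.
#'
#' @param metrics Row-bound [phase_metrics()] tibbles of >= 1 procedure.
#' @param path Optional path; when given the summary table is also written
#'   as CSV.
#' @return Tibble keyed by (`surgery_type`, `phase`) with mean percentages
#'   and `n_procedures`.
#' @export
summarize_phase_metrics <- function(metrics, path = NULL) {
  assert_columns(metrics, c("procedure_id", "surgery_type", "phase",
                            "activity_pct", "interaction_pct", "movement_pct"),
                 "metrics")
  if (nrow(metrics) == 0L) abort("no procedures to summarise")
  out <- metrics %>%
    group_by(.data$surgery_type, .data$phase) %>%
    summarise(
      activity_pct = mean(.data$activity_pct, na.rm = TRUE),
      interaction_pct = mean(.data$interaction_pct, na.rm = TRUE),
      movement_pct = mean(.data$movement_pct, na.rm = TRUE),
      n_procedures = dplyr::n_distinct(.data$procedure_id),
      .groups = "drop"
    )
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
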