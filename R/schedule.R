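#' Planned-vs-actual phase deviations
#'
#' Signed deviation (actual - planned, minutes) per phase and in total for
#' each procedure; negative values mean the phase finished early. Records
#' with any missing planned or actual duration are excluded (complete-case
#' rule, no imputation); the number excluded is attached as attribute
#' `n_excluded`.
#'
#' @param records Schedule tibble in the [read_schedule()] layout.
#' @return Tibble `procedure_id`, `surgery_type`, `dev_phase1_min`,
#'   `dev_phase2_min`, `dev_phase3_min`, `dev_total_min`.
#' @export
schedule_deviation <- function(records) {
  validate_schedule(records)
  dur_cols <- c(paste0("planned_phase", 1:3, "_min"),
                paste0("actual_phase", 1:3, "_min"))
  ok <- complete.cases(records[, dur_cols])
  out <- records[ok, ] %>%
    mutate(
      dev_phase1_min = .data$actual_phase1_min - .data$planned_phase1_min,
      dev_phase2_min = .data$actual_phase2_min - .data$planned_phase2_min,
      dev_phase3_min = .data$actual_phase3_min - .data$planned_phase3_min,
      dev_total_min = .data$dev_phase1_min + .data$dev_phase2_min +
        .data$dev_phase3_min
    ) %>%
    select("procedure_id", "surgery_type", dplyr::starts_with("dev_"))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Time spent in the dark
#'
#' Periods under dimmed room lights occur primarily during the cutting
#' phase (phase 2), so dark time is proxied by the actual phase-2 duration.
#' When the record carries a dedicated `dark_time_min` field it is used
#' directly. Records missing the required field are excluded.
#'
#' @param records Schedule tibble.
#' @return Tibble `procedure_id`, `surgery_type`, `dark_time_min`; the
#'   number of excluded records is attached as attribute `n_excluded`.
#' @export
dark_time <- function(records) {
  validate_schedule(records)
  src <- if ("dark_time_min" %in% names(records)) {
    records$dark_time_min
  } else {
    records$actual_phase2_min
  }
  ok <- !is.na(src)
  out <- tibble(
    procedure_id = records$procedure_id[ok],
    surgery_type = records$surgery_type[ok],
    dark_time_min = src[ok]
  )
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Summarise hospital schedule records per surgery type
#'
#' Complete-case group summaries: mean total actual duration, mean signed
#' deviation per phase and in total, mean dark time, mean patient risk
#' class, the risk-class distribution and mean staff count.
#'
#' @param records Schedule tibble (>= 1 record).
#' @return Tibble keyed by `surgery_type` with summary columns; the
#'   risk-class distribution is a list column of class-count tibbles.
#' @export
summarize_schedule <- function(records) {
  validate_schedule(records)
  if (nrow(records) == 0L) abort("no records to summarise")
  dev <- schedule_deviation(records)
  dk <- dark_time(records)
  base <- records %>%
    semi_join(dev, by = "procedure_id") %>%
    mutate(total_actual_min = .data$actual_phase1_min + .data$actual_phase2_min +
             .data$actual_phase3_min)
  out <- base %>%
    group_by(.data$surgery_type) %>%
    summarise(
      n = dplyr::n(),
      mean_total_min = mean(.data$total_actual_min),
      mean_risk = mean(.data$risk_class, na.rm = TRUE),
      mean_staff = mean(.data$staff_count, na.rm = TRUE),
      emergency_rate = mean(.data$emergency_flag, na.rm = TRUE),
      risk_distribution = list(count(dplyr::pick("risk_class"), .data$risk_class)),
      .groups = "drop"
    ) %>%
    left_join(
      dev %>% group_by(.data$surgery_type) %>%
        summarise(across(dplyr::starts_with("dev_"), mean,
                         .names = "mean_{.col}"), .groups = "drop"),
      by = "surgery_type"
    ) %>%
    left_join(
      dk %>% group_by(.data$surgery_type) %>%
        summarise(mean_dark_min = mean(.data$dark_time_min), .groups = "drop"),
      by = "surgery_type"
    )
  attr(out, "n_excluded") <- attr(dev, "n_excluded")
  out
}
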