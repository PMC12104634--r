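#' Parameter grids for the questionnaire simulator
#'
#' `surgtlx_params_uniform()` builds a full 7-domain x 3-type x 3-phase grid
#' with a single mean/SD everywhere. `surgtlx_reference_params()` returns the
#' package's reference calibration on the per-phase 0-20 scale: for the four
#' domains with published phase-summed descriptives (mental demand, temporal
#' demand, distractions, job satisfaction) the per-phase mean and SD are the
#' phase-summed values divided by 3; the remaining three domains (physical
#' demand, task complexity, situational stress), for which no per-type
#' descriptives are published, are given neutral values that preserve the
#' reported ordering of overall workload (robotic-assisted highest, the two
#' conventional modalities close together).
#'
#' @param mean,sd Mean and SD on the 0-20 per-phase scale.
#' @return Tibble with columns `domain`, `surgery_type`, `phase`, `mean`, `sd`.
#' @export
surgtlx_params_uniform <- function(mean = 10, sd = 0) {
  grid <- tidyr::expand_grid(
    domain = surgtlx_domains(), surgery_type = surgery_types(), phase = 1:3
  )
  grid$mean <- mean
  grid$sd <- sd
  grid
}

#' @rdname surgtlx_params_uniform
#' @export
surgtlx_reference_params <- function() {
  # phase-summed (0-60 scale) means/SDs per surgery type OS, MIS, RAS
  summed <- list(
    mental = list(m = c(18.95, 16.00, 22.58), s = c(10.96, 10.42, 11.41)),
    temporal = list(m = c(20.26, 19.68, 25.37), s = c(11.39, 10.27, 12.43)),
    distractions = list(m = c(16.16, 16.84, 23.05), s = c(10.87, 10.23, 14.40)),
    satisfaction = list(m = c(46.47, 34.53, 31.95), s = c(8.53, 13.83, 14.27)),
    physical = list(m = c(17.0, 15.0, 20.0), s = c(10.5, 10.5, 10.5)),
    complexity = list(m = c(16.0, 15.0, 22.0), s = c(10.5, 10.5, 10.5)),
    stress = list(m = c(17.0, 15.0, 23.0), s = c(10.5, 10.5, 10.5))
  )
  purrr::imap(summed, function(v, dom) {
    tidyr::expand_grid(surgery_type = surgery_types(), phase = 1:3) %>%
      mutate(
        domain = dom,
        mean = v$m[match(.data$surgery_type, surgery_types())] / 3,
        sd = v$s[match(.data$surgery_type, surgery_types())] / 3
      )
  }) %>%
    bind_rows() %>%
    select("domain", "surgery_type", "phase", "mean", "sd")
}

#' Simulate questionnaire responses
#'
#' Each of the 63 cells (7 domains x 3 surgery types x 3 phases) of each
#' respondent is drawn from a normal distribution with the configured
#' mean/SD and clamped to the instrument's 0-20 scale. Clamping (rather
#' than resampling) keeps the generator monotone in the configured mean;
#' at extreme means it biases the sample mean toward the scale centre,
#' which recovery tests must account for. A fraction `missing_rate` of
#' respondents leaves the quantitative section incomplete: at least one of
#' their cells is missing.
#'
#' @param n_respondents Number of respondents.
#' @param params Parameter grid as from [surgtlx_reference_params()] /
#'   [surgtlx_params_uniform()]: one row per (domain, surgery_type, phase)
#'   with `mean` in [0, 20] and `sd` >= 0.
#' @param missing_rate Probability a respondent is incomplete
#'   (0 <= rate < 1).
#' @param cell_missing_prob Probability each cell of an incomplete
#'   respondent is missing (at least one is forced).
#' @param seed Integer seed.
#' @return Long response tibble (`respondent`, `domain`, `surgery_type`,
#'   `phase`, `score`; `NA` score = missing cell).
#' @export
#' @examples
#' r <- simulate_surgtlx(19, surgtlx_params_uniform(10, 0), seed = 1)
#' all(r$score == 10)
simulate_surgtlx <- function(n_respondents,
                             params = surgtlx_reference_params(),
                             missing_rate = 0,
                             cell_missing_prob = 0.25,
                             seed = 1L) {
  assert_count(n_respondents, "n_respondents")
  assert_number(missing_rate, "missing_rate", lower = 0, upper = 1, strict_upper = TRUE)
  assert_columns(params, c("domain", "surgery_type", "phase", "mean", "sd"), "params")
  full <- tidyr::expand_grid(
    domain = surgtlx_domains(), surgery_type = surgery_types(), phase = 1:3
  )
  params <- full %>% left_join(params, by = c("domain", "surgery_type", "phase"))
  if (any(is.na(params$mean)) || any(is.na(params$sd))) {
    abort("params must cover all 63 (domain, surgery_type, phase) cells")
  }
  if (any(params$mean < 0 | params$mean > 20)) {
    abort("params: means must lie in [0, 20] (the instrument scale)")
  }
  if (any(params$sd < 0)) abort("params: sds must be >= 0")

  withr::with_seed(seed, {
    out <- purrr::map(seq_len(n_respondents), function(r) {
      params %>%
        mutate(
          respondent = r,
          score = pmin(20, pmax(0, rnorm(dplyr::n(), .data$mean, .data$sd)))
        )
    }) %>% bind_rows()
    incomplete <- runif(n_respondents) < missing_rate
    if (any(incomplete)) {
      out <- out %>%
        group_by(.data$respondent) %>%
        mutate(miss = incomplete[.data$respondent[1]] &
                 runif(dplyr::n()) < cell_missing_prob) %>%
        ungroup()
      # force at least one missing cell for each incomplete respondent
      for (r in which(incomplete)) {
        rows <- which(out$respondent == r)
        if (!any(out$miss[rows])) {
          out$miss[rows[sample.int(length(rows), 1L)]] <- TRUE
        }
      }
      out$score[out$miss] <- NA_real_
      out$miss <- NULL
    }
    out %>%
      select("respondent", "domain", "surgery_type", "phase", "score") %>%
      arrange(.data$respondent)
  })
}

#' Simulate hospital schedule records
#'
#' Generates per-procedure planned and actual phase durations, patient risk
#' class, emergency flag and staff count with surgery-type profiles chosen
#' to mirror routine gynaecology practice: minimally invasive procedures are
#' the most frequent and shortest; open and robotic-assisted procedures run
#' longer with the robotic cutting phase (phase 2, under dimmed lights)
#' longer than the minimally invasive one; open patients carry the highest
#' risk classes; open procedures tend to finish early while robotic ones
#' overrun. All profiles are arguments, so any of them can be overridden.
#'
#' @param n_procedures Number of records.
#' @param type_mix Named proportions over OS/MIS/RAS (must sum to 1).
#' @param planned_means 3x3 matrix (rows OS/MIS/RAS, cols phases 1-3) of
#'   planned phase durations in minutes.
#' @param planned_cv Coefficient of variation of planned durations.
#' @param deviation_mean Named per-type mean TOTAL deviation
#'   (actual - planned, minutes), split equally across the three phases.
#' @param deviation_sd SD of the total deviation (minutes); 0 gives the
#'   deterministic offset.
#' @param risk_probs 3x4 matrix of ASA class (1-4) probabilities per type.
#' @param staff_lambda Named per-type mean staff count.
#' @param emergency_prob Named per-type emergency probability.
#' @param seed Integer seed.
#' @return Schedule tibble in the [read_schedule()] layout.
#' @export
simulate_schedule <- function(n_procedures,
                              type_mix = c(OS = 0.15, MIS = 0.65, RAS = 0.20),
                              planned_means = rbind(
                                OS = c(35, 90, 25),
                                MIS = c(25, 55, 20),
                                RAS = c(40, 80, 30)
                              ),
                              planned_cv = 0.15,
                              deviation_mean = c(OS = -8, MIS = 0, RAS = 7),
                              deviation_sd = 6,
                              risk_probs = rbind(
                                OS = c(0.10, 0.30, 0.40, 0.20),
                                MIS = c(0.25, 0.45, 0.25, 0.05),
                                RAS = c(0.40, 0.45, 0.13, 0.02)
                              ),
                              staff_lambda = c(OS = 7, MIS = 5, RAS = 7),
                              emergency_prob = c(OS = 0.15, MIS = 0.05, RAS = 0.01),
                              seed = 1L) {
  assert_count(n_procedures, "n_procedures")
  if (length(type_mix) != 3L || abs(sum(type_mix) - 1) > 1e-8 || any(type_mix < 0)) {
    abort("`type_mix` must be 3 non-negative proportions summing to 1")
  }
  names(type_mix) <- names(type_mix) %||% surgery_types()

  empty <- tibble(
    procedure_id = character(), surgery_type = character(),
    risk_class = integer(), emergency_flag = logical(), staff_count = integer(),
    planned_phase1_min = double(), planned_phase2_min = double(),
    planned_phase3_min = double(),
    actual_phase1_min = double(), actual_phase2_min = double(),
    actual_phase3_min = double()
  )
  if (n_procedures == 0L) return(empty)

  withr::with_seed(seed, {
    types <- sample(surgery_types(), n_procedures, replace = TRUE,
                    prob = type_mix[surgery_types()])
    rows <- purrr::map(seq_len(n_procedures), function(i) {
      ty <- types[i]
      pm <- planned_means[ty, ]
      planned <- pmax(1, rnorm(3, pm, planned_cv * pm))
      dev <- rnorm(1, deviation_mean[ty], deviation_sd)
      actual <- pmax(1, planned + dev / 3)
      tibble(
        procedure_id = sprintf("proc%04d", i),
        surgery_type = ty,
        risk_class = sample(1:4, 1L, prob = risk_probs[ty, ]),
        emergency_flag = unname(runif(1) < emergency_prob[[ty]]),
        staff_count = max(1L, stats::rpois(1, staff_lambda[[ty]])),
        planned_phase1_min = planned[1], planned_phase2_min = planned[2],
        planned_phase3_min = planned[3],
        actual_phase1_min = actual[1], actual_phase2_min = actual[2],
        actual_phase3_min = actual[3]
      )
    })
    bind_rows(rows)
  })
}
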