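#' Surgical phase timeline of one procedure
#'
#' A procedure is split into three clinical phases delimited by four ordered
#' events: phase 1 runs from patient entry to first incision, phase 2 from
#' incision to closing (the "cutting phase", typically under dimmed lights),
#' and phase 3 from closing to patient exit. Boundaries are 0-based frame
#' indices in the analysed video.
#'
#' @param procedure_id Label of the procedure.
#' @param surgery_type One of `"OS"`, `"MIS"`, `"RAS"` (open / minimally
#'   invasive / robotic-assisted surgery).
#' @param phase1_start,incision,closing,patient_exit Strictly increasing
#'   frame indices.
#' @param fps Frames per second of the video, used when converting frame
#'   counts to seconds.
#' @return A one-row `phase_timeline` tibble.
#' @export
#' @examples
#' tl <- phase_timeline("P1", "MIS", 0, 500, 2000, 2600, fps = 25)
#' phase_of_frame(tl, c(0, 499, 500, 2599))
phase_timeline <- function(procedure_id, surgery_type,
                           phase1_start, incision, closing, patient_exit,
                           fps = 25) {
  surgery_type <- match.arg(surgery_type, surgery_types())
  b <- c(phase1_start, incision, closing, patient_exit)
  if (any(!is.finite(b)) || any(diff(b) <= 0)) {
    abort("phase boundaries must be finite and strictly increasing")
  }
  assert_number(fps, "fps", lower = 0, strict_lower = TRUE)
  structure(
    tibble(
      procedure_id = as.character(procedure_id),
      surgery_type = surgery_type,
      phase1_start = phase1_start, incision = incision,
      closing = closing, patient_exit = patient_exit,
      fps = fps
    ),
    class = c("phase_timeline", "tbl_df", "tbl", "data.frame")
  )
}

#' The three surgery technology levels
#' @return `c("OS", "MIS", "RAS")`.
#' @export
surgery_types <- function() c("OS", "MIS", "RAS")

#' Phase membership of frames
#'
#' @param timeline A [phase_timeline()].
#' @param frame Vector of frame indices.
#' @return Integer vector: 1, 2 or 3, or `NA` outside the procedure.
#' @export
phase_of_frame <- function(timeline, frame) {
  stopifnot(nrow(timeline) == 1L)
  dplyr::case_when(
    frame < timeline$phase1_start ~ NA_integer_,
    frame < timeline$incision ~ 1L,
    frame < timeline$closing ~ 2L,
    frame < timeline$patient_exit ~ 3L,
    TRUE ~ NA_integer_
  )
}

#' Frame ranges and durations per phase
#'
#' @param timeline A [phase_timeline()].
#' @return Tibble with one row per phase: `phase`, `start`, `end`
#'   (half-open frame range), `n_frames`, `duration_s`.
#' @export
phase_frames <- function(timeline) {
  stopifnot(nrow(timeline) == 1L)
  starts <- c(timeline$phase1_start, timeline$incision, timeline$closing)
  ends <- c(timeline$incision, timeline$closing, timeline$patient_exit)
  tibble(
    phase = 1:3,
    start = starts,
    end = ends,
    n_frames = ends - starts,
    duration_s = (ends - starts) / timeline$fps
  )
}
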