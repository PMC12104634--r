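#' Read and write per-frame pose detections
#'
#' The on-disk format is a flat delimited table (CSV, UTF-8, '.' decimal):
#' one row per person hypothesis per frame, columns `frame`, `det` and three
#' columns per COCO keypoint (`<name>_x`, `<name>_y`, `<name>_conf`), 53
#' columns in total. Absent keypoints are empty fields — distinct from a
#' keypoint detected with confidence 0. In memory detections are a long
#' tibble with one row per present keypoint: `frame`, `det`, `keypoint`,
#' `x`, `y`, `confidence` — the tidy shape every downstream verb consumes.
#'
#' @param path File path.
#' @return `read_detections()`: a long detections tibble sorted by frame;
#'   `write_detections()`: `path`, invisibly.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- detection_columns()
  extra <- setdiff(names(wide), expected)
  if (length(extra) > 0L) {
    bad <- sub("_(x|y|conf)$", "", extra)
    abort(sprintf(
      "%s: unknown column(s) %s (unknown keypoint name?)",
      path, paste(extra, collapse = ", ")
    ))
  }
  assert_columns(wide, c("frame", "det"), path)
  if (nrow(wide) == 0L) {
    return(tibble(frame = integer(), det = integer(), keypoint = character(),
                  x = double(), y = double(), confidence = double()))
  }
  missing_kp_cols <- setdiff(expected, names(wide))
  for (cc in missing_kp_cols) wide[[cc]] <- NA_real_
  long <- detections_long(wide)
  # validate with row/field context: re-scan the wide table
  check_detection_values(wide, path)
  validate_poses(long, id_col = "det", what = path)
  long %>% arrange(.data$frame, .data$det, match(.data$keypoint, coco_keypoints()))
}

detection_columns <- function() {
  kp <- coco_keypoints()
  c("frame", "det", as.vector(rbind(
    paste0(kp, "_x"), paste0(kp, "_y"), paste0(kp, "_conf")
  )))
}

detections_long <- function(wide) {
  kp <- coco_keypoints()
  pieces <- purrr::map(kp, function(k) {
    tibble(
      frame = wide$frame, det = wide$det, keypoint = k,
      x = wide[[paste0(k, "_x")]],
      y = wide[[paste0(k, "_y")]],
      confidence = wide[[paste0(k, "_conf")]]
    )
  })
  bind_rows(pieces) %>% filter(!is.na(.data$x) & !is.na(.data$y))
}

check_detection_values <- function(wide, path) {
  kp <- coco_keypoints()
  for (k in kp) {
    cc <- paste0(k, "_conf")
    bad <- which(!is.na(wide[[cc]]) & (wide[[cc]] < 0 | wide[[cc]] > 1))
    if (length(bad) > 0L) {
      abort(sprintf(
        "%s: row %d, field %s: confidence %s outside [0, 1]",
        path, bad[1], cc, format(wide[[cc]][bad[1]])
      ))
    }
    xc <- paste0(k, "_x"); yc <- paste0(k, "_y")
    half <- which(is.na(wide[[xc]]) != is.na(wide[[yc]]))
    if (length(half) > 0L) {
      abort(sprintf(
        "%s: row %d, field %s/%s: keypoint with only one coordinate",
        path, half[1], xc, yc
      ))
    }
  }
  bad_f <- which(is.na(wide$frame) | wide$frame < 0 | wide$frame != floor(wide$frame))
  if (length(bad_f) > 0L) {
    abort(sprintf("%s: row %d, field frame: must be a non-negative integer", path, bad_f[1]))
  }
  invisible(TRUE)
}

#' @rdname read_detections
#' @param detections Long detections tibble (`frame`, `det`, `keypoint`,
#'   `x`, `y`, `confidence`).
#' @export
write_detections <- function(detections, path) {
  validate_poses(detections, id_col = "det", what = "detections")
  ids <- detections %>% distinct(.data$frame, .data$det) %>% arrange(.data$frame, .data$det)
  kp <- coco_keypoints()
  wide <- ids
  for (k in kp) {
    sub <- detections %>% filter(.data$keypoint == k)
    m <- ids %>% left_join(sub, by = c("frame", "det"))
    wide[[paste0(k, "_x")]] <- m$x
    wide[[paste0(k, "_y")]] <- m$y
    wide[[paste0(k, "_conf")]] <- m$confidence
  }
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read and write zone annotations (JSON)
#'
#' Zones are stored as a JSON object with `camera_id` and one array of
#' `[x, y]` vertex pairs per zone. Invalid polygons (< 3 vertices, zero
#' area, self-intersecting) are rejected at load time.
#'
#' @param path File path.
#' @return `read_zones()`: a [zone_set()].
#' @export
read_zones <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("wrist_zone", "shoulder_zone", "head_zone")) {
    if (is.null(j[[nm]])) abort(sprintf("%s: missing zone `%s`", path, nm))
  }
  poly <- function(m) tibble(x = m[, 1], y = m[, 2])
  zone_set(
    wrist_zone = poly(as.matrix(j$wrist_zone)),
    shoulder_zone = poly(as.matrix(j$shoulder_zone)),
    head_zone = poly(as.matrix(j$head_zone)),
    camera_id = j$camera_id %||% "cam1"
  )
}

#' @rdname read_zones
#' @param zones A [zone_set()].
#' @export
write_zones <- function(zones, path) {
  stopifnot(inherits(zones, "zone_set"))
  obj <- list(
    camera_id = zones$camera_id,
    wrist_zone = unname(as.matrix(zones$wrist_zone)),
    shoulder_zone = unname(as.matrix(zones$shoulder_zone)),
    head_zone = unname(as.matrix(zones$head_zone))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write a phase timeline (JSON)
#'
#' @param path File path.
#' @return `read_timeline()`: a [phase_timeline()].
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- j$boundaries
  for (nm in c("phase1_start", "incision", "closing", "patient_exit")) {
    if (is.null(b[[nm]])) abort(sprintf("%s: missing boundary `%s`", path, nm))
  }
  phase_timeline(
    procedure_id = j$procedure_id %||% "procedure",
    surgery_type = j$surgery_type,
    phase1_start = b$phase1_start, incision = b$incision,
    closing = b$closing, patient_exit = b$patient_exit,
    fps = j$fps %||% 25
  )
}

#' @rdname read_timeline
#' @param timeline A [phase_timeline()].
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "phase_timeline"))
  obj <- list(
    procedure_id = timeline$procedure_id,
    surgery_type = timeline$surgery_type,
    fps = timeline$fps,
    boundaries = list(
      phase1_start = timeline$phase1_start, incision = timeline$incision,
      closing = timeline$closing, patient_exit = timeline$patient_exit
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write hospital schedule records (CSV)
#'
#' One row per procedure: identifier, surgery type, ASA-like patient risk
#' class, emergency flag, staff count and planned/actual duration (minutes)
#' per clinical phase. Missing durations are permitted on read; downstream
#' summaries apply complete-case filtering.
#'
#' @param path File path.
#' @return `read_schedule()`: a tibble of procedure records.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_schedule(df, what = path)
}

validate_schedule <- function(df, what = "schedule") {
  req <- c(
    "procedure_id", "surgery_type", "risk_class", "emergency_flag", "staff_count",
    paste0("planned_phase", 1:3, "_min"), paste0("actual_phase", 1:3, "_min")
  )
  assert_columns(df, req, what)
  bad_type <- which(!df$surgery_type %in% surgery_types())
  if (length(bad_type) > 0L) {
    abort(sprintf(
      "%s: row %d, field surgery_type: %s is not one of %s",
      what, bad_type[1], df$surgery_type[bad_type[1]],
      paste(surgery_types(), collapse = "/")
    ))
  }
  dur_cols <- c(paste0("planned_phase", 1:3, "_min"), paste0("actual_phase", 1:3, "_min"))
  for (cc in dur_cols) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad) > 0L) {
      abort(sprintf("%s: row %d, field %s: negative duration", what, bad[1], cc))
    }
  }
  bad_staff <- which(!is.na(df$staff_count) & df$staff_count < 0)
  if (length(bad_staff) > 0L) {
    abort(sprintf("%s: row %d, field staff_count: negative", what, bad_staff[1]))
  }
  as_tibble(df)
}

#' @rdname read_schedule
#' @param records Schedule tibble as returned by [read_schedule()] or
#'   [simulate_schedule()].
#' @export
write_schedule <- function(records, path) {
  validate_schedule(records)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read and write questionnaire responses (CSV)
#'
#' Long format, one row per answered cell: `respondent`, `domain` (one of
#' the seven instrument domains), `surgery_type`, `phase`, `score` on the
#' 0-20 scale. A respondent with fewer than the full 7 x 3 x 3 = 63 rows
#' (or with empty `score` fields) is incomplete. Scores outside [0, 20]
#' are rejected at load time.
#'
#' @param path File path.
#' @return `read_surgtlx()`: a long response tibble.
#' @export
read_surgtlx <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_surgtlx(df, what = path)
}

validate_surgtlx <- function(df, what = "responses") {
  assert_columns(df, c("respondent", "domain", "surgery_type", "phase", "score"), what)
  bad_dom <- which(!df$domain %in% surgtlx_domains())
  if (length(bad_dom) > 0L) {
    abort(sprintf(
      "%s: row %d, field domain: unknown domain %s",
      what, bad_dom[1], df$domain[bad_dom[1]]
    ))
  }
  bad_type <- which(!df$surgery_type %in% surgery_types())
  if (length(bad_type) > 0L) {
    abort(sprintf("%s: row %d, field surgery_type: invalid", what, bad_type[1]))
  }
  bad_phase <- which(!df$phase %in% 1:3)
  if (length(bad_phase) > 0L) {
    abort(sprintf("%s: row %d, field phase: must be 1, 2 or 3", what, bad_phase[1]))
  }
  bad_score <- which(!is.na(df$score) & (df$score < 0 | df$score > 20))
  if (length(bad_score) > 0L) {
    abort(sprintf(
      "%s: row %d, field score: %s outside the 0-20 scale",
      what, bad_score[1], format(df$score[bad_score[1]])
    ))
  }
  dup <- df %>% count(.data$respondent, .data$domain, .data$surgery_type, .data$phase) %>%
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf(
      "%s: duplicated cell for respondent %s (%s, %s, phase %d)",
      what, dup$respondent[1], dup$domain[1], dup$surgery_type[1], dup$phase[1]
    ))
  }
  as_tibble(df)
}

#' @rdname read_surgtlx
#' @param responses Long response tibble.
#' @export
write_surgtlx <- function(responses, path) {
  validate_surgtlx(responses)
  readr::write_csv(responses, path, progress = FALSE)
  invisible(path)
}
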