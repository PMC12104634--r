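# Independent re-implementations of the written rules, used as oracles.
# Deliberately scalar and loop-based; they share no code path with the
# package's vectorised implementations.

# ray-casting point-in-polygon, boundary counted as inside
pip_ray <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    # on-segment check (boundary inclusive)
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) < 1e-9 &&
        px >= min(xi, xj) - 1e-9 && px <= max(xi, xj) + 1e-9 &&
        py >= min(yi, yj) - 1e-9 && py <= max(yi, yj) + 1e-9) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      x_int <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

# brute-force frame-by-frame activity classification from the written
# rules: both wrists in wrist zone, both shoulders in shoulder zone, head
# centroid (present nose/eyes/ears) in head zone; veto when the mean
# shoulder/head displacement over `window` frames strictly exceeds the
# threshold; undetermined when a required point or the displacement is
# missing and no definite rule fires
oracle_classify <- function(poses, zones, threshold = 17.5, window = 5,
                            min_conf = 0.3) {
  ids <- sort(unique(poses$track_id))
  out <- list()
  for (id in ids) {
    tp <- poses[poses$track_id == id, ]
    frames <- sort(unique(tp$frame))
    by_frame <- split(as.data.frame(tp), tp$frame)
    get_kp <- function(f, kp) {
      fr <- by_frame[[as.character(f)]]
      if (is.null(fr)) return(NULL)
      r <- fr[fr$keypoint == kp, ]
      r <- r[!is.na(r$confidence) & r$confidence >= min_conf, ]
      if (nrow(r) == 0) NULL else c(r$x[1], r$y[1])
    }
    get_head <- function(f) {
      pts <- list()
      for (kp in c("nose", "left_eye", "right_eye", "left_ear", "right_ear")) {
        p <- get_kp(f, kp)
        if (!is.null(p)) pts[[length(pts) + 1]] <- p
      }
      if (length(pts) == 0) NULL else colMeans(do.call(rbind, pts))
    }
    in_poly <- function(p, poly) pip_ray(p[1], p[2], poly$x, poly$y)
    statuses <- character(length(frames))
    for (k in seq_along(frames)) {
      f <- frames[k]
      lw <- get_kp(f, "left_wrist"); rw <- get_kp(f, "right_wrist")
      ls <- get_kp(f, "left_shoulder"); rs <- get_kp(f, "right_shoulder")
      hd <- get_head(f)
      zone <- if (is.null(lw) || is.null(rw) || is.null(ls) || is.null(rs) ||
                  is.null(hd)) {
        "undetermined"
      } else if (in_poly(lw, zones$wrist_zone) && in_poly(rw, zones$wrist_zone) &&
                 in_poly(ls, zones$shoulder_zone) && in_poly(rs, zones$shoulder_zone) &&
                 in_poly(hd, zones$head_zone)) {
        "pass"
      } else {
        "fail"
      }
      disp <- NA_real_
      if (f >= window && (f - window) %in% frames) {
        ls0 <- get_kp(f - window, "left_shoulder")
        rs0 <- get_kp(f - window, "right_shoulder")
        hd0 <- get_head(f - window)
        if (!is.null(ls) && !is.null(rs) && !is.null(hd) &&
            !is.null(ls0) && !is.null(rs0) && !is.null(hd0)) {
          disp <- mean(c(
            sqrt(sum((ls - ls0)^2)),
            sqrt(sum((rs - rs0)^2)),
            sqrt(sum((hd - hd0)^2))
          ))
        }
      }
      statuses[k] <- if (zone == "fail" || (!is.na(disp) && disp > threshold)) {
        "inactive"
      } else if (zone == "pass" && !is.na(disp)) {
        "active"
      } else {
        "undetermined"
      }
    }
    out[[length(out) + 1]] <- data.frame(track_id = id, frame = frames,
                                         status = statuses)
  }
  do.call(rbind, out)
}

# exhaustive one-to-one matching maximizing total similarity over pairs at
# or above the threshold; returns the maximal total similarity
oracle_best_matching <- function(sim, threshold) {
  nr <- nrow(sim); nc <- ncol(sim)
  if (nr == 0 || nc == 0) return(0)
  best <- 0
  assign_next <- function(row, used_cols, total) {
    if (row > nr) {
      best <<- max(best, total)
      return(invisible())
    }
    assign_next(row + 1, used_cols, total) # leave this row unmatched
    for (cc in seq_len(nc)) {
      if (!used_cols[cc] && sim[row, cc] >= threshold) {
        used_cols[cc] <- TRUE
        assign_next(row + 1, used_cols, total + sim[row, cc])
        used_cols[cc] <- FALSE
      }
    }
  }
  assign_next(1, rep(FALSE, nc), 0)
  best
}

# identity switches of a tracking result against the simulator's
# detection-to-person map: a switch is a change in the true person label
# along one track's frame-ordered assignments
count_id_switches <- function(tracks, det_map) {
  m <- merge(as.data.frame(tracks$poses[, c("track_id", "frame", "det")]),
             as.data.frame(det_map), by = c("frame", "det"))
  m <- unique(m[, c("track_id", "frame", "person")])
  m <- m[order(m$track_id, m$frame), ]
  switches <- 0L
  for (id in unique(m$track_id)) {
    p <- m$person[m$track_id == id]
    if (length(p) > 1) switches <- switches + sum(diff(p) != 0)
  }
  switches
}

# small pose builder for hand-constructed cases
mk_pose <- function(...) {
  kps <- list(...)
  tibble::tibble(
    keypoint = names(kps),
    x = vapply(kps, function(p) p[1], numeric(1)),
    y = vapply(kps, function(p) p[2], numeric(1)),
    confidence = vapply(kps, function(p) if (length(p) > 2) p[3] else 1, numeric(1))
  )
}

# square zone set used across hand-constructed activity tests
square_zones <- function() {
  zone_set(
    wrist_zone = data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
    shoulder_zone = data.frame(x = c(-50, 150, 150, -50), y = c(-50, -50, 150, 150)),
    head_zone = data.frame(x = c(-100, 200, 200, -100), y = c(-100, -100, 200, 200))
  )
}

# full-body pose rows for one (track, frame): body centre + in-zone wrists
full_pose_rows <- function(track_id, frame, cx, cy, wrist_xy = NULL, conf = 1) {
  kp <- coco_keypoints()
  dx <- c(0, -4, 4, -8, 8, -18, 18, -24, 24, -20, 20, -12, 12, -12, 12, -12, 12)
  dy <- c(-6, -9, -9, -10, -10, 0, 0, 12, 12, 24, 24, 30, 30, 52, 52, 74, 74)
  df <- tibble::tibble(track_id = track_id, frame = frame, keypoint = kp,
                       x = cx + dx, y = cy + dy, confidence = conf)
  if (!is.null(wrist_xy)) {
    df$x[df$keypoint == "left_wrist"] <- wrist_xy[1]
    df$y[df$keypoint == "left_wrist"] <- wrist_xy[2]
    df$x[df$keypoint == "right_wrist"] <- wrist_xy[3]
    df$y[df$keypoint == "right_wrist"] <- wrist_xy[4]
  }
  df
}

# random small scene configs for oracle-equivalence sweeps
random_scene <- function(seed, max_staff = 5, max_frames = 200) {
  withr::with_seed(seed * 1000 + 17, {
    n_staff <- sample(0:max_staff, 1)
    total_s <- runif(1, 2, max_frames / 25)
    durs <- total_s * c(0.25, 0.5, 0.25)
    jitter <- runif(1, 0, 3)
    dropout <- runif(1, 0, 0.1)
    scene_config(
      n_staff = n_staff, phase_durations = durs,
      jitter_sd = jitter, dropout_rate = dropout, seed = seed
    )
  })
}

# classify a scene's detections under the true person identities
classify_scene_truthid <- function(scene, params = activity_params()) {
  poses <- dplyr::inner_join(scene$detections, scene$truth$det_map,
                             by = c("frame", "det"))
  poses <- dplyr::select(poses, track_id = "person", "frame", "keypoint",
                         "x", "y", "confidence")
  classify_activity(poses, scene$zones, params)
}
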