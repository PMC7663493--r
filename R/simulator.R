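#' Anthropometric profile of a simulated person
#'
#' Head breadth (the inter-ear distance, which sets every detector
#' threshold) follows the dimensional data for a 40-year-old American male:
#' 5th percentile 14.8 cm, 50th 15.7 cm, 95th 16.8 cm. The remaining fields
#' only shape the static body pose.
#'
#' @param preset `"p50"`, `"p05"` or `"p95"` head-breadth percentile preset.
#' @param head_breadth_cm Override the preset head breadth.
#' @param height_cm Standing height (default 175).
#' @param shoulder_width_cm,arm_length_cm Pose parameters.
#' @return List of class `anthropometric_profile`.
#' @export
#' @examples
#' anthropometric_profile("p95")$head_breadth_cm
anthropometric_profile <- function(preset = c("p50", "p05", "p95"),
                                   head_breadth_cm = NULL, height_cm = 175,
                                   shoulder_width_cm = 46, arm_length_cm = 74) {
  preset <- match.arg(preset)
  hb <- c(p05 = 14.8, p50 = 15.7, p95 = 16.8)[[preset]]
  if (!is.null(head_breadth_cm)) hb <- head_breadth_cm
  stopifnot(hb > 0, height_cm > 0)
  structure(list(preset = preset, head_breadth_cm = hb, height_cm = height_cm,
                 shoulder_width_cm = shoulder_width_cm,
                 arm_length_cm = arm_length_cm),
            class = "anthropometric_profile")
}

#' Gesture script for the simulator
#'
#' A script is an ordered table of gesture specifications. Kinds:
#' `contact` (thumb touches a target face area: `mouth_nose`, `right_eye`,
#' `left_eye`, `right_ear`, `left_ear`), `low_risk_touch` (thumb enters the
#' contact volume but stays beyond the low-risk threshold from every
#' landmark), `occlusion` (hand raised between camera and face, no contact),
#' and `idle`. Each gesture has an onset, an approach duration, a hold
#' duration and a return phase equal to the approach; gestures of one hand
#' must not overlap in time.
#'
#' @param df Data frame with columns `kind`, `target` (`NA` except for
#'   `contact`), `onset_s`, `approach_s`, `hold_s`, `hand` (`left`/`right`).
#' @return Validated data frame of class `gesture_script`.
#' @export
gesture_script <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("kind", "target", "onset_s", "approach_s", "hold_s", "hand")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("gesture script is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, needed]
  kinds <- c("contact", "low_risk_touch", "occlusion", "idle")
  if (!all(df$kind %in% kinds)) {
    stop("gesture kind must be one of: ", paste(kinds, collapse = ", "))
  }
  targets <- setdiff(contact_areas(), "low_risk")
  bad <- df$kind == "contact" & !(df$target %in% targets)
  if (any(bad)) stop("contact gestures need a target in: ",
                     paste(targets, collapse = ", "))
  if (!all(df$hand %in% c("left", "right"))) stop("hand must be left or right")
  if (any(df$onset_s < 0 | df$approach_s <= 0 | df$hold_s <= 0)) {
    stop("onset_s must be >= 0 and approach_s, hold_s > 0")
  }
  df <- df[order(df$onset_s), , drop = FALSE]
  for (h in c("left", "right")) {
    sub <- df[df$hand == h & df$kind != "idle", , drop = FALSE]
    if (nrow(sub) > 1L) {
      ends <- sub$onset_s + 2 * sub$approach_s + sub$hold_s
      if (any(sub$onset_s[-1L] < ends[-nrow(sub)])) {
        stop("gestures overlap in time for the ", h, " hand")
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("gesture_script", "data.frame")
  df
}

#' Joint-noise model
#'
#' Isotropic zero-mean Gaussian jitter applied per joint per frame, and
#' independent dropout of face/thumb joints. Identical seeds give identical
#' streams. The default jitter (5 mm) is small relative to the >= 100 mm
#' contact radius, mimicking the slight coordinate jitter of depth-based
#' body tracking.
#'
#' @param jitter_sd_mm Jitter standard deviation per axis, mm.
#' @param dropout_prob Per-frame probability that a face or thumb joint is
#'   missing.
#' @param seed Integer RNG seed.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(jitter_sd_mm = 5, dropout_prob = 0, seed = 1L) {
  stopifnot(jitter_sd_mm >= 0, dropout_prob >= 0, dropout_prob <= 1)
  structure(list(jitter_sd_mm = jitter_sd_mm, dropout_prob = dropout_prob,
                 seed = as.integer(seed)), class = "noise_model")
}

# static 32-joint pose, mm, camera space (x right, y down, z away); the
# sensor sits at the origin, `sensor_height_mm` above the ground plane
base_pose <- function(profile, distance_mm, sensor_height_mm) {
  h <- profile$height_cm * 10
  r <- profile$head_breadth_cm * 10 / 2
  sw <- profile$shoulder_width_cm * 10
  ground <- sensor_height_mm
  hc <- c(0, ground - (h - 110), distance_mm)   # head-sphere center
  pelvis <- c(0, ground - 0.53 * h, distance_mm)
  at <- function(dx, dy, dz, from = hc) from + c(dx, dy, dz)
  pose <- list(
    head = at(0, 0.25 * r, 0),
    neck = at(0, 1.8 * r, 0),
    nose = at(0, 0.15 * r, -1.0 * r),
    eye_l = at(0.35 * r, -0.3 * r, -0.85 * r),
    eye_r = at(-0.35 * r, -0.3 * r, -0.85 * r),
    ear_l = at(r, 0, 0),
    ear_r = at(-r, 0, 0),
    pelvis = pelvis,
    spine_navel = pelvis + c(0, -150, 0),
    spine_chest = at(0, 3.2 * r, 20),
    clavicle_l = at(0.15 * sw, 2.6 * r, 0),
    clavicle_r = at(-0.15 * sw, 2.6 * r, 0),
    shoulder_l = at(0.5 * sw, 2.8 * r, 0),
    shoulder_r = at(-0.5 * sw, 2.8 * r, 0),
    elbow_l = at(0.55 * sw, 2.8 * r + 280, -20),
    elbow_r = at(-0.55 * sw, 2.8 * r + 280, -20),
    hip_l = pelvis + c(100, 30, 0),
    hip_r = pelvis + c(-100, 30, 0),
    knee_l = pelvis + c(100, 0.22 * h, 0),
    knee_r = pelvis + c(-100, 0.22 * h, 0),
    ankle_l = pelvis + c(100, 0.44 * h, 0),
    ankle_r = pelvis + c(-100, 0.44 * h, 0),
    foot_l = pelvis + c(100, 0.46 * h, -120),
    foot_r = pelvis + c(-100, 0.46 * h, -120)
  )
  # resting hand chains at hip height, far below every detector threshold
  for (side in c("l", "r")) {
    s <- if (side == "l") 1 else -1
    thumb <- pelvis + c(s * 250, 0, -100)
    pose[[paste0("thumb_", side)]] <- thumb
    pose[[paste0("wrist_", side)]] <- thumb + c(s * 20, 60, 30)
    pose[[paste0("hand_", side)]] <- thumb + c(s * 10, 30, 10)
    pose[[paste0("handtip_", side)]] <- thumb + c(0, -30, -30)
  }
  pose[K4A_JOINTS]
}

# gesture target point for the thumb, from the noiseless pose
gesture_target <- function(gesture, pose, contact_ratio = 0.70,
                           contact_offset_mm = 10) {
  hc <- (pose$ear_l + pose$ear_r) / 2
  interear <- sqrt(sum((pose$ear_l - pose$ear_r)^2))
  rc <- contact_ratio * interear
  unit <- function(v) v / sqrt(sum(v^2))
  if (gesture$kind == "contact") {
    lmj <- c(mouth_nose = "nose", right_eye = "eye_r", left_eye = "eye_l",
             right_ear = "ear_r", left_ear = "ear_l")[[gesture$target]]
    lm <- pose[[lmj]]
    lm + contact_offset_mm * unit(lm - hc)
  } else if (gesture$kind == "low_risk_touch") {
    # up-and-back of the head: inside the volume, far from every landmark
    hc + 0.93 * rc * unit(c(0, -0.35, 0.937))
  } else if (gesture$kind == "occlusion") {
    # on the head-to-sensor line, in front of the face, outside the volume
    hc + 1.5 * rc * unit(-hc)
  } else {
    NULL
  }
}

# thumb position at time t for one gesture; staging keeps the approach
# radial near the head so entry/exit and the touched region are unambiguous
gesture_thumb_path <- function(t, gesture, target, rest, hc, rc) {
  a <- gesture$approach_s
  t0 <- gesture$onset_s
  t1 <- t0 + a
  t2 <- t1 + gesture$hold_s
  t3 <- t2 + a
  if (t < t0 || t > t3) return(rest)
  unit <- function(v) v / sqrt(sum(v^2))
  staging <- if (gesture$kind == "occlusion") target else {
    hc + (rc + 0.4 * rc / 0.7) * unit(target - hc)
  }
  lerp <- function(p, q, f) p + f * (q - p)
  if (t < t1) {                       # approach: rest -> staging -> target
    f <- (t - t0) / a
    if (f < 0.8) lerp(rest, staging, f / 0.8) else lerp(staging, target, (f - 0.8) / 0.2)
  } else if (t <= t2) {
    target
  } else {                            # return, mirrored
    f <- (t - t2) / a
    if (f < 0.2) lerp(target, staging, f / 0.2) else lerp(staging, rest, (f - 0.2) / 0.8)
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a skeleton stream with known ground truth
#'
#' Emulates a person standing in front of the depth sensor (default 2 m
#' away, sensor 170 cm above ground) executing scripted hand-to-face
#' gestures. The trunk and legs are static; during a gesture the scripted
#' hand's thumb (with its wrist/hand/handtip chain) moves on a
#' piecewise-linear path from a rest pose at hip height to the target, holds
#' and returns, with the final approach segment radial to the head so the
#' touched region is unambiguous. Ground-truth labels and events derive from
#' the noiseless trajectory; jitter and dropout only corrupt the emitted
#' stream.
#'
#' @param script A [gesture_script].
#' @param profile An [anthropometric_profile].
#' @param noise A [noise_model] (default: noiseless, seed 1).
#' @param fps Frame rate (default 30).
#' @param distance_mm Standing distance from the sensor.
#' @param sensor_height_mm Sensor height above the ground.
#' @param body_id Body id of the simulated person.
#' @param contact_offset_mm Radial offset of the thumb beyond the target
#'   landmark at full touch (default 10).
#' @param config [detection_config] whose ratios define the truth geometry.
#' @return List of class `sim_stream`: `stream` (a [skeleton_stream]),
#'   `truth_events` ([event_records], including occlusion events),
#'   `truth_labels` (`frame_labels` of the noiseless trajectory) and
#'   `script`.
#' @export
generate_stream <- function(script, profile = anthropometric_profile(),
                            noise = noise_model(0, 0, 1L), fps = 30,
                            distance_mm = 2000, sensor_height_mm = 1700,
                            body_id = 0L, contact_offset_mm = 10,
                            config = detection_config()) {
  script <- gesture_script(script)
  stopifnot(fps > 0)
  pose <- base_pose(profile, distance_mm, sensor_height_mm)
  hc <- (pose$ear_l + pose$ear_r) / 2
  interear <- sqrt(sum((pose$ear_l - pose$ear_r)^2))
  rc <- config$contact_ratio * interear

  active <- script[script$kind != "idle", , drop = FALSE]
  t_end <- if (nrow(active)) {
    max(active$onset_s + 2 * active$approach_s + active$hold_s) + 0.5
  } else max(script$onset_s, 0) + 0.5
  times <- seq(0, t_end, by = 1 / fps)
  nt <- length(times)
  nj <- length(K4A_JOINTS)

  # noiseless joint trajectories: frames x joints x xyz
  A <- array(rep(t(matrix(unlist(pose), nrow = 3)), each = nt),
             dim = c(nt, nj, 3))
  targets <- lapply(seq_len(nrow(active)), function(i) {
    gesture_target(active[i, ], pose, config$contact_ratio, contact_offset_mm)
  })
  state <- rep("no_contact", nt)
  area <- rep(NA_character_, nt)
  for (i in seq_len(nrow(active))) {
    g <- active[i, ]
    rest <- pose[[paste0("thumb_", substr(g$hand, 1, 1))]]
    chain <- paste0(c("thumb_", "wrist_", "hand_", "handtip_"),
                    substr(g$hand, 1, 1))
    offs <- lapply(pose[chain], function(p) p - rest)
    span <- which(times >= g$onset_s & times <= g$onset_s + 2 * g$approach_s + g$hold_s)
    for (k in span) {
      p <- gesture_thumb_path(times[k], g, targets[[i]], rest, hc, rc)
      for (cj in chain) A[k, match(cj, K4A_JOINTS), ] <- p + offs[[cj]]
      if (g$kind %in% c("contact", "low_risk_touch") &&
          sqrt(sum((p - hc)^2)) <= rc) {
        state[k] <- "contact"
        area[k] <- if (g$kind == "contact") g$target else "low_risk"
      }
    }
  }

  truth_labels <- data.frame(timestamp_s = times, body_id = as.integer(body_id),
                             state = state, area = area,
                             hand = NA_character_, degraded = FALSE,
                             stringsAsFactors = FALSE)
  class(truth_labels) <- c("frame_labels", "data.frame")
  truth_events <- group_events(truth_labels)
  occl <- active[active$kind == "occlusion", , drop = FALSE]
  if (nrow(occl)) {
    oev <- do.call(rbind, lapply(seq_len(nrow(occl)), function(i) {
      g <- occl[i, ]
      span <- times[times >= g$onset_s + g$approach_s &
                    times <= g$onset_s + g$approach_s + g$hold_s]
      data.frame(event_id = 0L, body_id = as.integer(body_id),
                 start_s = min(span), end_s = max(span), label = "occlusion",
                 n_frames = length(span))
    }))
    truth_events <- rbind(as.data.frame(truth_events), oev)
    truth_events <- truth_events[order(truth_events$start_s), , drop = FALSE]
    truth_events$event_id <- seq_len(nrow(truth_events))
    truth_events <- event_records(truth_events)
  }

  noisy <- with_seed(noise$seed, {
    B <- A
    if (noise$jitter_sd_mm > 0) {
      B <- B + array(stats::rnorm(length(B), 0, noise$jitter_sd_mm), dim = dim(B))
    }
    drop_mask <- matrix(FALSE, nt, nj)
    if (noise$dropout_prob > 0) {
      dj <- match(c("ear_l", "ear_r", "eye_l", "eye_r", "nose",
                    "thumb_l", "thumb_r"), K4A_JOINTS)
      drop_mask[, dj] <- stats::runif(nt * length(dj)) < noise$dropout_prob
    }
    list(B = B, drop = drop_mask)
  })

  df <- data.frame(
    timestamp_s = rep(times, each = nj),
    body_id = as.integer(body_id),
    joint = rep(K4A_JOINTS, nt),
    x_mm = as.vector(t(noisy$B[, , 1])),
    y_mm = as.vector(t(noisy$B[, , 2])),
    z_mm = as.vector(t(noisy$B[, , 3])),
    confidence = 3L, stringsAsFactors = FALSE
  )
  df <- df[!as.vector(t(noisy$drop)), , drop = FALSE]

  structure(list(stream = skeleton_stream(df), truth_events = truth_events,
                 truth_labels = truth_labels, script = script),
            class = "sim_stream")
}

#' @export
print.sim_stream <- function(x, ...) {
  cat(sprintf("<sim_stream> %d frames, %d truth events (%d gestures scripted)\n",
              nrow(frame_index(x$stream)), nrow(x$truth_events),
              sum(x$script$kind != "idle")))
  invisible(x)
}

#' Simulate a validation session with a requested event-class mix
#'
#' Builds a script containing exactly the requested number of truth events
#' per class (the six contact classes plus occlusions) in seeded random
#' order with idle gaps, alternating hands, and simulates it.
#'
#' @param n_events Named integer vector over
#'   `mouth_nose, right_eye, left_eye, right_ear, left_ear, low_risk,
#'   occlusion` (missing names count as 0).
#' @inheritParams generate_stream
#' @param gap_s Idle gap between consecutive gestures.
#' @param approach_s,hold_s Gesture phase durations.
#' @return A `sim_stream` (see [generate_stream()]).
#' @export
generate_validation_set <- function(n_events, profile = anthropometric_profile(),
                                    noise = noise_model(5, 0, 1L), fps = 30,
                                    gap_s = 0.5, approach_s = 0.4, hold_s = 0.6,
                                    ...) {
  classes <- c(contact_areas(), "occlusion")
  n <- stats::setNames(rep(0L, length(classes)), classes)
  bad <- setdiff(names(n_events), classes)
  if (length(bad)) stop("unknown class(es) in n_events: ", paste(bad, collapse = ", "))
  n[names(n_events)] <- as.integer(n_events)
  seq_classes <- rep(names(n), n)
  if (!length(seq_classes)) {
    script <- gesture_script(data.frame(kind = "idle", target = NA_character_,
                                        onset_s = 0, approach_s = approach_s,
                                        hold_s = hold_s, hand = "right"))
    return(generate_stream(script, profile, noise, fps, ...))
  }
  seq_classes <- with_seed(noise$seed, sample(seq_classes))
  kind <- ifelse(seq_classes == "occlusion", "occlusion",
                 ifelse(seq_classes == "low_risk", "low_risk_touch", "contact"))
  target <- ifelse(kind == "contact", seq_classes, NA_character_)
  onsets <- gap_s + (seq_along(seq_classes) - 1L) * (2 * approach_s + hold_s + gap_s)
  script <- gesture_script(data.frame(
    kind = kind, target = target, onset_s = onsets, approach_s = approach_s,
    hold_s = hold_s,
    hand = rep_len(c("right", "left"), length(kind)), stringsAsFactors = FALSE))
  generate_stream(script, profile, noise, fps, ...)
}

#' Merge simulated streams into a multi-body scene
#'
#' Places each body so that pelvis-pelvis distances equal `separation_mm`
#' (exact for up to 4 bodies: pair, equilateral triangle or tetrahedron in
#' camera space) and merges the streams with distinct body ids.
#'
#' @param streams List of [skeleton_stream] objects sharing a time base.
#' @param separation_mm Pairwise pelvis separation, mm.
#' @return A merged [skeleton_stream].
#' @export
generate_multibody <- function(streams, separation_mm) {
  stopifnot(length(streams) >= 2L, length(streams) <= 4L, separation_mm > 0)
  s <- separation_mm
  offsets <- list(
    rbind(c(-s / 2, 0, 0), c(s / 2, 0, 0)),
    rbind(c(-s / 2, 0, 0), c(s / 2, 0, 0), c(0, 0, s * sqrt(3) / 2)),
    rbind(c(-s / 2, 0, 0), c(s / 2, 0, 0), c(0, 0, s * sqrt(3) / 2),
          c(0, -s * sqrt(2 / 3), s * sqrt(3) / 6))
  )[[length(streams) - 1L]]
  parts <- lapply(seq_along(streams), function(k) {
    st <- as.data.frame(streams[[k]])
    st$x_mm <- st$x_mm + offsets[k, 1]
    st$y_mm <- st$y_mm + offsets[k, 2]
    st$z_mm <- st$z_mm + offsets[k, 3]
    st$body_id <- k - 1L
    st
  })
  skeleton_stream(do.call(rbind, parts))
}
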