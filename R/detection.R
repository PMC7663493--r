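#' Thumb-in-contact-volume test
#'
#' A frame is a hand-face contact when a thumb joint lies inside the contact
#' volume, i.e. its distance from the head-sphere center is at most the
#' contact radius (boundary inclusive, favoring sensitivity). When both
#' thumbs are inside, the one nearer the center triggers.
#'
#' @param frame Single-frame rows of a [skeleton_stream].
#' @param sphere A [compute_head_sphere] result.
#' @return List with `in_contact` (logical), `hand` (`"left"`/`"right"`/`NA`),
#'   `thumb_position` (mm, or `NULL`), `distance_mm` and `degraded` (no thumb
#'   tracked).
#' @export
detect_contact <- function(frame, sphere) {
  tl <- joint_position(frame, "thumb_l")
  tr <- joint_position(frame, "thumb_r")
  if (is.null(tl) && is.null(tr)) {
    return(list(in_contact = FALSE, hand = NA_character_, thumb_position = NULL,
                distance_mm = NA_real_, degraded = TRUE))
  }
  dl <- if (is.null(tl)) Inf else sqrt(sum((tl - sphere$center)^2))
  dr <- if (is.null(tr)) Inf else sqrt(sum((tr - sphere$center)^2))
  if (dl <= dr) {
    hand <- "left"; thumb <- tl; dist <- dl
  } else {
    hand <- "right"; thumb <- tr; dist <- dr
  }
  list(in_contact = dist <= sphere$contact_radius, hand = hand,
       thumb_position = thumb, distance_mm = dist, degraded = FALSE)
}

#' Nearest-landmark contact-area classification (7-way, pre-merge)
#'
#' Assigns the contact to the face landmark nearest to the thumb, which
#' partitions the head sphere into regions like a Voronoi diagram. If the
#' distance to the nearest landmark exceeds the low-risk threshold (strictly),
#' the contact falls in the low-risk area far from mucous membranes. Ties are
#' broken by the fixed priority order
#' nose > mouth > right_eye > left_eye > right_ear > left_ear.
#'
#' @param thumb_position Numeric length-3 (mm).
#' @param landmarks A [face_landmarks] matrix (missing landmarks as `NA`).
#' @param sphere A [compute_head_sphere] result.
#' @return One of `nose, mouth, right_eye, left_eye, right_ear, left_ear,
#'   low_risk`.
#' @export
classify_contact_area <- function(thumb_position, landmarks, sphere) {
  d <- sqrt(rowSums((landmarks - matrix(thumb_position, nrow(landmarks), 3,
                                        byrow = TRUE))^2))
  d[!is.finite(d)] <- Inf
  if (all(is.infinite(d)) || min(d) > sphere$lowrisk_threshold) return("low_risk")
  rownames(landmarks)[which.min(d)]
}

#' Merge the mouth and nose areas
#'
#' The mouth area is adjacent to the nose area, so the 7-way classification
#' is reduced to six classes by merging them into `mouth_nose`.
#'
#' @param area Character vector of 7-way labels.
#' @return Character vector of 6-way labels.
#' @export
#' @examples
#' merge_areas(c("nose", "mouth", "low_risk", "right_eye"))
merge_areas <- function(area) {
  ok <- area %in% c(AREA7, "low_risk")
  if (any(!ok & !is.na(area))) {
    stop("unknown pre-merge area label(s): ",
         paste(unique(area[!ok & !is.na(area)]), collapse = ", "))
  }
  ifelse(area %in% c("nose", "mouth"), "mouth_nose", area)
}

#' Label a single frame / a whole stream
#'
#' `label_frame()` applies the full per-frame pipeline -- head sphere,
#' contact-volume test, mouth synthesis, nearest-landmark classification and
#' the mouth/nose merge -- to one frame. It is a pure function of that frame:
#' no cross-frame state. Frames that are not processable (missing an ear or
#' both thumbs) are labeled `no_contact` with `degraded = TRUE`; face
#' occlusions, by design, also yield plain no-contact frames.
#'
#' `label_stream()` does the same for every frame of a stream, vectorized over
#' frames, returning one row per (timestamp, body).
#'
#' @param frame Single-frame rows of a [skeleton_stream].
#' @param stream A [skeleton_stream].
#' @param config A [detection_config].
#' @return A `frame_labels` data frame with columns `timestamp_s`, `body_id`,
#'   `state` (`contact`/`no_contact`), `area` (six-class label or `NA`),
#'   `hand` (`left`/`right`/`NA`) and `degraded` (logical).
#' @export
label_frame <- function(frame, config = detection_config()) {
  stopifnot(nrow(frame) >= 1L)
  label_stream(skeleton_stream(frame), config)
}

#' @rdname label_frame
#' @export
label_stream <- function(stream, config = detection_config()) {
  stream <- skeleton_stream(stream)
  idx <- frame_index(stream)
  n <- nrow(idx)
  out <- data.frame(timestamp_s = idx$timestamp_s, body_id = idx$body_id,
                    state = rep("no_contact", n), area = rep(NA_character_, n),
                    hand = rep(NA_character_, n), degraded = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("frame_labels", "data.frame")
  if (!n) return(out)

  fkey <- paste(idx$timestamp_s, idx$body_id)
  jm <- function(name) {
    sub <- stream[stream$joint == name, , drop = FALSE]
    i <- match(fkey, paste(sub$timestamp_s, sub$body_id))
    cbind(sub$x_mm[i], sub$y_mm[i], sub$z_mm[i])
  }
  el <- jm("ear_l"); er <- jm("ear_r")
  ctr <- (el + er) / 2
  interear <- sqrt(rowSums((el - er)^2))
  r_contact <- config$contact_ratio * interear
  r_lowrisk <- config$lowrisk_ratio * interear

  tl <- jm("thumb_l"); tr <- jm("thumb_r")
  dl <- sqrt(rowSums((tl - ctr)^2))
  dr <- sqrt(rowSums((tr - ctr)^2))
  dl[!is.finite(dl)] <- Inf
  dr[!is.finite(dr)] <- Inf

  has_ears <- is.finite(interear) & interear > 0
  has_thumb <- is.finite(dl) | is.finite(dr)
  degraded <- !(has_ears & has_thumb)
  out$degraded <- degraded

  use_left <- dl <= dr
  dmin <- pmin(dl, dr)
  contact <- !degraded & dmin <= r_contact
  if (!any(contact)) return(out)

  thumb <- tl
  thumb[!use_left, ] <- tr[!use_left, ]

  # landmarks, priority order: nose, mouth, right_eye, left_eye, right_ear, left_ear
  nose <- jm("nose")
  head <- jm("head"); neck <- jm("neck")
  axis <- neck - head
  axis_len <- sqrt(rowSums(axis^2))
  scale <- ifelse(is.finite(axis_len) & axis_len > 0,
                  0.25 * interear / axis_len, NA_real_)
  mouth <- nose + axis * scale
  fallback <- !is.finite(mouth[, 1]) | !is.finite(mouth[, 2]) | !is.finite(mouth[, 3])
  mouth[fallback, ] <- nose[fallback, ]
  lm <- list(nose = nose, mouth = mouth, right_eye = jm("eye_r"),
             left_eye = jm("eye_l"), right_ear = er, left_ear = el)
  D <- vapply(lm, function(p) sqrt(rowSums((p - thumb)^2)), numeric(n))
  D <- matrix(D, nrow = n)
  D[!is.finite(D)] <- Inf

  nearest <- max.col(-D, ties.method = "first")
  area7 <- c(AREA7, "low_risk")[ifelse(apply(D, 1L, min) > r_lowrisk, 7L, nearest)]
  out$state[contact] <- "contact"
  out$area[contact] <- merge_areas(area7[contact])
  out$hand[contact] <- ifelse(use_left[contact], "left", "right")
  out
}
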