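#' Detection parameters
#'
#' The two thresholds of the detector are expressed as fractions of the
#' inter-ear distance so they adapt to the tracked person's head breadth:
#' the contact sphere radius (default 0.70, i.e. 70% of the inter-ear
#' distance) and the secondary low-risk distance threshold (default 0.75).
#' Both defaults come from an empirical tradeoff tuned toward sensitivity for
#' risk contacts.
#'
#' @param contact_ratio Contact sphere radius as a fraction of the inter-ear
#'   distance.
#' @param lowrisk_ratio Low-risk distance threshold as a fraction of the
#'   inter-ear distance.
#' @return A list with class `detection_config`.
#' @export
detection_config <- function(contact_ratio = 0.70, lowrisk_ratio = 0.75) {
  stopifnot(is.numeric(contact_ratio), contact_ratio > 0,
            is.numeric(lowrisk_ratio), lowrisk_ratio > 0)
  structure(list(contact_ratio = contact_ratio, lowrisk_ratio = lowrisk_ratio),
            class = "detection_config")
}

#' Per-frame head-sphere model
#'
#' The head is modeled as a sphere centered at the midpoint between the two
#' ear joints with diameter equal to their distance. Around it, the contact
#' volume is a concentric sphere of radius `contact_ratio` times the
#' inter-ear distance; a thumb joint inside it defines a hand-face contact.
#' The low-risk threshold is `lowrisk_ratio` times the inter-ear distance.
#'
#' @param frame Single-frame rows of a [skeleton_stream]; both ear joints
#'   must be present and distinct.
#' @inheritParams detection_config
#' @return List of class `head_sphere` with `center` (mm), `interear_mm`,
#'   `head_radius`, `contact_radius`, `lowrisk_threshold` (all mm) and the
#'   two ratios.
#' @export
#' @examples
#' f <- data.frame(timestamp_s = 0, body_id = 0L,
#'                 joint = c("ear_l", "ear_r"),
#'                 x_mm = c(75, -75), y_mm = 0, z_mm = 2000)
#' compute_head_sphere(f)
compute_head_sphere <- function(frame, contact_ratio = 0.70, lowrisk_ratio = 0.75) {
  el <- joint_position(frame, "ear_l")
  er <- joint_position(frame, "ear_r")
  if (is.null(el) || is.null(er)) {
    stop(degraded_frame_condition("missing ear joint: head sphere undefined"))
  }
  d <- sqrt(sum((el - er)^2))
  if (d <= 0) stop("degenerate geometry: zero inter-ear distance")
  structure(list(
    center = (el + er) / 2,
    interear_mm = d,
    head_radius = d / 2,
    contact_radius = contact_ratio * d,
    lowrisk_threshold = lowrisk_ratio * d,
    contact_ratio = contact_ratio,
    lowrisk_ratio = lowrisk_ratio
  ), class = "head_sphere")
}

degraded_frame_condition <- function(msg) {
  structure(class = c("facetouch_degraded_frame", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.head_sphere <- function(x, ...) {
  cat(sprintf(paste0(
    "<head_sphere> center (%.1f, %.1f, %.1f) mm\n",
    "  inter-ear %.1f mm | head radius %.1f mm | contact radius %.1f mm ",
    "(x%.2f) | low-risk threshold %.1f mm (x%.2f)\n"),
    x$center[1], x$center[2], x$center[3], x$interear_mm, x$head_radius,
    x$contact_radius, x$contact_ratio, x$lowrisk_threshold, x$lowrisk_ratio))
  invisible(x)
}

#' Synthesize the mouth landmark
#'
#' The 32-joint skeleton has no mouth joint, but the classifier distinguishes
#' a mouth area (later merged with the nose area). The mouth point is
#' synthesized by offsetting the nose joint by a quarter of the inter-ear
#' distance along the head-to-neck axis, which places it below the nose for
#' any head pose. When the head or neck joint (or the ears needed for the
#' scale) is missing, the nose position is used unchanged -- harmless because
#' mouth and nose merge downstream.
#'
#' @param frame Single-frame rows of a [skeleton_stream]; the nose joint must
#'   be present.
#' @return Numeric length-3 position (mm).
#' @export
derive_mouth_point <- function(frame) {
  nose <- joint_position(frame, "nose")
  if (is.null(nose)) stop("derive_mouth_point: nose joint missing")
  head <- joint_position(frame, "head")
  neck <- joint_position(frame, "neck")
  el <- joint_position(frame, "ear_l")
  er <- joint_position(frame, "ear_r")
  if (is.null(head) || is.null(neck) || is.null(el) || is.null(er)) return(nose)
  axis <- neck - head
  len <- sqrt(sum(axis^2))
  if (len <= 0) return(nose)
  interear <- sqrt(sum((el - er)^2))
  nose + 0.25 * interear * axis / len
}

#' Face landmarks used for contact-area classification
#'
#' The six classification targets: nose, the synthesized mouth point, both
#' eyes and both ears. Missing joints yield `NA` rows; classification then
#' runs over the available subset.
#'
#' @param frame Single-frame rows of a [skeleton_stream].
#' @return 6 x 3 numeric matrix (mm) with rownames
#'   `nose, mouth, right_eye, left_eye, right_ear, left_ear`
#'   (tie-break priority order).
#' @export
face_landmarks <- function(frame) {
  pos <- function(p) if (is.null(p)) rep(NA_real_, 3) else p
  nose <- joint_position(frame, "nose")
  mouth <- if (is.null(nose)) NULL else derive_mouth_point(frame)
  m <- rbind(
    nose = pos(nose),
    mouth = pos(mouth),
    right_eye = pos(joint_position(frame, "eye_r")),
    left_eye = pos(joint_position(frame, "eye_l")),
    right_ear = pos(joint_position(frame, "ear_r")),
    left_ear = pos(joint_position(frame, "ear_l"))
  )
  colnames(m) <- c("x_mm", "y_mm", "z_mm")
  m
}
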