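# Shared fixtures: parametric head frames, an independent straight-line
# oracle for the per-frame classifier, and small random generators.

# One frame with a canonical upright head (half-breadth r, center cc) plus
# optional thumbs and pelvis. Landmark layout mirrors typical tracked
# geometry: eyes up-front, nose frontmost, neck below head.
make_head_frame <- function(r = 75, cc = c(0, 0, 2000), thumb_r = NULL,
                            thumb_l = NULL, t = 0, body = 0L, drop = character()) {
  pos <- list(
    ear_l = cc + c(r, 0, 0),
    ear_r = cc + c(-r, 0, 0),
    eye_l = cc + c(0.35 * r, -0.3 * r, -0.85 * r),
    eye_r = cc + c(-0.35 * r, -0.3 * r, -0.85 * r),
    nose = cc + c(0, 0.15 * r, -r),
    head = cc + c(0, 0.25 * r, 0),
    neck = cc + c(0, 1.8 * r, 0),
    pelvis = cc + c(0, 900, 0)
  )
  if (!is.null(thumb_r)) pos$thumb_r <- thumb_r
  if (!is.null(thumb_l)) pos$thumb_l <- thumb_l
  pos <- pos[setdiff(names(pos), drop)]
  m <- do.call(rbind, pos)
  data.frame(timestamp_s = t, body_id = body, joint = names(pos),
             x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3],
             stringsAsFactors = FALSE)
}

# Independent oracle: literal transcription of the detection rules with
# explicit per-landmark distances, no shared code with the package internals.
oracle_label_frame <- function(frame, contact_ratio = 0.70, lowrisk_ratio = 0.75) {
  jp <- function(n) {
    i <- which(frame$joint == n)
    if (length(i)) as.numeric(frame[i[1], c("x_mm", "y_mm", "z_mm")]) else NULL
  }
  d3 <- function(a, b) sqrt(sum((a - b)^2))
  no_contact <- function(degraded) {
    list(state = "no_contact", area = NA_character_, hand = NA_character_,
         degraded = degraded)
  }
  el <- jp("ear_l"); er <- jp("ear_r")
  tl <- jp("thumb_l"); tr <- jp("thumb_r")
  if (is.null(el) || is.null(er) || (is.null(tl) && is.null(tr))) {
    return(no_contact(TRUE))
  }
  interear <- d3(el, er)
  if (interear <= 0) return(no_contact(TRUE))
  ctr <- (el + er) / 2
  dl <- if (is.null(tl)) Inf else d3(tl, ctr)
  dr <- if (is.null(tr)) Inf else d3(tr, ctr)
  if (dl <= dr) { hand <- "left"; thumb <- tl } else { hand <- "right"; thumb <- tr }
  if (min(dl, dr) > contact_ratio * interear) return(no_contact(FALSE))

  nose <- jp("nose"); head <- jp("head"); neck <- jp("neck")
  mouth <- NULL
  if (!is.null(nose)) {
    mouth <- nose
    if (!is.null(head) && !is.null(neck) && d3(head, neck) > 0) {
      mouth <- nose + 0.25 * interear * (neck - head) / d3(head, neck)
    }
  }
  lms <- list(nose = nose, mouth = mouth, right_eye = jp("eye_r"),
              left_eye = jp("eye_l"), right_ear = er, left_ear = el)
  dist6 <- vapply(lms, function(p) if (is.null(p)) Inf else d3(p, thumb),
                  numeric(1))
  area <- if (all(is.infinite(dist6)) || min(dist6) > lowrisk_ratio * interear) {
    "low_risk"
  } else {
    nm <- names(dist6)[which.min(dist6)]  # which.min: first index on ties
    if (nm %in% c("nose", "mouth")) "mouth_nose" else nm
  }
  list(state = "contact", area = area, hand = hand, degraded = FALSE)
}

# n random frames: varying head breadth and center, right thumb uniform in a
# 0.5 m cube around the head center, left thumb resting far away.
random_frame_batch <- function(n, seed = 1) {
  set.seed(seed)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    r <- runif(1, 65, 90)
    cc <- c(runif(1, -500, 500), runif(1, -300, 300), runif(1, 1500, 2500))
    frames[[i]] <- make_head_frame(
      r = r, cc = cc, t = i / 30, body = 0L,
      thumb_r = cc + runif(3, -250, 250),
      thumb_l = cc + c(250, 900, -100))
  }
  frames
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_frame <- function(frame, R, shift = c(0, 0, 0)) {
  m <- t(R %*% t(as.matrix(frame[, c("x_mm", "y_mm", "z_mm")])))
  frame$x_mm <- m[, 1] + shift[1]
  frame$y_mm <- m[, 2] + shift[2]
  frame$z_mm <- m[, 3] + shift[3]
  frame
}

# random frame-label sequence for event-grouping properties
random_labels <- function(n, seed, bodies = 1L, p_contact = 0.5) {
  set.seed(seed)
  areas <- contact_areas()
  out <- do.call(rbind, lapply(seq_len(bodies) - 1L, function(b) {
    state <- ifelse(runif(n) < p_contact, "contact", "no_contact")
    data.frame(timestamp_s = seq_len(n) / 30, body_id = b, state = state,
               area = ifelse(state == "contact", sample(areas, n, TRUE),
                             NA_character_),
               hand = ifelse(state == "contact", "right", NA_character_),
               degraded = FALSE, stringsAsFactors = FALSE)
  }))
  class(out) <- c("frame_labels", "data.frame")
  out
}

random_confusion <- function(k, seed, lambda = 8) {
  set.seed(seed)
  cls <- paste0("c", seq_len(k))
  m <- matrix(rpois(k * k, lambda), k, k, dimnames = list(cls, cls))
  m[1, 1] <- m[1, 1] + 1L  # never fully empty
  confusion_matrix(m)
}

# default test script touching every contact class once
six_class_script <- function(approach_s = 0.4, hold_s = 0.6) {
  gesture_script(data.frame(
    kind = c(rep("contact", 5), "low_risk_touch"),
    target = c("mouth_nose", "right_eye", "left_eye", "right_ear", "left_ear", NA),
    onset_s = seq(0.5, by = 1.9, length.out = 6),
    approach_s = approach_s, hold_s = hold_s,
    hand = rep(c("right", "left"), 3), stringsAsFactors = FALSE))
}
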