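#' Streaming transition detector
#'
#' Compares a newly acquired frame label with the previous one and emits a
#' signal exactly on transitions: no-contact to contact (`contact_started`),
#' a change of contact area (`area_changed`), or contact to no-contact
#' (`contact_ended`). Identical consecutive labels emit nothing.
#'
#' @param previous Previous one-row frame label, or `NULL` at stream start.
#' @param current Current one-row frame label (same body).
#' @return `NULL`, or a list with `signal`, `area`, `timestamp_s`, `body_id`.
#' @export
monitor_step <- function(previous, current) {
  stopifnot(nrow(current) == 1L)
  prev_state <- if (is.null(previous)) "no_contact" else previous$state
  prev_area <- if (is.null(previous)) NA_character_ else previous$area
  if (!is.null(previous)) {
    if (previous$body_id != current$body_id) {
      stop("monitor_step: labels belong to different bodies")
    }
    if (current$timestamp_s <= previous$timestamp_s) {
      stop("monitor_step: timestamps must increase")
    }
  }
  sig <- NULL
  if (prev_state == "no_contact" && current$state == "contact") {
    sig <- list(signal = "contact_started", area = current$area)
  } else if (prev_state == "contact" && current$state == "contact" &&
             !identical(prev_area, current$area)) {
    sig <- list(signal = "area_changed", area = current$area)
  } else if (prev_state == "contact" && current$state == "no_contact") {
    sig <- list(signal = "contact_ended", area = NA_character_)
  }
  if (is.null(sig)) return(NULL)
  c(sig, list(timestamp_s = current$timestamp_s, body_id = current$body_id))
}

#' All transition signals of a label stream
#'
#' Runs [monitor_step()] along each body's time-ordered label sequence and
#' collects the emitted signals (this is the warning feed that a user
#' interface or the command-line `monitor` log consumes).
#'
#' @param labels A `frame_labels` data frame (see [label_stream()]).
#' @return Data frame with `timestamp_s`, `body_id`, `signal`, `area`.
#' @export
monitor_signals <- function(labels) {
  labels <- labels[order(labels$body_id, labels$timestamp_s), , drop = FALSE]
  out <- list()
  for (b in unique(labels$body_id)) {
    sub <- labels[labels$body_id == b, , drop = FALSE]
    prev <- NULL
    for (i in seq_len(nrow(sub))) {
      cur <- sub[i, , drop = FALSE]
      sig <- monitor_step(prev, cur)
      if (!is.null(sig)) out[[length(out) + 1L]] <- as.data.frame(sig)
      prev <- cur
    }
  }
  if (!length(out)) {
    return(data.frame(timestamp_s = numeric(), body_id = integer(),
                      signal = character(), area = character()))
  }
  res <- do.call(rbind, out)
  res[, c("timestamp_s", "body_id", "signal", "area")]
}

#' Group labeled frames into contact events
#'
#' Maximal runs of consecutive contact frames sharing one area label become
#' one event (run-length encoding of the (state, area) sequence): start and
#' end are the first and last frame timestamps of the run and `n_frames` its
#' length. By default nothing is smoothed: a single contact frame is an
#' event, and tracking jitter that splits a touch into several runs yields
#' several events. `merge_gap_s` optionally merges consecutive same-area
#' events separated by at most that gap, and `min_frames` drops events
#' shorter than the given run length; both default to off.
#'
#' @param labels A `frame_labels` data frame (one or more bodies).
#' @param min_frames Minimum run length to keep (default 1 = keep all).
#' @param merge_gap_s Merge same-area events separated by <= this many
#'   seconds (default 0 = off).
#' @return An [event_records] table with six-class labels.
#' @export
group_events <- function(labels, min_frames = 1L, merge_gap_s = 0) {
  out <- list()
  labels <- labels[order(labels$body_id, labels$timestamp_s), , drop = FALSE]
  for (b in unique(labels$body_id)) {
    sub <- labels[labels$body_id == b, , drop = FALSE]
    key <- ifelse(sub$state == "contact", paste0("contact:", sub$area), "no")
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- startsWith(r$values, "contact:")
    if (!any(keep)) next
    ev <- data.frame(
      body_id = b,
      start_s = sub$timestamp_s[starts[keep]],
      end_s = sub$timestamp_s[ends[keep]],
      label = sub("^contact:", "", r$values[keep]),
      n_frames = r$lengths[keep], stringsAsFactors = FALSE
    )
    if (merge_gap_s > 0 && nrow(ev) > 1L) {
      i <- 1L
      merged <- ev[1L, , drop = FALSE]
      for (k in 2L:nrow(ev)) {
        last <- nrow(merged)
        if (ev$label[k] == merged$label[last] &&
            ev$start_s[k] - merged$end_s[last] <= merge_gap_s) {
          merged$end_s[last] <- ev$end_s[k]
          merged$n_frames[last] <- merged$n_frames[last] + ev$n_frames[k]
        } else {
          merged <- rbind(merged, ev[k, , drop = FALSE])
        }
      }
      ev <- merged
    }
    ev <- ev[ev$n_frames >= min_frames, , drop = FALSE]
    if (nrow(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$start_s, ev$body_id), , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  event_records(ev)
}

#' Interpersonal-distance alerts
#'
#' For every timestamp at which more than one body is tracked, computes the
#' 3D Euclidean distance between the pelvis joints of every unordered body
#' pair and emits one alert per pair closer than the safety threshold
#' (default 1 m). Bodies without a tracked pelvis are skipped and tallied in
#' the `n_skipped` attribute.
#'
#' @param stream A [skeleton_stream] (possibly multi-body).
#' @param threshold_mm Safety distance in mm (default 1000).
#' @return Data frame `timestamp_s, body_a, body_b, distance_mm,
#'   threshold_mm` with attribute `n_skipped`.
#' @export
check_distance <- function(stream, threshold_mm = 1000) {
  pel <- stream[stream$joint == "pelvis", , drop = FALSE]
  idx <- frame_index(stream)
  skipped <- nrow(idx) - nrow(pel)
  out <- list()
  for (t in unique(pel$timestamp_s)) {
    sub <- pel[pel$timestamp_s == t, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$body_id), , drop = FALSE]
    pairs <- utils::combn(seq_len(nrow(sub)), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      d <- sqrt(sum((as.numeric(sub[i, c("x_mm", "y_mm", "z_mm")]) -
                     as.numeric(sub[j, c("x_mm", "y_mm", "z_mm")]))^2))
      if (d < threshold_mm) {
        out[[length(out) + 1L]] <- data.frame(
          timestamp_s = t, body_a = sub$body_id[i], body_b = sub$body_id[j],
          distance_mm = d, threshold_mm = threshold_mm)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(timestamp_s = numeric(), body_a = integer(), body_b = integer(),
               distance_mm = numeric(), threshold_mm = numeric())
  }
  res <- res[order(res$timestamp_s, res$body_a, res$body_b), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}
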