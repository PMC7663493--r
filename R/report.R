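#' End-of-observation behavioral report
#'
#' Summarizes a finished observation: per-area contact-event counts and
#' total contact durations, events per hour, degraded-frame and
#' distance-alert tallies, plus the per-event table. An event's reported
#' duration is its timestamp span plus one median frame interval, so a run
#' of k frames sampled at `fps` contributes k/fps seconds and reports of
#' disjoint streams add up.
#'
#' @param labels A `frame_labels` data frame for the observation.
#' @param events An [event_records] table (typically [group_events()] of the
#'   same labels).
#' @param alerts Optional [check_distance()] result.
#' @return List of class `attitude_report`: `span_s`, `areas` (data frame
#'   `area, count, total_duration_s` over the six contact classes),
#'   `events_total`, `events_per_hour`, `degraded_frames`,
#'   `distance_alerts`, `events`.
#' @export
build_report <- function(labels, events, alerts = NULL) {
  span <- if (nrow(labels)) max(labels$timestamp_s) - min(labels$timestamp_s) else 0
  ts <- sort(unique(labels$timestamp_s))
  dt <- if (length(ts) > 1L) stats::median(diff(ts)) else 0
  areas <- data.frame(area = contact_areas(), count = 0L,
                      total_duration_s = 0, stringsAsFactors = FALSE)
  if (nrow(events)) {
    dur <- (events$end_s - events$start_s) + dt
    for (i in seq_len(nrow(areas))) {
      sel <- events$label == areas$area[i]
      areas$count[i] <- sum(sel)
      areas$total_duration_s[i] <- sum(dur[sel])
    }
  }
  total <- sum(areas$count)
  structure(list(
    span_s = span,
    areas = areas,
    events_total = total,
    events_per_hour = if (span > 0) total / span * 3600 else 0,
    degraded_frames = sum(labels$degraded),
    distance_alerts = if (is.null(alerts)) 0L else nrow(alerts),
    events = events
  ), class = "attitude_report")
}

#' @export
print.attitude_report <- function(x, ...) {
  cat(sprintf("<attitude_report> span %.2f s | %d contact events (%.1f/h) | %d degraded frames | %d distance alerts\n",
              x$span_s, x$events_total, x$events_per_hour,
              x$degraded_frames, x$distance_alerts))
  print(x$areas)
  invisible(x)
}

#' Write a behavioral report to CSV
#'
#' Deterministic layout: a `metric,value` block, the per-area summary block
#' (`area,count,total_duration_s`), then the per-event table in the events
#' CSV dialect, separated by blank lines.
#'
#' @param report An `attitude_report` (see [build_report()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "attitude_report"))
  lines <- c(
    "metric,value",
    sprintf("observation_span_s,%.6f", report$span_s),
    sprintf("events_total,%d", report$events_total),
    sprintf("events_per_hour,%.6f", report$events_per_hour),
    sprintf("degraded_frames,%d", report$degraded_frames),
    sprintf("distance_alerts,%d", report$distance_alerts),
    "",
    "area,count,total_duration_s",
    sprintf("%s,%d,%.6f", report$areas$area, report$areas$count,
            report$areas$total_duration_s),
    "",
    "event_id,body_id,start_s,end_s,label,n_frames",
    format_event_lines(report$events)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
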