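#' Construct and validate an event table
#'
#' Events are maximal runs of identically labeled contact frames (or, in
#' ground-truth annotations, occlusion events). Columns: `event_id`,
#' `body_id`, `start_s`, `end_s`, `label`, `n_frames`. Labels come from the
#' closed vocabulary [event_labels()]. `n_frames = 0` is permitted only so
#' that truth annotations lacking frame counts can be represented.
#'
#' @param df Data frame with the columns above.
#' @return Validated data frame with class `event_records`, sorted by
#'   (start_s, body_id).
#' @export
event_records <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("event_id", "body_id", "start_s", "end_s", "label", "n_frames")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, needed]
  df$event_id <- as.integer(df$event_id)
  df$body_id <- as.integer(df$body_id)
  df$label <- as.character(df$label)
  df$n_frames <- as.integer(df$n_frames)
  bad <- setdiff(unique(df$label), event_labels())
  if (length(bad)) {
    stop("unknown event label(s): ", paste(bad, collapse = ", "),
         "; permitted labels are: ", paste(event_labels(), collapse = ", "))
  }
  if (nrow(df) && any(df$start_s > df$end_s)) stop("event start_s > end_s")
  if (nrow(df) && any(df$start_s < 0)) stop("event times must be >= 0")
  if (nrow(df) && any(df$n_frames < 0L)) stop("n_frames must be >= 0")
  df <- df[order(df$start_s, df$body_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_records", "data.frame")
  df
}

empty_events <- function() {
  event_records(data.frame(event_id = integer(), body_id = integer(),
                           start_s = numeric(), end_s = numeric(),
                           label = character(), n_frames = integer()))
}

#' Read / write event CSV files
#'
#' The dialect is `event_id,body_id,start_s,end_s,label,n_frames`, events
#' sorted by start time; times are printed with 6 decimals so output is
#' byte-stable.
#'
#' @param path CSV file path.
#' @return `read_events()`: an [event_records] table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_records(df)
}

#' @rdname read_events
#' @param events An [event_records] table (or coercible data frame).
#' @return `write_events()`: `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- event_records(events)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("event_id,body_id,start_s,end_s,label,n_frames",
               format_event_lines(events)), con, sep = "\n")
  invisible(path)
}

format_event_lines <- function(events) {
  if (!nrow(events)) return(character())
  sprintf("%d,%d,%.6f,%.6f,%s,%d", events$event_id, events$body_id,
          events$start_s, events$end_s, events$label, events$n_frames)
}
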