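#' Construct and validate a skeleton stream
#'
#' A skeleton stream is a long-format data frame with one row per tracked
#' joint per frame: columns `timestamp_s`, `body_id`, `joint`, `x_mm`,
#' `y_mm`, `z_mm`, `confidence`. Coordinates are millimeters in the depth
#' camera frame (x right, y down, z away from the sensor). Confidence is the
#' k4a ordinal 0--3 (3 = highest, the default when absent).
#'
#' Validation enforces: known joint names only, finite coordinates,
#' non-negative timestamps, no duplicated (timestamp, body, joint) triple.
#' Rows are sorted by (timestamp, body_id, canonical joint order).
#'
#' @param df Data frame with the columns above (`confidence` optional).
#' @return The validated, sorted data frame with class `skeleton_stream`.
#' @export
#' @examples
#' df <- data.frame(timestamp_s = 0, body_id = 0L, joint = "pelvis",
#'                  x_mm = 0, y_mm = 900, z_mm = 2000)
#' skeleton_stream(df)
skeleton_stream <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("timestamp_s", "body_id", "joint", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("skeleton stream is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, c(needed, intersect("confidence", names(df)))]
  if (!"confidence" %in% names(df)) df$confidence <- rep(3L, nrow(df))
  df$confidence[is.na(df$confidence)] <- 3L
  df$body_id <- as.integer(df$body_id)
  df$joint <- as.character(df$joint)
  df$confidence <- as.integer(df$confidence)

  bad <- setdiff(unique(df$joint), K4A_JOINTS)
  if (length(bad)) {
    stop("unknown joint name(s): ", paste(bad, collapse = ", "),
         " (not in the 32-joint k4a skeleton)")
  }
  num <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(df) && !all(is.finite(num))) stop("non-finite joint coordinates")
  if (nrow(df) && any(!is.finite(df$timestamp_s) | df$timestamp_s < 0)) {
    stop("timestamps must be finite and >= 0")
  }
  if (nrow(df) && any(df$confidence < 0L | df$confidence > 3L)) {
    stop("confidence must be an ordinal in 0..3")
  }
  key <- paste(df$timestamp_s, df$body_id, df$joint)
  if (anyDuplicated(key)) {
    stop("duplicated (timestamp, body_id, joint) rows: a joint may appear ",
         "at most once per frame")
  }
  ord <- order(df$timestamp_s, df$body_id, match(df$joint, K4A_JOINTS))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("skeleton_stream", "data.frame")
  df
}

#' @export
print.skeleton_stream <- function(x, ...) {
  nf <- nrow(unique(as.data.frame(x)[c("timestamp_s", "body_id")]))
  cat(sprintf("<skeleton_stream> %d joint rows, %d frames, %d body(ies)",
              nrow(x), nf, length(unique(x$body_id))))
  if (nrow(x)) {
    cat(sprintf(", t = [%.3f, %.3f] s", min(x$timestamp_s), max(x$timestamp_s)))
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Extract one frame from a stream
#'
#' @param stream A `skeleton_stream`.
#' @param timestamp_s,body_id Frame key.
#' @return Rows of the stream belonging to that frame (a valid single-frame
#'   skeleton stream).
#' @export
get_frame <- function(stream, timestamp_s, body_id = NULL) {
  keep <- stream$timestamp_s == timestamp_s
  if (!is.null(body_id)) keep <- keep & stream$body_id == body_id
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position of one named joint within a frame
#'
#' @param frame Rows of a skeleton stream for a single frame.
#' @param name Joint name.
#' @return Numeric length-3 vector (mm), or `NULL` when the joint is absent.
#' @export
joint_position <- function(frame, name) {
  i <- which(frame$joint == name)
  if (!length(i)) return(NULL)
  as.numeric(frame[i[1L], c("x_mm", "y_mm", "z_mm")])
}

# unique frames of a stream, ordered by (timestamp, body)
frame_index <- function(stream) {
  idx <- unique(as.data.frame(stream)[c("timestamp_s", "body_id")])
  idx <- idx[order(idx$timestamp_s, idx$body_id), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' Is a frame processable by the contact detector?
#'
#' A frame is processable when it contains both ear joints and at least one
#' thumb joint; it is distance-checkable when it contains the pelvis.
#'
#' @param frame Rows of a skeleton stream for one frame.
#' @return Logical scalar.
#' @export
is_processable <- function(frame) {
  j <- frame$joint
  all(c("ear_l", "ear_r") %in% j) && any(c("thumb_l", "thumb_r") %in% j)
}

#' @rdname is_processable
#' @export
is_distance_checkable <- function(frame) "pelvis" %in% frame$joint
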