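#' Read a skeleton stream from disk
#'
#' Two dialects are supported and auto-detected from the file extension:
#' \describe{
#'   \item{jsonl}{one JSON object per line:
#'     `{"t": <s>, "body": <int>, "joints": {"<JOINT>": [x_mm, y_mm, z_mm, conf], ...}}`}
#'   \item{csv}{long format with header
#'     `timestamp_s,body_id,joint,x_mm,y_mm,z_mm,confidence`}
#' }
#' Frames are returned sorted by (timestamp, body_id). Unknown joint names are
#' rejected, and timestamps must be strictly increasing per body.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return A [skeleton_stream].
#' @export
read_skeleton_stream <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(format,
    jsonl = read_skeleton_jsonl(path),
    csv = read_skeleton_csv(path)
  )
  check_monotone(df)  # on file order, before canonical sorting
  skeleton_stream(df)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) return("jsonl")
  if (ext %in% c("csv", "tsv")) return("csv")
  stop("cannot infer stream format from extension '.", ext,
       "'; pass format = \"jsonl\" or \"csv\"")
}

read_skeleton_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(timestamp_s = numeric(), body_id = integer(),
                      joint = character(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric(), confidence = integer()))
  }
  parts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$t) || is.null(rec$body) || is.null(rec$joints)) {
      stop("parse error at line ", i, " of ", path)
    }
    jn <- names(rec$joints)
    coords <- rec$joints
    m <- t(vapply(coords, function(v) {
      v <- as.numeric(v)
      if (length(v) == 3L) v <- c(v, 3)
      if (length(v) != 4L) stop("parse error at line ", i, " of ", path,
                                ": joint entries need 3 or 4 numbers")
      v
    }, numeric(4)))
    parts[[i]] <- data.frame(
      timestamp_s = as.numeric(rec$t), body_id = as.integer(rec$body),
      joint = jn, x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3],
      confidence = as.integer(m[, 4]), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, parts)
}

read_skeleton_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("timestamp_s", "body_id", "joint", "x_mm", "y_mm", "z_mm")
  if (!all(needed %in% names(df))) {
    stop("skeleton CSV must have header ", paste(needed, collapse = ","),
         "[,confidence]")
  }
  num <- c("timestamp_s", "x_mm", "y_mm", "z_mm")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad)) {
      stop("parse error at line ", bad[1L] + 1L, " of ", path,
           ": non-numeric '", cn, "'")
    }
    df[[cn]] <- v
  }
  df
}

# timestamps strictly increasing per body, in order of first appearance
check_monotone <- function(df) {
  if (!nrow(df)) return(invisible(df))
  for (b in unique(df$body_id)) {
    t <- unique(df$timestamp_s[df$body_id == b])
    if (is.unsorted(t, strictly = TRUE)) {
      stop("timestamps are not strictly increasing for body ", b)
    }
  }
  invisible(df)
}

#' Write a skeleton stream to disk
#'
#' Output is byte-stable for a fixed input: frames ordered by
#' (timestamp, body_id), joints in the canonical 32-joint order, coordinates
#' printed with 3 decimals (mm) and timestamps with 6 decimals (s).
#'
#' @param stream A [skeleton_stream] (or coercible data frame).
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_skeleton_stream <- function(stream, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  stream <- skeleton_stream(stream)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "csv") {
    header <- "timestamp_s,body_id,joint,x_mm,y_mm,z_mm,confidence"
    lines <- sprintf("%.6f,%d,%s,%.3f,%.3f,%.3f,%d",
                     stream$timestamp_s, stream$body_id, stream$joint,
                     stream$x_mm, stream$y_mm, stream$z_mm, stream$confidence)
    writeLines(c(header, lines), con, sep = "\n")
  } else {
    idx <- frame_index(stream)
    key <- paste(stream$timestamp_s, stream$body_id)
    lines <- character(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      rows <- stream[key == paste(idx$timestamp_s[i], idx$body_id[i]), , drop = FALSE]
      ent <- sprintf("\"%s\":[%.3f,%.3f,%.3f,%d]", rows$joint,
                     rows$x_mm, rows$y_mm, rows$z_mm, rows$confidence)
      lines[i] <- sprintf("{\"t\":%.6f,\"body\":%d,\"joints\":{%s}}",
                          idx$timestamp_s[i], idx$body_id[i],
                          paste(ent, collapse = ","))
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
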