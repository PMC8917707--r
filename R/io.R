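# Delimited-text formats: recordings as `timestamp,x,y,z` with ISO-8601
# timestamps (fractional seconds, UTC), tags as
# `label,start,end,subject_id,subject_class`. These emulate a GENEActiv-style
# CSV export plus the observer's notebook of motion intervals.

iso_format <- function(start_time, seconds) {
  format(start_time + seconds, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

parse_iso <- function(x, what, path) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("%s: malformed %s timestamp at line %d of %s",
                 what, what, bad[1] + 1L, path), call. = FALSE)
  out
}

#' Write / read a recording as delimited text
#'
#' @param rec A \code{net_recording}.
#' @param path File path.
#' @return \code{write_recording}: the path, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(timestamp = iso_format(attr(rec, "start_time"), rec$time),
                   x = sprintf("%.10g", rec$x),
                   y = sprintf("%.10g", rec$y),
                   z = sprintf("%.10g", rec$z))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param tolerance Allowed relative deviation of inter-sample spacing from
#'   the median interval (default 10\%); the sample rate is inferred from
#'   the median spacing.
#' @return \code{read_recording}: a \code{net_recording}.
#' @export
read_recording <- function(path, tolerance = 0.1) {
  if (!file.exists(path)) stop("read_recording: no such file: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df), c("timestamp", "x", "y", "z")))
    stop("read_recording: header must be 'timestamp,x,y,z' in ", path, call. = FALSE)
  if (nrow(df) < 2)
    stop("read_recording: need at least 2 samples in ", path, call. = FALSE)
  ts <- parse_iso(df$timestamp, "read_recording", path)
  vals <- lapply(c("x", "y", "z"), function(ax) suppressWarnings(as.numeric(df[[ax]])))
  names(vals) <- c("x", "y", "z")
  for (ax in c("x", "y", "z")) {
    bad <- which(is.na(vals[[ax]]))
    if (length(bad))
      stop(sprintf("read_recording: malformed %s value at line %d of %s",
                   ax, bad[1] + 1L, path), call. = FALSE)
  }
  secs <- as.numeric(difftime(ts, ts[1], units = "secs"))
  dt <- diff(secs)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop(sprintf("read_recording: timestamps not strictly increasing at line %d of %s",
                 i + 2L, path), call. = FALSE)
  }
  # timestamps are written at millisecond precision; snap the median interval
  # to the microsecond grid so the inferred rate is not polluted by POSIXct
  # floating-point wobble
  med <- round(median(dt), 6)
  off <- which(abs(dt - med) > tolerance * med)
  if (length(off))
    stop(sprintf(paste0("read_recording: sampling gap at line %d of %s ",
                        "(interval %.4f s vs median %.4f s)"),
                 off[1] + 2L, path, dt[off[1]], med), call. = FALSE)
  rate <- 1 / med
  samples <- cbind(x = vals$x, y = vals$y, z = vals$z)
  rec <- new_recording(samples, rate, start_time = ts[1])
  # snap times to the uniform grid implied by the inferred rate
  rec$time <- round(secs * rate) / rate
  rec
}

#' Write / read motion tags as delimited text
#'
#' @param tags A \code{net_tags} data frame (start/end in seconds from
#'   \code{start_time}).
#' @param path File path.
#' @param start_time Recording start used to render absolute timestamps.
#' @return \code{write_tags}: the path, invisibly.
#' @export
write_tags <- function(tags, path,
                       start_time = as.POSIXct("2022-01-10 20:00:00", tz = "UTC")) {
  df <- data.frame(label = tags$label,
                   start = iso_format(start_time, tags$start),
                   end = iso_format(start_time, tags$end),
                   subject_id = tags$subject_id,
                   subject_class = tags$subject_class)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tags
#' @param recording Optional \code{net_recording}; when given, tag times are
#'   returned in seconds from its start (and must fall inside it).
#' @return \code{read_tags}: a \code{net_tags} data frame.
#' @export
read_tags <- function(path, recording = NULL) {
  if (!file.exists(path)) stop("read_tags: no such file: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character")
  want <- c("label", "start", "end", "subject_id", "subject_class")
  if (!identical(names(df), want))
    stop("read_tags: header must be '", paste(want, collapse = ","), "' in ",
         path, call. = FALSE)
  bad <- setdiff(unique(df$label), motion_labels())
  if (length(bad))
    stop("read_tags: unknown label(s): ", paste(bad, collapse = ", "),
         " in ", path, call. = FALSE)
  start <- parse_iso(df$start, "read_tags", path)
  end <- parse_iso(df$end, "read_tags", path)
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    stop(sprintf("read_tags: end <= start at line %d of %s", i + 1L, path),
         call. = FALSE)
  }
  origin <- if (!is.null(recording)) attr(recording, "start_time") else start[1]
  tags <- data.frame(label = df$label,
                     start = as.numeric(difftime(start, origin, units = "secs")),
                     end = as.numeric(difftime(end, origin, units = "secs")),
                     subject_id = df$subject_id,
                     subject_class = df$subject_class,
                     stringsAsFactors = FALSE)
  class(tags) <- c("net_tags", "data.frame")
  check_tag_overlap(tags)
  tags
}
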