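# Delimited-text input/output in the package's exchange formats.
# All files are tab-separated UTF-8 with '.' decimal and a mandatory header.

#' Write / read a trace file
#'
#' Trace files have one row per frame with columns \code{frame_index}
#' (0-based), \code{time_s}, \code{x_mm}, \code{y_mm}, \code{heading_deg},
#' \code{tail_angle_deg} and \code{flagged}.
#'
#' @param trace a [TailTrace-class].
#' @param path file path.
#' @export
writeTraceFile <- function(trace, path) {
  fr <- traceFrames(trace)
  out <- data.frame(frame_index = fr$frame, time_s = fr$time_s,
                    x_mm = fr$x_mm, y_mm = fr$y_mm,
                    heading_deg = fr$heading_deg,
                    tail_angle_deg = fr$tail_angle_deg,
                    flagged = as.integer(fr$flagged))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTraceFile
#' @param rate sampling rate (Hz) of the stored trace.
#' @param stim_time optional stimulus time (s).
#' @return \code{readTraceFile}: a [TailTrace-class].
#' @export
readTraceFile <- function(path, rate = NULL, stim_time = NA_real_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         fileEncoding = "UTF-8")
  if (is.null(rate)) rate <- 1 / stats::median(diff(d$time_s))
  frames <- data.frame(frame = d$frame_index, time_s = d$time_s,
                       x_mm = d$x_mm, y_mm = d$y_mm,
                       heading_deg = d$heading_deg,
                       tail_angle_deg = d$tail_angle_deg,
                       flagged = as.logical(d$flagged %||% FALSE))
  newTailTrace(frames, rate, stimTime = stim_time)
}

#' Write a table in the exchange format
#'
#' Used for ground-truth, bout, fish-summary and comparison tables.
#' List columns (per-bout bend sequences) are serialized as
#' semicolon-separated values.
#'
#' @param x data.frame.
#' @param path file path.
#' @export
writeTable <- function(x, path) {
  for (cn in names(x)) {
    if (is.list(x[[cn]]))
      x[[cn]] <- vapply(x[[cn]], function(v)
        paste(signif(v, 8), collapse = ";"), character(1))
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTable
#' @return \code{readTable}: the data.frame.
#' @export
readTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' Write image stacks
#'
#' Saves rendered frames as numbered 8-bit grayscale PNG files.
#'
#' @param stack result of [renderFrames()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the written file paths, invisibly.
#' @export
writeFrames <- function(stack, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$images))
  for (i in seq_along(stack$images)) {
    paths[i] <- file.path(dir, sprintf("%s_%05d.png", prefix, i - 1))
    png::writePNG(stack$images[[i]], paths[i])
  }
  invisible(paths)
}
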