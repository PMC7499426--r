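#' @import methods
NULL

#' TailTrace: a per-frame recording of one fish
#'
#' Holds the per-frame time series produced either by the synthetic generator
#' or by the silhouette tracker: head position (mm), heading (degrees) and the
#' signed tail angle (degrees), together with the sampling rate, the optional
#' stimulus time for escape trials, the ground-truth bout table when the trace
#' is synthetic, and session metadata (fish, clutch, genotype identifiers).
#'
#' The \code{frames} slot is a data.frame with columns \code{frame} (0-based),
#' \code{time_s}, \code{x_mm}, \code{y_mm}, \code{heading_deg},
#' \code{tail_angle_deg} and \code{flagged} (tracking-failure indicator).
#'
#' Sign convention: tail bends towards the fish's left are positive, and a
#' straight tail pointing directly behind the head has angle 0.
#'
#' @slot frames data.frame of per-frame samples (see Details).
#' @slot rate sampling rate in Hz.
#' @slot stimTime stimulus time in seconds (NA for spontaneous sessions).
#' @slot groundTruth data.frame of true injected bouts (empty for real data).
#' @slot meta named list of session metadata.
#' @export
setClass("TailTrace",
  representation(
    frames = "data.frame",
    rate = "numeric",
    stimTime = "numeric",
    groundTruth = "data.frame",
    meta = "list"
  ),
  prototype(
    frames = data.frame(),
    rate = NA_real_,
    stimTime = NA_real_,
    groundTruth = data.frame(),
    meta = list()
  )
)

setValidity("TailTrace", function(object) {
  msg <- character()
  need <- c("frame", "time_s", "x_mm", "y_mm", "heading_deg", "tail_angle_deg")
  if (!all(need %in% names(object@frames)))
    msg <- c(msg, paste("frames must contain columns:", paste(need, collapse = ", ")))
  if (length(object@rate) != 1 || (!is.na(object@rate) && object@rate <= 0))
    msg <- c(msg, "rate must be a single positive number")
  if (nrow(object@frames) > 1) {
    dt <- diff(object@frames$time_s)
    if (any(dt <= 0)) msg <- c(msg, "time_s must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TailTrace compact display
#' @param object a TailTrace
#' @export
setMethod("show", "TailTrace", function(object) {
  cat("TailTrace:", nrow(object@frames), "frames at", object@rate, "Hz")
  if (!is.na(object@stimTime)) cat(" (stimulus at", object@stimTime, "s)")
  cat("\n")
  if (nrow(object@groundTruth))
    cat("  ground truth:", nrow(object@groundTruth), "injected bouts\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

#' Accessors for TailTrace
#'
#' @param x a \code{TailTrace}
#' @return \code{traceFrames}: the per-frame data.frame; \code{traceRate}: the
#'   sampling rate (Hz); \code{groundTruth}: the ground-truth bout table;
#'   \code{stimTime}: the stimulus time (s) or NA; \code{traceDuration}: the
#'   recording duration in seconds.
#' @export
traceFrames <- function(x) x@frames

#' @rdname traceFrames
#' @export
traceRate <- function(x) x@rate

#' @rdname traceFrames
#' @export
groundTruth <- function(x) x@groundTruth

#' @rdname traceFrames
#' @export
stimTime <- function(x) x@stimTime

#' @rdname traceFrames
#' @export
traceDuration <- function(x) nrow(x@frames) / x@rate

#' Midline: tracked body geometry for one frame
#'
#' The tracker output for a single frame: head position, heading (the
#' direction the head points, degrees, mathematical convention with y up) and
#' ten points along the tail ordered from just behind the head to the tail
#' tip, in mm.
#'
#' @slot headXY numeric length-2, head position (mm).
#' @slot headingDeg heading in degrees.
#' @slot tailPoints 10 x 2 matrix of tail coordinates head-to-tip (mm).
#' @slot quality "ok" or "suspect".
#' @export
setClass("Midline",
  representation(
    headXY = "numeric",
    headingDeg = "numeric",
    tailPoints = "matrix",
    quality = "character"
  ),
  prototype(quality = "ok")
)

setValidity("Midline", function(object) {
  msg <- character()
  if (length(object@headXY) != 2 || any(!is.finite(object@headXY)))
    msg <- c(msg, "headXY must be two finite coordinates")
  if (!is.finite(object@headingDeg))
    msg <- c(msg, "headingDeg must be finite")
  if (!all(dim(object@tailPoints) == c(10, 2)))
    msg <- c(msg, "tailPoints must be a 10 x 2 matrix")
  else {
    seg <- sqrt(rowSums(diff(rbind(object@headXY, object@tailPoints))^2))
    if (any(seg <= 0)) msg <- c(msg, "consecutive midline points must be distinct")
  }
  if (!object@quality %in% c("ok", "suspect"))
    msg <- c(msg, "quality must be 'ok' or 'suspect'")
  if (length(msg)) msg else TRUE
})

#' @describeIn Midline compact display
#' @param object a Midline
#' @export
setMethod("show", "Midline", function(object) {
  cat(sprintf("Midline: head (%.2f, %.2f) mm, heading %.1f deg, quality %s\n",
              object@headXY[1], object@headXY[2], object@headingDeg, object@quality))
  invisible(NULL)
})

# internal constructor used by the generator and the tracker
newTailTrace <- function(frames, rate, stimTime = NA_real_,
                         groundTruth = data.frame(), meta = list()) {
  if (is.null(frames$flagged)) frames$flagged <- FALSE
  new("TailTrace", frames = frames, rate = rate, stimTime = stimTime,
      groundTruth = groundTruth, meta = meta)
}
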