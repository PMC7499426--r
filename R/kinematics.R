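# Bout segmentation and per-bout kinematics from tail-angle traces.

#' Detection settings for bout segmentation
#'
#' Default settings of the envelope-with-hysteresis bout detector, scaled to
#' the recording regime: slow spontaneous swimming (100 Hz class) or
#' high-speed escape trials (650 Hz class). The envelope is a sliding RMS of
#' the tail angle; a bout opens when the envelope exceeds \code{theta_on}
#' for at least \code{min_on} seconds and closes when it falls below
#' \code{theta_off} for at least \code{min_off} seconds; intervals separated
#' by less than \code{merge_gap} are merged; interval edges are then refined
#' to the first/last frame whose smoothed absolute angle exceeds
#' \code{refine_thresh}.
#'
#' @param rate sampling rate in Hz.
#' @param regime "slow" or "escape".
#' @return named list of detection settings (all config-exposed).
#' @export
detectionParams <- function(rate, regime = c("slow", "escape")) {
  regime <- match.arg(regime)
  if (regime == "slow") {
    list(rate = rate, env_window = 0.05, theta_on = 1.0, theta_off = 0.5,
         min_on = 0.02, min_off = 0.05, merge_gap = 0.03,
         refine_thresh = 0.45, peak_floor = 0.5, sg_window = 5,
         max_flagged = 0.2)
  } else {
    list(rate = rate, env_window = 0.012, theta_on = 5, theta_off = 2.5,
         min_on = 0.004, min_off = 0.010, merge_gap = 0.010,
         refine_thresh = 1.0, peak_floor = 2.0, sg_window = 7,
         max_flagged = 0.2)
  }
}

# Savitzky-Golay smoothing of the tail angle used for peak finding and edge
# refinement (quadratic, short window: preserves peak shape, kills noise)
smoothAngle <- function(theta, sg_window) {
  if (length(theta) <= sg_window) return(theta)
  as.numeric(signal::sgolayfilt(theta, p = 2, n = sg_window))
}

#' Detect swim bouts in a tail-angle trace
#'
#' Envelope-based segmentation (see [detectionParams()]). Returns 0-based,
#' half-open frame intervals \code{[onset, offset)}, time-ordered and
#' non-overlapping. Sessions with more than \code{max_flagged} tracking-
#' flagged frames are rejected.
#'
#' @param trace a [TailTrace-class].
#' @param params detection settings; default chosen from the trace's rate
#'   (escape settings when the rate exceeds 300 Hz).
#' @return data.frame with columns \code{onset}, \code{offset} (frames).
#' @export
detectBouts <- function(trace, params = NULL) {
  fr <- traceFrames(trace)
  rate <- traceRate(trace)
  if (is.null(params))
    params <- detectionParams(rate, if (rate > 300) "escape" else "slow")
  flagged <- fr$flagged %||% rep(FALSE, nrow(fr))
  if (mean(flagged) > params$max_flagged)
    stop(sprintf("session rejected: %.1f%% of frames are tracking-flagged",
                 100 * mean(flagged)), call. = FALSE)
  theta <- fr$tail_angle_deg
  theta[flagged] <- 0  # flagged frames carry no motion evidence
  theta <- theta - stats::median(theta)
  w <- max(3L, as.integer(round(params$env_window * rate)))
  if (w %% 2 == 0) w <- w + 1L
  env <- sqrt(pmax(runMean(theta^2, w), 0))

  n <- length(env)
  above_off <- env >= params$theta_off
  r <- rle(above_off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_on_f <- max(1L, as.integer(round(params$min_on * rate)))
  min_off_f <- max(1L, as.integer(round(params$min_off * rate)))
  iv <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    seg <- env[s:e]
    # must contain a sustained crossing of theta_on
    hot <- rle(seg >= params$theta_on)
    if (!any(hot$values & hot$lengths >= min_on_f)) next
    iv[[length(iv) + 1]] <- c(s, e)
  }
  if (!length(iv)) return(data.frame(onset = integer(), offset = integer()))
  iv <- do.call(rbind, iv)
  # closing requires min_off below theta_off: merge intervals whose gap is
  # shorter than max(merge_gap, min_off)
  gap_f <- max(as.integer(round(params$merge_gap * rate)), min_off_f)
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] - last[2] <= gap_f) merged[[length(merged)]][2] <- iv[i, 2]
      else merged[[length(merged) + 1]] <- iv[i, ]
    }
  }
  iv <- do.call(rbind, merged)
  # edge refinement on the raw angle (threshold ~3 sigma of sensor noise;
  # smoothing would smear the edges by half a window)
  thsm <- abs(theta)
  res <- matrix(NA_integer_, nrow(iv), 2)
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1]; e <- iv[i, 2]
    inb <- which(thsm[s:e] >= params$refine_thresh)
    if (!length(inb)) next  # micro-movement: envelope crossed, no real bend
    res[i, ] <- c(s + inb[1] - 1L, min(s + inb[length(inb)] - 1L + 1L, n))
  }
  res <- res[!is.na(res[, 1]), , drop = FALSE]
  data.frame(onset = as.integer(res[, 1] - 1L),   # to 0-based
             offset = as.integer(res[, 2]))
}

#' Detect signed bend peaks within a bout
#'
#' Local extrema of the tail angle inside the interval: peaks are located on
#' a Savitzky-Golay-smoothed copy, required to exceed the prominence floor,
#' forced to alternate in sign (of two same-sign neighbours the larger is
#' kept), and their amplitudes are refined on the raw trace by a three-point
#' parabolic fit around the peak frame (removes the sampling-offset bias).
#'
#' @param trace a [TailTrace-class].
#' @param interval numeric length-2: 0-based half-open \code{c(onset, offset)}.
#' @param params detection settings, see [detectionParams()].
#' @return numeric vector of signed peak amplitudes in bout order (empty if
#'   no peak clears the floor).
#' @export
detectBends <- function(trace, interval, params = NULL) {
  fr <- traceFrames(trace)
  rate <- traceRate(trace)
  if (is.null(params))
    params <- detectionParams(rate, if (rate > 300) "escape" else "slow")
  idx <- (interval[1] + 1L):interval[2]  # 1-based rows of the half-open interval
  theta <- fr$tail_angle_deg[idx]
  ths <- smoothAngle(theta, params$sg_window)
  n <- length(ths)
  if (n < 3) return(numeric())
  d <- diff(ths)
  # local extrema: sign change of the first difference (ties to the earlier frame)
  s <- sign(d); s[s == 0] <- 1
  ext <- which(diff(s) != 0) + 1L
  ext <- ext[abs(ths[ext]) >= params$peak_floor]
  if (!length(ext)) return(numeric())
  # enforce alternating signs: keep the largest of each same-sign run
  sg <- sign(ths[ext])
  keep <- integer()
  i <- 1
  while (i <= length(ext)) {
    j <- i
    while (j < length(ext) && sg[j + 1] == sg[i]) j <- j + 1
    run <- ext[i:j]
    keep <- c(keep, run[which.max(abs(ths[run]))])
    i <- j + 1
  }
  # parabolic amplitude refinement on the raw angle
  amp <- vapply(keep, function(p) {
    if (p <= 1 || p >= n) return(theta[p])
    y1 <- theta[p - 1]; y2 <- theta[p]; y3 <- theta[p + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < 1e-12) return(y2)
    dx <- 0.5 * (y1 - y3) / den
    if (abs(dx) > 1) dx <- sign(dx)
    y2 - 0.25 * (y1 - y3) * dx
  }, numeric(1))
  # re-apply the floor on the refined raw amplitudes: a flat-to-rise corner
  # of the smoothed trace can pass the first screen with a near-zero raw peak
  amp[abs(amp) >= params$peak_floor]
}

#' Per-bout kinematic parameters
#'
#' Computes the bout's kinematics from its interval and bend peaks: distance
#' is the path length of the (lightly smoothed) head trajectory across the
#' half-open frame interval, duration is \code{(offset - onset)/rate}, speed
#' is distance over duration, the number of oscillations is
#' \code{ceiling(n_peaks / peaks_per_osc)} (one oscillation = one left+right
#' half-beat pair), TBF is oscillations over duration, and the maximal and
#' median bend amplitudes are taken over \code{|bends|}.
#'
#' @param trace a [TailTrace-class].
#' @param interval 0-based half-open \code{c(onset, offset)} frame interval.
#' @param bends signed peak amplitudes from [detectBends()].
#' @param peaks_per_osc half-beats per oscillation (default 2).
#' @param smooth_window position-smoothing window in frames (running mean)
#'   applied before the path-length sum; suppresses sensor-noise inflation.
#' @return one-row data.frame of bout parameters.
#' @export
boutKinematics <- function(trace, interval, bends, peaks_per_osc = 2,
                           smooth_window = 5) {
  fr <- traceFrames(trace)
  rate <- traceRate(trace)
  onset <- interval[1]; offset <- interval[2]
  stopifnot(offset > onset)
  xs <- runMean(fr$x_mm, smooth_window)
  ys <- runMean(fr$y_mm, smooth_window)
  # pad by the smoothing half-width so edge displacement spread by the
  # running mean is not lost from the path sum
  pad <- smooth_window %/% 2
  lo <- max(1L, onset + 1L - pad)
  hi <- min(offset + 1L + pad, nrow(fr))  # steps across the padded interval
  dist <- sum(sqrt(diff(xs[lo:hi])^2 + diff(ys[lo:hi])^2))
  dur <- (offset - onset) / rate
  n_osc <- as.integer(ceiling(length(bends) / peaks_per_osc))
  data.frame(
    onset = onset, offset = offset,
    onset_s = onset / rate, duration_s = dur,
    distance_mm = dist, speed_mm_s = dist / dur,
    n_peaks = length(bends), n_osc = n_osc, tbf_hz = n_osc / dur,
    max_bend_deg = if (length(bends)) max(abs(bends)) else NA_real_,
    median_bend_deg = if (length(bends)) stats::median(abs(bends)) else NA_real_,
    first_bend_deg = if (length(bends)) bends[1] else NA_real_
  )
}

#' Bout rate of a session
#'
#' @param bouts a bout table (or detection table); its row count is used.
#' @param duration recording duration in seconds.
#' @return bouts per second (Hz).
#' @examples
#' boutRate(data.frame(onset = 1:273), 300)  # 0.91
#' @export
boutRate <- function(bouts, duration) {
  stopifnot(duration > 0)
  nrow(bouts) / duration
}

#' Segment a whole session into a bout table
#'
#' Convenience wrapper chaining [detectBouts()], [detectBends()] and
#' [boutKinematics()] over a trace. Intervals without a qualifying bend peak
#' (micro-movements) are dropped.
#'
#' @inheritParams detectBouts
#' @return data.frame with one row per retained bout (columns of
#'   [boutKinematics()] plus \code{bout_index} and the trace's fish metadata).
#' @export
sessionBouts <- function(trace, params = NULL) {
  rate <- traceRate(trace)
  if (is.null(params))
    params <- detectionParams(rate, if (rate > 300) "escape" else "slow")
  iv <- detectBouts(trace, params)
  rows <- list()
  nfr <- nrow(traceFrames(trace))
  for (i in seq_len(nrow(iv))) {
    interval <- c(iv$onset[i], iv$offset[i])
    # pad the peak search so extrema sitting on the refined edges keep both
    # flanks; spurious out-of-bout peaks are blocked by the prominence floor
    bend_iv <- c(max(0L, iv$onset[i] - 2L), min(nfr, iv$offset[i] + 2L))
    bends <- detectBends(trace, bend_iv, params)
    if (!length(bends)) next  # micro-movement
    rows[[length(rows) + 1]] <-
      cbind(boutKinematics(trace, interval, bends),
            data.frame(bends = I(list(bends))))
  }
  if (!length(rows))
    return(data.frame())
  out <- do.call(rbind, rows)
  out$bout_index <- seq_len(nrow(out))
  meta <- trace@meta
  out$fish_id <- meta$fish_id %||% NA
  out$clutch <- meta$clutch %||% NA
  out$genotype <- meta$genotype %||% NA
  out
}
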