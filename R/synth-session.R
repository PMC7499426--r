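# Trace-level synthesis: bout waveforms, slow-swim sessions, escape trials.
#
# A bout with peaks p_1..p_np and duration d is a chain of half-beats: the
# i-th half-beat occupies [(i-1) d/np, i d/np) and the tail angle follows a
# half-sine reaching the signed peak p_i at its centre. The head advances
# along the (possibly rotating) heading by a per-frame step proportional to
# the local half-beat amplitude, so the bout's path length equals the drawn
# bout distance and propulsion tracks beat strength.

# signed bend peaks for a slow-swim bout; median(|peaks|) == bend_med exactly
slowBendPeaks <- function(category, bend_med, n_osc, first_bend, cal) {
  np <- 2L * n_osc - 1L
  mid <- (np + 1L) / 2L
  if (category == "forward") {
    blk <- cal$forward
    mag <- bend_med * pmax(blk$peak_decay^(seq_len(np) - mid), blk$peak_floor)
  } else {
    blk <- cal$turn
    mag <- bend_med * pmax(blk$peak_decay^(seq_len(np) - mid), blk$peak_floor)
    mag[1] <- first_bend
  }
  sgn <- sample(c(-1, 1), 1)
  mag * sgn * (-1)^(seq_len(np) - 1)
}

# sample the bout waveform on the frame grid and move the head;
# returns per-frame angle, positions, heading for frames f0..f1-1
sampleBout <- function(peaks, onset, duration, distance, heading0, dheading,
                       x0, y0, rate) {
  np <- length(peaks)
  f0 <- ceiling(onset * rate)
  f1 <- ceiling((onset + duration) * rate) - 1L
  if (f1 < f0) f1 <- f0
  fr <- f0:f1
  trel <- fr / rate - onset
  seg <- pmin(floor(trel * np / duration) + 1, np)
  frac <- trel * np / duration - (seg - 1)
  theta <- peaks[seg] * sin(pi * frac)
  w <- abs(peaks[seg])
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  heading <- heading0 + dheading * trel / duration
  step <- distance * w
  dx <- cumsum(step * cos(heading * pi / 180))
  dy <- cumsum(step * sin(heading * pi / 180))
  list(frames = fr, theta = theta, x = x0 + dx, y = y0 + dy,
       heading = heading, heading_end = heading0 + dheading)
}

# expected bout duration implied by median-parametrized (distance, speed)
expectedDuration <- function(dist_med, speed_med, sx, ss, rho) {
  sd2 <- sx^2 + ss^2 - 2 * rho * sx * ss
  dist_med / speed_med * exp(sd2 / 2)
}

#' Simulate a spontaneous slow-swim session
#'
#' Generates a beat-and-glide tail-angle and head-trajectory trace for one
#' fish: bout onsets follow a renewal process (gamma-distributed glide times
#' plus the bout durations), each bout is a forward swim with probability
#' \code{p_forward} or a routine turn otherwise, and every injected bout is
#' recorded in the ground-truth table. Per-bout distance and speed are drawn
#' as correlated lognormals with medians at the fish's latent values and the
#' duration is their ratio; bend-amplitude sequences are scaled so that the
#' median absolute bend equals the drawn per-bout value. Turns rotate the
#' heading by \code{heading_gain} times the signed first bend.
#'
#' @param fish a one-row data.frame (or list) of fish latents as produced by
#'   [generateCohort()].
#' @param duration recording length in seconds.
#' @param rate sampling rate in Hz.
#' @param calibration calibration list (waveform constants, noise, gaps).
#' @param boundary_stress if TRUE, bouts are drawn with maximal bend
#'   amplitudes near the 25-degree forward/turn cutoff (uniform in 23-27
#'   degrees) to stress the classifier; ground-truth categories then follow
#'   the actual maximal bend.
#' @param noise if FALSE, sensor noise is omitted (clean traces).
#' @return a [TailTrace-class] whose \code{groundTruth} table has one row per
#'   injected bout (onset/offset, category, distance, duration, speed,
#'   n_osc, tbf, max/median bend, first bend, heading change).
#' @export
simulateSlowSession <- function(fish, duration = 300, rate = 100,
                                calibration = defaultCalibration(),
                                boundary_stress = FALSE, noise = TRUE) {
  stopifnot(duration > 0, rate > 0)
  cal <- calibration
  fish <- as.list(fish)
  n_frames <- floor(duration * rate)
  theta <- numeric(n_frames)
  x <- numeric(n_frames); y <- numeric(n_frames)
  hd <- numeric(n_frames)

  mean_dur <- fish$p_forward *
    expectedDuration(fish$fwd_distance, fish$fwd_speed,
                     cal$forward$bout_sdlog[["distance"]],
                     cal$forward$bout_sdlog[["speed"]], cal$forward$bout_rho_ds) +
    (1 - fish$p_forward) *
    expectedDuration(fish$trn_distance, fish$trn_speed,
                     cal$turn$bout_sdlog[["distance"]],
                     cal$turn$bout_sdlog[["speed"]], cal$turn$bout_rho_ds)
  mean_gap <- 1 / fish$bout_rate - mean_dur
  if (mean_gap <= cal$session$min_gap)
    stop("requested bout rate too high: bouts cannot fit without overlap",
         call. = FALSE)

  gt <- list()
  t_now <- 0
  heading <- stats::runif(1, 0, 360)
  pos <- c(0, 0)
  bout_i <- 0L
  last_fill <- 0L
  repeat {
    gap <- cal$session$min_gap +
      stats::rgamma(1, shape = cal$session$gap_shape,
                    scale = (mean_gap - cal$session$min_gap) / cal$session$gap_shape)
    onset <- t_now + gap
    category <- if (stats::runif(1) < fish$p_forward) "forward" else "turn"
    blk <- if (category == "forward") cal$forward else cal$turn
    pref <- if (category == "forward") "fwd" else "trn"
    ds <- exp(rbvnorm(1, blk$bout_sdlog[["distance"]], blk$bout_sdlog[["speed"]],
                      blk$bout_rho_ds) +
              log(c(fish[[paste0(pref, "_distance")]],
                    fish[[paste0(pref, "_speed")]])))
    dist <- ds[1]; speed <- ds[2]
    d <- dist / speed
    k <- max(1L, as.integer(round(rlnormMedian(1, fish[[paste0(pref, "_nosc")]],
                                               blk$bout_sdlog[["n_osc"]]))))
    bend_med <- max(cal$min_bend,
                    rlnormMedian(1, fish[[paste0(pref, "_bend")]],
                                 blk$bout_sdlog[["bend"]]))
    first_bend <- NA_real_
    if (category == "turn") {
      repeat {
        first_bend <- stats::rnorm(1, cal$turn$first_bend_mean, cal$turn$first_bend_sd)
        if (first_bend >= cal$turn$first_bend_range[1] &&
            first_bend <= cal$turn$first_bend_range[2]) break
      }
    }
    peaks <- slowBendPeaks(category, bend_med, k, first_bend, cal)
    if (boundary_stress) {
      peaks <- peaks / max(abs(peaks)) * stats::runif(1, 23, 27)
      category <- if (max(abs(peaks)) < 25) "forward" else "turn"
    }
    if (onset + d > duration - 0.05) break
    dheading <- if (category == "turn")
      cal$heading_gain * peaks[1] else 0
    sb <- sampleBout(peaks, onset, d, dist, heading, dheading,
                     pos[1], pos[2], rate)
    idx <- sb$frames + 1L
    theta[idx] <- sb$theta
    # hold position/heading constant through the preceding glide
    if (min(idx) > last_fill + 1L) {
      hold <- (last_fill + 1L):(min(idx) - 1L)
      x[hold] <- pos[1]; y[hold] <- pos[2]; hd[hold] <- heading
    }
    x[idx] <- sb$x; y[idx] <- sb$y; hd[idx] <- sb$heading
    last_fill <- max(idx)
    pos <- c(sb$x[length(sb$x)], sb$y[length(sb$y)])
    heading <- sb$heading_end
    bout_i <- bout_i + 1L
    gt[[bout_i]] <- data.frame(
      bout_index = bout_i, onset_s = onset, offset_s = onset + d,
      category = category, duration_s = d, distance_mm = dist,
      speed_mm_s = speed, n_osc = k, tbf_hz = k / d,
      max_bend_deg = max(abs(peaks)), median_bend_deg = stats::median(abs(peaks)),
      first_bend_deg = peaks[1],
      heading_change_deg = dheading, stringsAsFactors = FALSE
    )
    t_now <- onset + d
  }
  if (last_fill < n_frames) {
    hold <- (last_fill + 1L):n_frames
    x[hold] <- pos[1]; y[hold] <- pos[2]; hd[hold] <- heading
  }
  if (noise) {
    theta <- theta + stats::rnorm(n_frames, 0, cal$noise$angle_sd)
    x <- x + stats::rnorm(n_frames, 0, cal$noise$pos_sd)
    y <- y + stats::rnorm(n_frames, 0, cal$noise$pos_sd)
  }
  frames <- data.frame(
    frame = 0:(n_frames - 1L), time_s = (0:(n_frames - 1L)) / rate,
    x_mm = x, y_mm = y, heading_deg = hd, tail_angle_deg = theta,
    flagged = FALSE
  )
  gt <- if (bout_i) do.call(rbind, gt) else data.frame()
  newTailTrace(frames, rate, groundTruth = gt,
               meta = list(fish_id = fish$fish_id %||% NA,
                           clutch = fish$clutch %||% NA,
                           genotype = fish$genotype %||% NA,
                           kind = "slow"))
}

#' Simulate one acousto-vestibular escape trial
#'
#' Generates a single-trial trace: quiescence until the stimulus plus the
#' drawn response latency, then an escape bout starting with the large
#' C-bend, followed by the opposite-sign counter bend and geometrically
#' decaying oscillations at the drawn tail beat frequency. The bout duration
#' is n_osc / TBF so that the per-bout tail beat frequency recovered as
#' oscillations over duration matches the drawn value.
#'
#' @inheritParams simulateSlowSession
#' @param trial_len trial length in seconds.
#' @param stim_time stimulus onset in seconds after trial start.
#' @param rate sampling rate in Hz.
#' @return a [TailTrace-class] with a one-row ground-truth table (latency,
#'   C-bend, counter bend and the bout-level parameters).
#' @export
simulateEscapeTrial <- function(fish, trial_len = 1, stim_time = 0.2, rate = 650,
                                calibration = defaultCalibration(), noise = TRUE) {
  cal <- calibration
  fish <- as.list(fish)
  esc <- cal$escape
  sdlog <- function(cv) sqrt(log(1 + cv^2))
  lat_ms <- rlnormMean(1, fish$esc_latency, sdlog(esc$trial_cv[["latency"]]))
  tbf <- rlnormMean(1, fish$esc_tbf, sdlog(esc$trial_cv[["tbf"]]))
  k <- max(3L, as.integer(round(rlnormMean(1, fish$esc_nosc,
                                           sdlog(esc$trial_cv[["n_osc"]])))))
  d <- k / tbf
  dist <- rlnormMean(1, fish$esc_distance, sdlog(esc$trial_cv[["distance"]]))
  cbend <- stats::rnorm(1, fish$esc_cbend, esc$trial_sd[["cbend"]])
  counter <- max(5, stats::rnorm(1, fish$esc_counter, esc$trial_sd[["counter"]]))
  counter <- min(counter, 0.8 * abs(cbend))  # the C-bend is always the largest
  onset <- stim_time + lat_ms / 1000
  if (onset + d >= trial_len - 0.02)
    stop("stimulus time + latency + bout duration exceed the trial length",
         call. = FALSE)
  np <- 2L * k - 1L
  mag <- c(cbend, counter * esc$peak_decay^(0:(np - 2L)))
  mag <- pmax(mag, esc$peak_floor * cbend)
  mag[1] <- cbend
  sgn <- sample(c(-1, 1), 1)
  peaks <- mag * sgn * (-1)^(seq_len(np) - 1)

  n_frames <- floor(trial_len * rate)
  theta <- numeric(n_frames); x <- numeric(n_frames); y <- numeric(n_frames)
  heading0 <- stats::runif(1, 0, 360)
  dheading <- cal$heading_gain * peaks[1]
  sb <- sampleBout(peaks, onset, d, dist, heading0, dheading, 0, 0, rate)
  idx <- sb$frames + 1L
  idx_ok <- idx[idx <= n_frames]
  theta[idx_ok] <- sb$theta[seq_along(idx_ok)]
  hd <- rep(heading0, n_frames)
  x[idx_ok] <- sb$x[seq_along(idx_ok)]
  y[idx_ok] <- sb$y[seq_along(idx_ok)]
  hd[idx_ok] <- sb$heading[seq_along(idx_ok)]
  if (max(idx_ok) < n_frames) {
    aft <- (max(idx_ok) + 1L):n_frames
    x[aft] <- sb$x[length(sb$x)]; y[aft] <- sb$y[length(sb$y)]
    hd[aft] <- sb$heading_end
  }
  if (noise) {
    theta <- theta + stats::rnorm(n_frames, 0, cal$noise$angle_sd)
    x <- x + stats::rnorm(n_frames, 0, cal$noise$pos_sd)
    y <- y + stats::rnorm(n_frames, 0, cal$noise$pos_sd)
  }
  frames <- data.frame(
    frame = 0:(n_frames - 1L), time_s = (0:(n_frames - 1L)) / rate,
    x_mm = x, y_mm = y, heading_deg = hd, tail_angle_deg = theta,
    flagged = FALSE
  )
  gt <- data.frame(
    bout_index = 1L, onset_s = onset, offset_s = onset + d,
    category = "escape", duration_s = d, distance_mm = dist,
    speed_mm_s = dist / d, n_osc = k, tbf_hz = tbf,
    max_bend_deg = abs(cbend), median_bend_deg = stats::median(abs(peaks)),
    first_bend_deg = peaks[1], heading_change_deg = dheading,
    latency_ms = lat_ms, cbend_deg = abs(cbend), counterbend_deg = abs(peaks[2]),
    stringsAsFactors = FALSE
  )
  newTailTrace(frames, rate, stimTime = stim_time, groundTruth = gt,
               meta = list(fish_id = fish$fish_id %||% NA,
                           clutch = fish$clutch %||% NA,
                           genotype = fish$genotype %||% NA,
                           kind = "escape"))
}
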