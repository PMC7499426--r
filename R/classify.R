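# Bout classification, escape selection, fish-level QC and aggregation.

#' Classify a slow-swim bout as forward swim or routine turn
#'
#' Forward swims are bouts whose maximal absolute bend amplitude is strictly
#' below the cutoff (default 25 degrees); all others (including a bout
#' exactly at the cutoff) are routine turns.
#'
#' @param max_bend maximal absolute bend amplitude(s), degrees (vectorized).
#' @param cutoff classification cutoff in degrees.
#' @return character vector, "forward" or "turn".
#' @examples
#' classifyBout(c(10, 60, 25))  # forward, turn, turn
#' @export
classifyBout <- function(max_bend, cutoff = 25) {
  ifelse(max_bend < cutoff, "forward", "turn")
}

#' Select the escape response of one trial
#'
#' Applies the selection rule: the first bout starting after the stimulus
#' whose latency is below \code{max_latency_ms} and whose first tail bend
#' exceeds \code{min_first_bend} in absolute value. Latency is measured from
#' the stimulus to the timestamp of the bout-onset frame. A bout overlapping
#' the stimulus marks the trial as contaminated by spontaneous motion and
#' nothing is selected.
#'
#' @param bouts time-ordered bout table of one trial ([sessionBouts()]).
#' @param stim_time stimulus time in seconds.
#' @param rate sampling rate in Hz.
#' @param max_latency_ms latency criterion (strict upper bound), ms.
#' @param min_first_bend first-bend criterion (strict lower bound), degrees.
#' @return one-row data.frame: \code{selected}, \code{contaminated},
#'   \code{latency_ms}, \code{cbend_deg}, \code{counterbend_deg} and the six
#'   bout-level parameters of the selected bout (NA when nothing selected).
#' @export
selectEscape <- function(bouts, stim_time, rate,
                         max_latency_ms = 30, min_first_bend = 60) {
  empty <- data.frame(selected = FALSE, contaminated = FALSE,
                      latency_ms = NA_real_, cbend_deg = NA_real_,
                      counterbend_deg = NA_real_, distance_mm = NA_real_,
                      duration_s = NA_real_, speed_mm_s = NA_real_,
                      n_osc = NA_integer_, tbf_hz = NA_real_)
  if (!nrow(bouts)) return(empty)
  onset_t <- bouts$onset / rate
  offset_t <- bouts$offset / rate
  if (any(onset_t < stim_time & offset_t > stim_time)) {
    empty$contaminated <- TRUE
    return(empty)
  }
  post <- which(onset_t >= stim_time)
  for (i in post) {
    lat <- (onset_t[i] - stim_time) * 1000
    bends <- bouts$bends[[i]]
    if (lat < max_latency_ms && abs(bends[1]) > min_first_bend) {
      return(data.frame(
        selected = TRUE, contaminated = FALSE, latency_ms = lat,
        cbend_deg = abs(bends[1]),
        counterbend_deg = if (length(bends) > 1) abs(bends[2]) else NA_real_,
        distance_mm = bouts$distance_mm[i], duration_s = bouts$duration_s[i],
        speed_mm_s = bouts$speed_mm_s[i], n_osc = bouts$n_osc[i],
        tbf_hz = bouts$tbf_hz[i]))
    }
  }
  empty
}

.slowParams <- c("distance_mm", "duration_s", "speed_mm_s",
                 "n_osc", "tbf_hz", "median_bend_deg")
.escapeParams <- c("distance_mm", "duration_s", "speed_mm_s", "n_osc",
                   "tbf_hz", "latency_ms", "cbend_deg", "counterbend_deg")

#' Aggregate one fish into a summary row
#'
#' Slow-swim bouts are classified, the fish passes QC if it swam at least
#' \code{min_bouts} bouts over the session, and the per-fish value of each
#' kinematic parameter is the median over all bouts of a category. Escape
#' parameters are means over the selected trials only; a fish with no
#' selected trial keeps NA escape fields (excluded from the escape
#' comparison but not from the slow-swim one).
#'
#' @param bouts slow-swim bout table of one fish (may be empty).
#' @param escapes data.frame of per-trial [selectEscape()] rows (may be NULL).
#' @param meta named list/row with \code{fish_id}, \code{clutch},
#'   \code{genotype}.
#' @param session_duration slow-swim recording length (s) for the bout rate.
#' @param cutoff forward/turn cutoff, degrees.
#' @param min_bouts QC threshold: fish with fewer bouts fail QC.
#' @return one-row data.frame (a FishSummary).
#' @export
summarizeFish <- function(bouts, escapes = NULL, meta = list(),
                          session_duration = 300, cutoff = 25,
                          min_bouts = 30) {
  n_bouts <- if (is.null(bouts)) 0L else nrow(bouts)
  out <- data.frame(
    fish_id = meta$fish_id %||% NA, clutch = meta$clutch %||% NA,
    genotype = meta$genotype %||% NA,
    n_bouts = n_bouts,
    bout_rate_hz = if (n_bouts) boutRate(bouts, session_duration) else 0,
    qc_pass = n_bouts >= min_bouts,
    stringsAsFactors = FALSE
  )
  cats <- if (n_bouts) classifyBout(bouts$max_bend_deg, cutoff) else character()
  out$n_forward <- sum(cats == "forward")
  out$n_turn <- sum(cats == "turn")
  for (cat in c("forward", "turn")) {
    pre <- if (cat == "forward") "fwd" else "trn"
    sel <- cats == cat
    for (p in .slowParams) {
      out[[paste(pre, p, sep = "_")]] <-
        if (any(sel)) stats::median(bouts[[p]][sel]) else NA_real_
    }
  }
  if (!is.null(escapes) && nrow(escapes)) {
    sel <- escapes$selected
    out$n_trials <- nrow(escapes)
    out$n_selected <- sum(sel)
    for (p in .escapeParams) {
      out[[paste("esc", p, sep = "_")]] <-
        if (any(sel)) mean(escapes[[p]][sel]) else NA_real_
    }
  } else {
    out$n_trials <- 0L
    out$n_selected <- 0L
    for (p in .escapeParams) out[[paste("esc", p, sep = "_")]] <- NA_real_
  }
  out
}

#' Forward/turn composition per genotype
#'
#' Pools bout counts over the QC-passing fish of each genotype and returns
#' the fraction of forward swims and routine turns.
#'
#' @param summaries fish-summary table ([summarizeFish()] rows).
#' @return data.frame per genotype: pooled counts and fractions (sum to 1).
#' @export
categoryRatio <- function(summaries) {
  s <- summaries[summaries$qc_pass, , drop = FALSE]
  out <- do.call(rbind, lapply(split(s, s$genotype), function(d) {
    nf <- sum(d$n_forward); nt <- sum(d$n_turn)
    data.frame(genotype = d$genotype[1], n_forward = nf, n_turn = nt,
               frac_forward = nf / (nf + nt), frac_turn = nt / (nf + nt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
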