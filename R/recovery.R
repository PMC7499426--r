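# Calibration-recovery driver: simulate a single-genotype cohort at the
# study's protocol and push every fish through the full measurement pipeline
# (trace synthesis -> bout detection -> bend peaks -> classification ->
# aggregation). Used to verify that the pipeline recovers the calibrated
# group-level values.

#' Simulate a cohort and recover per-fish summaries through the pipeline
#'
#' @param genotype "wt" or "mut" (the calibrated genotype level to draw).
#' @param regime "slow" (5-min spontaneous sessions) or "escape"
#'   (1-s trials at 650 Hz with the stimulus at 200 ms).
#' @param n_fish number of fish.
#' @param seed master seed; per-fish seeds derive from it.
#' @param n_clutches clutches the fish are spread over.
#' @param duration,rate slow-session protocol.
#' @param n_trials,trial_len,stim_time,escape_rate escape protocol.
#' @return fish-summary data.frame (one row per fish, [summarizeFish()]
#'   columns).
#' @export
cohortRecovery <- function(genotype = "mut", regime = c("slow", "escape"),
                           n_fish = 58, seed = 1, n_clutches = 4,
                           duration = 300, rate = 100,
                           n_trials = 10, trial_len = 1, stim_time = 0.2,
                           escape_rate = 650) {
  regime <- match.arg(regime)
  cc <- cohortConfig(n_clutches = n_clutches, seed = seed)
  nf <- stats::setNames(n_fish, genotype)
  coh <- generateCohort(cc, n_fish = nf)
  out <- vector("list", nrow(coh))
  for (i in seq_len(nrow(coh))) {
    f <- as.list(coh[i, ])
    set.seed(childSeed(seed, i))
    if (regime == "slow") {
      tr <- simulateSlowSession(f, duration = duration, rate = rate)
      bouts <- sessionBouts(tr)
      out[[i]] <- summarizeFish(bouts, NULL, meta = f,
                                session_duration = duration)
    } else {
      escapes <- do.call(rbind, lapply(seq_len(n_trials), function(j) {
        et <- simulateEscapeTrial(f, trial_len = trial_len,
                                  stim_time = stim_time, rate = escape_rate)
        selectEscape(sessionBouts(et), stim_time, escape_rate)
      }))
      out[[i]] <- summarizeFish(NULL, escapes, meta = f)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
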