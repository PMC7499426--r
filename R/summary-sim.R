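# Summary-level cohort simulator: draws the per-fish summary statistics
# directly from the generator's bout-level distributions, skipping trace
# synthesis and detection. Used for statistical calibration studies
# (type-I error, family-wise error, power) where thousands of cohorts are
# needed; the distributional structure (latent hierarchy, per-bout
# dispersions, derived duration/speed/TBF, escape selection rule) is the
# same as the trace-level path.

#' Simulate fish summaries without trace synthesis
#'
#' For each fish of a [generateCohort()] cohort, draws its bouts'
#' (distance, speed) pairs, bend medians and oscillation counts from the
#' same per-bout distributions the trace generator uses, aggregates per-fish
#' medians per category, and simulates the escape trials with the selection
#' rule (latency < 30 ms, first bend > 60 deg) and per-fish means over the
#' selected trials. Bout counts are Poisson at the fish's latent rate.
#'
#' @param config a [cohortConfig()].
#' @param n_fish optional per-genotype totals (see [generateCohort()]).
#' @param n_trials escape trials per fish.
#' @param session_duration slow-swim session length (s).
#' @return a fish-summary data.frame compatible with [compareGroups()].
#' @export
simulateFishSummaries <- function(config, n_fish = NULL, n_trials = 10,
                                  session_duration = 300) {
  coh <- generateCohort(config, n_fish = n_fish)
  cal <- config$calibration
  sdlog <- function(cv) sqrt(log(1 + cv^2))
  esc <- cal$escape
  out <- vector("list", nrow(coh))
  for (i in seq_len(nrow(coh))) {
    f <- as.list(coh[i, ])
    nb <- stats::rpois(1, f$bout_rate * session_duration)
    cats <- stats::runif(nb) < f$p_forward
    row <- coh[i, c("fish_id", "clutch", "genotype")]
    row$n_bouts <- nb
    row$bout_rate_hz <- nb / session_duration
    row$qc_pass <- nb >= 30
    row$n_forward <- sum(cats)
    row$n_turn <- nb - sum(cats)
    for (cat in c("forward", "turn")) {
      blk <- if (cat == "forward") cal$forward else cal$turn
      pre <- if (cat == "forward") "fwd" else "trn"
      n <- if (cat == "forward") sum(cats) else nb - sum(cats)
      if (n == 0) {
        for (p in .slowParams) row[[paste(pre, p, sep = "_")]] <- NA_real_
        next
      }
      ds <- exp(rbvnorm(n, blk$bout_sdlog[["distance"]],
                        blk$bout_sdlog[["speed"]], blk$bout_rho_ds) +
                rep(log(c(f[[paste0(pre, "_distance")]],
                          f[[paste0(pre, "_speed")]])), each = n))
      d <- ds[, 1] / ds[, 2]
      k <- pmax(1, round(rlnormMedian(n, f[[paste0(pre, "_nosc")]],
                                      blk$bout_sdlog[["n_osc"]])))
      bend <- rlnormMedian(n, f[[paste0(pre, "_bend")]],
                           blk$bout_sdlog[["bend"]])
      row[[paste0(pre, "_distance_mm")]] <- stats::median(ds[, 1])
      row[[paste0(pre, "_duration_s")]] <- stats::median(d)
      row[[paste0(pre, "_speed_mm_s")]] <- stats::median(ds[, 2])
      row[[paste0(pre, "_n_osc")]] <- stats::median(k)
      row[[paste0(pre, "_tbf_hz")]] <- stats::median(k / d)
      row[[paste0(pre, "_median_bend_deg")]] <- stats::median(bend)
    }
    lat <- rlnormMean(n_trials, f$esc_latency, sdlog(esc$trial_cv[["latency"]]))
    tbf <- rlnormMean(n_trials, f$esc_tbf, sdlog(esc$trial_cv[["tbf"]]))
    k <- pmax(3, round(rlnormMean(n_trials, f$esc_nosc,
                                  sdlog(esc$trial_cv[["n_osc"]]))))
    d <- k / tbf
    dist <- rlnormMean(n_trials, f$esc_distance, sdlog(esc$trial_cv[["distance"]]))
    cb <- stats::rnorm(n_trials, f$esc_cbend, esc$trial_sd[["cbend"]])
    ct <- pmin(pmax(5, stats::rnorm(n_trials, f$esc_counter,
                                    esc$trial_sd[["counter"]])), 0.8 * abs(cb))
    sel <- lat < 30 & abs(cb) > 60
    row$n_trials <- n_trials
    row$n_selected <- sum(sel)
    vals <- list(distance_mm = dist, duration_s = d, speed_mm_s = dist / d,
                 n_osc = k, tbf_hz = k / d, latency_ms = lat,
                 cbend_deg = abs(cb), counterbend_deg = ct)
    for (p in names(vals))
      row[[paste0("esc_", p)]] <-
        if (any(sel)) mean(vals[[p]][sel]) else NA_real_
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
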