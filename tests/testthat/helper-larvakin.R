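# shared fixtures built in code

# a minimal TailTrace from a tail-angle vector (stationary head)
traceFromAngles <- function(theta, rate = 100, x = NULL, y = NULL) {
  n <- length(theta)
  fr <- data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / rate,
                   x_mm = x %||% rep(0, n), y_mm = y %||% rep(0, n),
                   heading_deg = 0, tail_angle_deg = theta, flagged = FALSE)
  larvakin:::newTailTrace(fr, rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-row trace for a static rendered pose
poseTrace <- function(heading, alpha, x = 0, y = 0, rate = 100) {
  fr <- data.frame(frame = 0L, time_s = 0, x_mm = x, y_mm = y,
                   heading_deg = heading, tail_angle_deg = alpha,
                   flagged = FALSE)
  larvakin:::newTailTrace(fr, rate)
}

# a deterministic fish: genotype-level latents with zero dispersion
fixedFish <- function(genotype = "mut", seed = 1) {
  cfg <- cohortConfig(seed = seed, sd_scale = 0)
  coh <- generateCohort(cfg)
  as.list(coh[coh$genotype == genotype, ][1, ])
}

# greedy 1:1 matching of detected bouts to ground truth by onset time
matchBouts <- function(detected, gt, rate, tol_s = 0.1) {
  used <- rep(FALSE, nrow(detected))
  pairs <- NULL
  for (i in seq_len(nrow(gt))) {
    d <- abs(detected$onset_s - gt$onset_s[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(gt = i, det = j))
    }
  }
  npairs <- if (is.null(pairs)) 0L else nrow(pairs)
  list(pairs = pairs,
       recall = npairs / nrow(gt),
       precision = if (nrow(detected)) npairs / nrow(detected) else NA_real_)
}

# exact-rank matrices with known Spearman correlations
spearmanHalfPair <- function() cbind(a = 1:5, b = c(2, 4, 1, 3, 5))   # rho = 0.5
spearmanZeroPair <- function() cbind(a = 1:4, b = c(2, 4, 1, 3))      # rho = 0
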