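test_that("cohort layout, degenerate variance and determinism", {
  cfg <- cohortConfig(n_clutches = 4, fish_per_clutch_per_genotype = 15,
                      seed = 7)
  coh <- generateCohort(cfg)
  expect_equal(nrow(coh), 120)
  expect_equal(length(unique(coh$clutch)), 4)
  expect_equal(unname(table(coh$genotype)[c("wt", "mut")]), c(60L, 60L),
               ignore_attr = TRUE)

  # zero dispersion: all fish of a genotype share identical latents
  coh0 <- generateCohort(cohortConfig(seed = 3, sd_scale = 0))
  for (p in c("fwd_distance", "esc_cbend", "bout_rate"))
    expect_equal(length(unique(round(coh0[[p]][coh0$genotype == "mut"], 12))), 1)

  # latents equal the calibrated genotype values when dispersion is 0
  cal <- defaultCalibration()
  expect_equal(coh0$fwd_distance[coh0$genotype == "mut"][1],
               cal$forward$distance[["mut"]])
  expect_equal(coh0$esc_latency[coh0$genotype == "wt"][1],
               cal$escape$latency[["wt"]])

  # same seed twice: identical cohorts
  expect_identical(generateCohort(cohortConfig(seed = 11)),
                   generateCohort(cohortConfig(seed = 11)))
  # different seed: different draws
  expect_false(identical(generateCohort(cohortConfig(seed = 11)),
                         generateCohort(cohortConfig(seed = 12))))

  # invalid configs
  expect_error(cohortConfig(n_clutches = 0), "counts")
  expect_error(cohortConfig(sd_scale = -1), "sd_scale")
})

test_that("null effect scale equalizes genotype-level values", {
  coh <- generateCohort(cohortConfig(seed = 5, sd_scale = 0, effect_scale = 0))
  expect_equal(coh$fwd_distance[coh$genotype == "mut"][1],
               coh$fwd_distance[coh$genotype == "wt"][1])
})

test_that("slow-session traces honor the renewal/waveform contract", {
  f <- fixedFish("mut")
  set.seed(42)
  tr <- simulateSlowSession(f, duration = 60, rate = 100)
  gt <- groundTruth(tr)
  expect_gt(nrow(gt), 30)
  # conservation: bouts inside the recording, ordered, non-overlapping
  expect_true(all(gt$onset_s >= 0 & gt$offset_s <= 60))
  expect_true(all(diff(gt$onset_s) > 0))
  expect_true(all(utils::head(gt$offset_s, -1) < utils::tail(gt$onset_s, -1)))
  # sampling arithmetic: ground-truth duration times rate gives the frame span
  expect_equal(gt$offset_s - gt$onset_s, gt$duration_s)
  # tail angle quiescent between bouts (noise only)
  th <- traceFrames(tr)$tail_angle_deg
  inb <- rep(FALSE, length(th))
  for (i in seq_len(nrow(gt)))
    inb[(floor(gt$onset_s[i] * 100):ceiling(gt$offset_s[i] * 100)) + 1] <- TRUE
  expect_lt(stats::sd(th[!inb]), 3 * defaultCalibration()$noise$angle_sd)
  # category construction: every forward < 25 deg, every turn > 25 deg
  expect_true(all(gt$max_bend_deg[gt$category == "forward"] < 25))
  expect_true(all(gt$max_bend_deg[gt$category == "turn"] > 25))
  # determinism
  set.seed(42)
  tr2 <- simulateSlowSession(f, duration = 60, rate = 100)
  expect_identical(traceFrames(tr), traceFrames(tr2))

  # vanishing bout rate: pure-noise trace, empty ground truth
  f0 <- f; f0$bout_rate <- 1e-4
  set.seed(1)
  tr0 <- simulateSlowSession(f0, duration = 20, rate = 100)
  expect_equal(nrow(groundTruth(tr0)), 0)
  expect_lt(max(abs(traceFrames(tr0)$tail_angle_deg)), 1)

  # over-dense bout request cannot fit
  fhi <- f; fhi$bout_rate <- 5
  expect_error(simulateSlowSession(fhi, duration = 10, rate = 100), "overlap")
})

test_that("per-bout draws are calibrated to the configured targets", {
  # law-of-large-numbers check on ground truth only (no detection):
  # slow-swim draws are median-parametrized, escape draws mean-parametrized
  f <- fixedFish("mut")
  cal <- defaultCalibration()
  set.seed(101)
  gt <- do.call(rbind, lapply(1:5, function(i)
    groundTruth(simulateSlowSession(f, duration = 300, rate = 100,
                                    noise = FALSE))))
  fwd <- gt[gt$category == "forward", ]
  expect_gt(nrow(fwd), 900)
  med_se <- function(v) 1.2533 * stats::sd(v) / sqrt(length(v))
  expect_lt(abs(stats::median(fwd$distance_mm) - cal$forward$distance[["mut"]]),
            2 * med_se(fwd$distance_mm))
  expect_lt(abs(stats::median(fwd$speed_mm_s) - cal$forward$speed[["mut"]]),
            2 * med_se(fwd$speed_mm_s))
  expect_lt(abs(stats::median(fwd$median_bend_deg) - cal$forward$bend[["mut"]]),
            2 * med_se(fwd$median_bend_deg) + 0.02)
  # bout rate: renewal process count over the session
  n_sessions <- 5
  rate_hat <- nrow(gt) / (n_sessions * 300)
  expect_lt(abs(rate_hat - cal$session$bout_rate[["mut"]]),
            2 * sqrt(nrow(gt)) / (n_sessions * 300))

  set.seed(102)
  egt <- do.call(rbind, lapply(1:1000, function(i)
    groundTruth(simulateEscapeTrial(f, noise = FALSE))))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(egt$distance_mm) - cal$escape$distance[["mut"]]),
            2 * sem(egt$distance_mm))
  expect_lt(abs(mean(egt$tbf_hz) - cal$escape$tbf[["mut"]]),
            2 * sem(egt$tbf_hz))
  expect_lt(abs(mean(egt$latency_ms) - cal$escape$latency[["mut"]]),
            2 * sem(egt$latency_ms))
  expect_lt(abs(mean(egt$cbend_deg) - cal$escape$cbend[["mut"]]),
            2 * sem(egt$cbend_deg))
})

test_that("escape trials are quiescent before the response and C-bend led", {
  f <- fixedFish("mut")
  set.seed(7)
  for (i in 1:10) {
    tr <- simulateEscapeTrial(f)
    gt <- groundTruth(tr)
    expect_equal(nrow(gt), 1)
    # onset a few frames after the stimulus at the calibrated ~5.5 ms latency
    onset_frame <- gt$onset_s * 650
    stim_frame <- 0.2 * 650
    expect_gt(onset_frame - stim_frame, 1)
    expect_lt(onset_frame - stim_frame, 15)
    # pre-response quiescence
    th <- traceFrames(tr)$tail_angle_deg
    pre <- th[seq_len(floor(gt$onset_s * 650) - 1)]
    expect_lt(max(abs(pre)), 1)
    # C-bend is the largest, counter bend opposite in sign
    expect_gt(gt$cbend_deg, gt$counterbend_deg)
    expect_equal(gt$max_bend_deg, gt$cbend_deg)
  }
  # sign alternation of the injected peaks
  set.seed(8)
  tr <- simulateEscapeTrial(f, noise = FALSE)
  th <- traceFrames(tr)$tail_angle_deg
  b <- detectBends(tr, c(floor(groundTruth(tr)$onset_s * 650) - 2,
                         ceiling(groundTruth(tr)$offset_s * 650) + 2))
  expect_true(all(diff(sign(b)) != 0))
})

test_that("boundary-stress mode draws bouts at the classification cutoff", {
  f <- fixedFish("mut")
  set.seed(33)
  tr <- simulateSlowSession(f, duration = 120, rate = 100,
                            boundary_stress = TRUE)
  gt <- groundTruth(tr)
  expect_true(all(gt$max_bend_deg > 22.9 & gt$max_bend_deg < 27.1))
  expect_identical(gt$category, ifelse(gt$max_bend_deg < 25, "forward", "turn"))
  expect_true(all(c("forward", "turn") %in% gt$category))
})
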