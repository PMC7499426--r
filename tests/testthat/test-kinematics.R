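test_that("detection returns nothing on motionless traces", {
  expect_equal(nrow(detectBouts(traceFromAngles(rep(0, 2000)))), 0)
  set.seed(1)  # pure sensor noise is below the envelope threshold
  expect_equal(nrow(detectBouts(traceFromAngles(rnorm(2000, 0, 0.15)))), 0)
})

test_that("sessions with excessive tracking failures are rejected", {
  tr <- traceFromAngles(rep(0, 1000))
  tr@frames$flagged[1:300] <- TRUE
  expect_error(detectBouts(tr), "rejected")
})

test_that("bend peaks: constructed waveforms give the expected peak lists", {
  rate <- 100
  # single half-cycle reaching +30 degrees -> one peak of +30
  t <- seq(0, 0.1, by = 1 / rate)
  th <- c(rep(0, 20), 30 * sin(pi * t / 0.1), rep(0, 20))
  tr <- traceFromAngles(th)
  b <- detectBends(tr, c(0, length(th)))
  expect_equal(length(b), 1)
  expect_equal(b, 30, tolerance = 0.02)

  # symmetric sinusoid, 4 half-cycles at +-15: four alternating peaks
  t <- seq(0, 0.4 - 1e-9, by = 1 / rate)
  th <- c(rep(0, 20), 15 * sin(2 * pi * t / 0.2), rep(0, 20))
  b <- detectBends(traceFromAngles(th), c(0, length(th)))
  expect_equal(length(b), 4)
  expect_true(all(abs(abs(b) - 15) < 0.5))
  expect_true(all(diff(sign(b)) != 0))

  # noisy synthetic bout: peaks within 1 degree of the injected bends
  f <- fixedFish("mut")
  set.seed(12)
  tr <- simulateSlowSession(f, duration = 30, rate = 100)
  gt <- groundTruth(tr)
  iv <- detectBouts(tr)
  m <- matchBouts(cbind(iv, onset_s = iv$onset / 100), gt, 100)
  found <- 0
  for (k in seq_len(nrow(m$pairs))) {
    i <- m$pairs[k, "gt"]; j <- m$pairs[k, "det"]
    b <- detectBends(tr, c(max(0, iv$onset[j] - 2), iv$offset[j] + 2))
    if (length(b)) {
      # 1 degree for forward-scale bends; sharp large turn peaks carry a
      # slightly larger parabolic-fit error (relative bound)
      expect_lt(abs(max(abs(b)) - gt$max_bend_deg[i]),
                max(1, 0.03 * gt$max_bend_deg[i]))
      found <- found + 1
    }
  }
  expect_gt(found, 10)
})

test_that("bout kinematics follow the stated definitions", {
  # 8 bends over 0.25 s: n_osc = 4, TBF = 16 Hz
  tr <- traceFromAngles(rep(0, 100))
  bk <- boutKinematics(tr, c(10, 35), bends = rep(c(10, -10), 4))
  expect_equal(bk$n_osc, 4L)
  expect_equal(bk$tbf_hz, 16)
  expect_equal(bk$duration_s, 0.25)

  # distance convention: 0.02 mm/frame over a 27-frame half-open interval,
  # unsmoothed positions reduce to exactly 27 displacement steps
  n <- 100
  tr2 <- traceFromAngles(rep(0, n), x = 0.02 * (0:(n - 1)), y = rep(0, n))
  bk2 <- boutKinematics(tr2, c(10, 37), bends = c(10, -5), smooth_window = 1)
  expect_equal(bk2$distance_mm, 27 * 0.02)
  expect_equal(bk2$speed_mm_s, 0.54 / 0.27)
  expect_equal(bk2$max_bend_deg, 10)
  expect_equal(bk2$median_bend_deg, 7.5)
})

test_that("kinematics are invariant to translation and time reversal", {
  f <- fixedFish("mut")
  set.seed(77)
  tr <- simulateSlowSession(f, duration = 20, rate = 100)
  iv <- detectBouts(tr)
  expect_gt(nrow(iv), 3)
  b1 <- sessionBouts(tr)
  # constant offset on head coordinates
  tr2 <- tr
  tr2@frames$x_mm <- tr2@frames$x_mm + 12.3
  tr2@frames$y_mm <- tr2@frames$y_mm - 4.5
  b2 <- sessionBouts(tr2)
  expect_equal(b1$distance_mm, b2$distance_mm)
  expect_equal(b1$max_bend_deg, b2$max_bend_deg)
  # time reversal of the whole session: per-bout duration, distance and
  # n_osc are preserved (bouts appear at mirrored positions)
  n <- nrow(tr@frames)
  trR <- tr
  trR@frames$tail_angle_deg <- rev(tr@frames$tail_angle_deg)
  trR@frames$x_mm <- rev(tr@frames$x_mm)
  trR@frames$y_mm <- rev(tr@frames$y_mm)
  bR <- sessionBouts(trR)
  expect_equal(nrow(bR), nrow(b1))
  for (i in seq_len(nrow(b1))) {
    j <- which.min(abs(bR$onset - (n - b1$offset[i])))
    expect_equal(bR$duration_s[j], b1$duration_s[i], tolerance = 0.05)
    expect_equal(bR$distance_mm[j], b1$distance_mm[i], tolerance = 0.05)
    expect_equal(bR$n_osc[j], b1$n_osc[i])
  }
})

test_that("bout rate is count over duration", {
  expect_equal(boutRate(data.frame(onset = seq_len(273)), 300), 0.91)
  expect_equal(boutRate(data.frame(onset = seq_len(285)), 300), 0.95)
  expect_equal(boutRate(data.frame(onset = integer()), 300), 0)
})

test_that("detection recovers injected bouts 1:1 with accurate onsets", {
  f <- fixedFish("mut")
  set.seed(4)
  tr <- simulateSlowSession(f, duration = 120, rate = 100, noise = FALSE)
  gt <- groundTruth(tr)
  iv <- detectBouts(tr)
  m <- matchBouts(cbind(iv, onset_s = iv$onset / 100), gt, 100)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  onset_err <- abs(iv$onset[m$pairs[, "det"]] / 100 -
                   gt$onset_s[m$pairs[, "gt"]]) * 100
  expect_true(all(onset_err <= 2))
})

test_that("per-bout parameter recovery is unbiased up to discretization", {
  # paired recovered-vs-truth errors over ~1000 bouts; the allowance adds
  # the detector's sub-frame edge conventions on top of 2 SEM
  f <- fixedFish("mut")
  set.seed(55)
  pairs <- NULL
  for (r in 1:4) {
    tr <- simulateSlowSession(f, duration = 300, rate = 100)
    gt <- groundTruth(tr)
    b <- sessionBouts(tr)
    m <- matchBouts(b, gt, 100)
    pairs <- rbind(pairs,
                   data.frame(dur = b$duration_s[m$pairs[, "det"]] -
                                gt$duration_s[m$pairs[, "gt"]],
                              dist_rel = b$distance_mm[m$pairs[, "det"]] /
                                gt$distance_mm[m$pairs[, "gt"]] - 1,
                              bend = b$max_bend_deg[m$pairs[, "det"]] -
                                gt$max_bend_deg[m$pairs[, "gt"]],
                              tbf_rel = b$tbf_hz[m$pairs[, "det"]] /
                                gt$tbf_hz[m$pairs[, "gt"]] - 1))
  }
  expect_gt(nrow(pairs), 900)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(pairs$dur)), 2 * sem(pairs$dur) + 0.01)       # 1 frame
  expect_lt(abs(mean(pairs$dist_rel)), 2 * sem(pairs$dist_rel) + 0.02)
  expect_lt(abs(mean(pairs$bend)), 2 * sem(pairs$bend) + 0.3)
  expect_lt(abs(mean(pairs$tbf_rel)), 2 * sem(pairs$tbf_rel) + 0.025)
})
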