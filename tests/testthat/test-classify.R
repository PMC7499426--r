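test_that("forward/turn classification uses a strict 25-degree cutoff", {
  expect_equal(classifyBout(c(10, 60, 25, 24.999)),
               c("forward", "turn", "turn", "forward"))
  # config-exposed cutoff
  expect_equal(classifyBout(30, cutoff = 40), "forward")
})

test_that("escape selection applies the latency and first-bend rules", {
  rate <- 650
  mkbouts <- function(onsets_s, first_bends, dur = 0.25) {
    data.frame(onset = round(onsets_s * rate), offset = round((onsets_s + dur) * rate),
               distance_mm = 9, duration_s = dur, speed_mm_s = 9 / dur,
               n_osc = 8L, tbf_hz = 8 / dur, max_bend_deg = abs(first_bends),
               median_bend_deg = 20, first_bend_deg = first_bends,
               bends = I(lapply(first_bends, function(b) c(b, -0.45 * b, 0.3 * b))))
  }
  # 5.4 ms latency, 101-deg first bend: selected
  b <- mkbouts(0.2 + 5.4 / 1000, 101)
  r <- selectEscape(b, 0.2, rate)
  expect_true(r$selected)
  expect_equal(r$latency_ms, round((0.2 + 0.0054) * rate) / rate * 1000 - 200)
  expect_lt(abs(r$latency_ms - 5.4), 1.6)  # frame-start timestamp convention
  expect_equal(r$cbend_deg, 101)
  expect_equal(r$counterbend_deg, 45.45)
  # 35 ms latency: not selected
  expect_false(selectEscape(mkbouts(0.235, 101), 0.2, rate)$selected)
  # 50-deg first bend: not selected
  expect_false(selectEscape(mkbouts(0.205, 50), 0.2, rate)$selected)
  # 60 deg exactly: "above 60" is strict
  expect_false(selectEscape(mkbouts(0.205, 60), 0.2, rate)$selected)
  # second bout qualifies after a weak first response
  b2 <- rbind(mkbouts(0.204, 30), mkbouts(0.215, 95))
  r2 <- selectEscape(b2, 0.2, rate)
  expect_true(r2$selected)
  expect_equal(r2$cbend_deg, 95)
  # bout overlapping the stimulus: contamination, nothing selected
  b3 <- rbind(mkbouts(0.15, 80), mkbouts(0.21, 95))
  r3 <- selectEscape(b3, 0.2, rate)
  expect_false(r3$selected)
  expect_true(r3$contaminated)
  # idempotence / order stability
  expect_identical(selectEscape(b2, 0.2, rate), selectEscape(b2, 0.2, rate))
})

test_that("fish summaries apply QC and per-category medians", {
  mkb <- function(n, dist = 0.5, maxb = 10) {
    data.frame(onset = seq_len(n) * 100, offset = seq_len(n) * 100 + 27,
               onset_s = seq_len(n), duration_s = 0.27, distance_mm = dist,
               speed_mm_s = dist / 0.27, n_peaks = 7L, n_osc = 4L,
               tbf_hz = 4 / 0.27, max_bend_deg = maxb, median_bend_deg = 3,
               first_bend_deg = maxb)
  }
  s29 <- summarizeFish(mkb(29), session_duration = 300)
  expect_false(s29$qc_pass)
  s30 <- summarizeFish(mkb(30), session_duration = 300)
  expect_true(s30$qc_pass)
  expect_equal(s30$bout_rate_hz, 0.1)
  # per-category median of distances
  b <- mkb(3)
  b$distance_mm <- c(0.4, 0.5, 0.9)
  s <- summarizeFish(b, session_duration = 300)
  expect_equal(s$fwd_distance_mm, 0.5)
  expect_equal(s$n_forward, 3)
  expect_equal(s$n_turn, 0)
  expect_true(is.na(s$trn_distance_mm))
  # zero selected escape trials: NA escape fields, fish still summarised
  esc <- data.frame(selected = c(FALSE, FALSE), contaminated = FALSE,
                    latency_ms = NA_real_, cbend_deg = NA_real_,
                    counterbend_deg = NA_real_, distance_mm = NA_real_,
                    duration_s = NA_real_, speed_mm_s = NA_real_,
                    n_osc = NA_integer_, tbf_hz = NA_real_)
  s0 <- summarizeFish(mkb(40), esc, session_duration = 300)
  expect_equal(s0$n_selected, 0)
  expect_true(is.na(s0$esc_cbend_deg))
  expect_true(s0$qc_pass)
})

test_that("category ratios pool counts per genotype and sum to one", {
  s <- data.frame(fish_id = c("a", "b", "c"), genotype = c("g1", "g1", "g2"),
                  qc_pass = c(TRUE, TRUE, TRUE),
                  n_forward = c(4000, 3534, 100), n_turn = c(1500, 966, 0))
  r <- categoryRatio(s)
  expect_equal(r$frac_forward[r$genotype == "g1"], 0.7534)
  expect_equal(r$frac_turn[r$genotype == "g1"], 0.2466)
  expect_equal(r$frac_forward[r$genotype == "g2"], 1)
  expect_equal(r$frac_turn[r$genotype == "g2"], 0)
  expect_equal(r$frac_forward + r$frac_turn, c(1, 1))
  # QC-failing fish are excluded from the pool
  s$qc_pass[1] <- FALSE
  r2 <- categoryRatio(s)
  expect_equal(r2$n_forward[r2$genotype == "g1"], 3534)
})

test_that("pooled forward fraction matches the generator probability", {
  s <- simulateFishSummaries(cohortConfig(seed = 17), n_fish = c(mut = 40))
  r <- categoryRatio(s)
  p <- defaultCalibration()$session$p_forward[["mut"]]
  n <- r$n_forward + r$n_turn
  expect_lt(abs(r$frac_forward - p), 2 * sqrt(p * (1 - p) / n) + 0.002)
})
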