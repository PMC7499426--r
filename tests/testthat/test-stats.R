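test_that("Meff eigen computation reproduces exact-rank cases", {
  # Spearman rho exactly 0.5 on two parameters: eigenvalues {1.5, 0.5},
  # Vcorr = 0.5, Meff = 1.75
  m <- computeMeff(spearmanHalfPair())
  expect_equal(sort(m@eigenvalues), c(0.5, 1.5))
  expect_equal(m@vcorr, 0.5)
  expect_equal(m@meff, 1.75)
  # exactly uncorrelated ranks: Meff = k
  m0 <- computeMeff(spearmanZeroPair())
  expect_equal(m0@meff, 2)
  # k = 1 convention
  expect_equal(computeMeff(matrix(1:10, ncol = 1))@meff, 1)
  # constant column: informative error naming the column
  bad <- cbind(x = 1:10, flat = rep(2, 10))
  expect_error(computeMeff(bad), "flat")
})

test_that("Meff respects its limits and decreases with correlation", {
  # perfect correlation (monotone transforms): Meff = 1 exactly
  v <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  mat <- cbind(v, 2 * v + 1, exp(v / 3), rank(v), v^3, sqrt(v), v - 10, 5 * v)
  m1 <- computeMeff(mat)
  expect_equal(m1@meff, 1)
  expect_equal(sum(m1@eigenvalues), 8)
  # near-independence at large n: Meff close to k
  set.seed(1)
  m8 <- computeMeff(matrix(rnorm(8 * 400), ncol = 8))
  expect_gt(m8@meff, 7.5)
  expect_lte(m8@meff, 8)
  # exchangeable-correlation family, k = 6: monotone decreasing in rho
  k <- 6
  meffs <- vapply(c(0, 0.25, 0.5, 0.75, 0.99), function(rho) {
    set.seed(99)
    z <- matrix(rnorm(4000 * k), ncol = k)
    shared <- rnorm(4000)
    x <- sqrt(rho) * shared + sqrt(1 - rho) * z
    computeMeff(x)@meff
  }, numeric(1))
  expect_true(all(diff(meffs) < 0))
  expect_true(all(meffs >= 1 & meffs <= k))
})

test_that("p-value adjustment multiplies by Meff and caps at one", {
  expect_equal(adjustPvalues(0.007, 4.003), 0.028021)
  expect_equal(adjustPvalues(0.5, 7.230), 1)
  expect_equal(adjustPvalues(c(0.01, 0.2), 1), c(0.01, 0.2))
  p <- runif(50)
  a <- adjustPvalues(p, 3.7)
  expect_true(all(a >= p))
  expect_true(all(a <= 1))
  expect_error(adjustPvalues(0.1, 0.5))
})

test_that("transform choice follows residual skewness", {
  set.seed(5)
  g <- rep(c("a", "b"), each = 150)
  gauss <- rnorm(300) + (g == "b")
  expect_equal(chooseTransform(gauss, g), "none")
  lnorm <- exp(rnorm(300, sd = 1)) * ifelse(g == "b", 1.3, 1)
  expect_equal(chooseTransform(lnorm, g), "log")
  withzero <- c(0, abs(rnorm(299)))
  expect_false(chooseTransform(withzero, g) == "log")
})

test_that("the genotype Wald test is symmetric and matches references", {
  s <- simulateFishSummaries(cohortConfig(seed = 23),
                             n_fish = c(wt = 40, mut = 40))
  s$y <- s$fwd_distance_mm
  ft <- fitGenotypeModel(s, "y")
  expect_true(is.finite(ft$wald_chi2))
  expect_equal(ft$model, "lmm")
  # label symmetry
  s2 <- s
  s2$genotype <- ifelse(s$genotype == "wt", "zz", "aa")
  ft2 <- fitGenotypeModel(s2, "y")
  expect_equal(ft2$wald_chi2, ft$wald_chi2, tolerance = 1e-6)
  # independent route: car::Anova Type II Wald chi-square on the same fit
  fit <- suppressMessages(lme4::lmer(y ~ genotype + (1 | clutch), data = s))
  ca <- car::Anova(fit, type = 2, test.statistic = "Chisq")
  expect_equal(ft$wald_chi2, ca[["Chisq"]][1], tolerance = 1e-6)
  expect_equal(ft$p_raw, ca[["Pr(>Chisq)"]][1], tolerance = 1e-6)
  # degenerate clutch variance: still finite, close to the fixed-effects Wald
  s0 <- simulateFishSummaries(cohortConfig(seed = 29, clutch_frac = 0),
                              n_fish = c(wt = 40, mut = 40))
  s0$y <- s0$fwd_distance_mm
  f0 <- fitGenotypeModel(s0, "y")
  lmfit <- lm(y ~ genotype, data = s0)
  chi_lm <- (coef(lmfit)[2] / sqrt(diag(vcov(lmfit))[2]))^2
  expect_lt(abs(f0$wald_chi2 - chi_lm) / chi_lm, 0.2)
  # a missing genotype is an error
  expect_error(fitGenotypeModel(s[s$genotype == "wt", ], "y"), "genotype")
})

test_that("compareGroups assembles per-family results with shared Meff", {
  s <- simulateFishSummaries(cohortConfig(seed = 31),
                             n_fish = c(wt = 30, mut = 30))
  r <- compareGroups(s, "forward")
  expect_equal(nrow(r), 6)
  expect_equal(length(unique(r$meff)), 1)
  expect_true(all(r$meff >= 1 & r$meff <= 6))
  expect_true(all(r$p_adj >= r$p_raw & r$p_adj <= 1))
  expect_true(all(c("mean_wt", "sem_wt", "mean_mut", "sem_mut") %in% names(r)))
  # single-parameter analysis: Meff = 1, p_adj = p_raw
  rb <- compareGroups(s, "boutrate")
  expect_equal(rb$meff, 1)
  expect_equal(rb$p_adj, rb$p_raw)
  # escape family: eight parameters
  re <- compareGroups(s, "escape")
  expect_equal(nrow(re), 8)
})
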