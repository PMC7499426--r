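# small internal helpers

# wrap an angle in degrees to (-180, 180]
wrapAngle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# lognormal draw parametrized by its MEDIAN (exp(meanlog))
rlnormMedian <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# lognormal draw parametrized by its MEAN
rlnormMean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# correlated bivariate normal, unit marginals scaled by (s1, s2)
rbvnorm <- function(n, s1, s2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1 * s1, z2 * s2)
}

# derive a reproducible child seed (< 2^31) from a base seed and an index
childSeed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483587 + 1
}

# centered running mean (window w samples, odd), edges padded by replication
runMean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  xp <- c(rep(x[1], w %/% 2), x, rep(x[n], w %/% 2))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(w %/% 2 + 1):(w %/% 2 + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
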