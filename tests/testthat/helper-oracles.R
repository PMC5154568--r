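# Independent oracle implementations used to check the waveform indices:
# plain one-line formulas evaluated on explicitly constructed cycles, kept
# separate from the package's code paths.

oracleBot <- function(v) 100 * mean(v > (min(v) + max(v)) / 2)
oracleBos <- function(v) 100 * (1 - (max(v) - min(v)) / (2 * mean(v)))
oracleAti <- function(v) 100 * (which.max(v) - 1) / length(v)
oracleRi <- function(v) (max(v) - min(v)) / max(v)

# brute-force scan over all cyclically adjacent pairs
oracleFaiBrute <- function(v) {
  n <- length(v)
  best <- -Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    best <- max(best, v[j] - v[i])
  }
  best
}

# rising / falling rates on a cycle already starting at its trough, via
# direct segment arithmetic (monotone limbs assumed)
oracleRates <- function(v) {
  p <- which.max(v)
  rise <- diff(v[1:p]); rise <- rise[rise > 0]
  fall <- -diff(c(v[p:length(v)], v[1])); fall <- fall[fall > 0]
  c(rr = 100 * mean(rise) / mean(v), fr = 100 * mean(fall) / mean(v))
}

# weighted phase skewness computed longhand
oracleSkew <- function(v, scale = 10) {
  w <- (v - min(v)) / sum(v - min(v))
  u <- (seq_along(v) - 0.5) / length(v)
  mu <- sum(w * u)
  scale * sum(w * (u - mu)^3) / sum(w * (u - mu)^2)^1.5
}

# Sample a profile's analytic waveform at exactly n phases over one period,
# starting at the diastolic trough (phase 0).
analyticCycle <- function(profile, n = 30) {
  P <- 60 / profile@heartRate
  mbrWaveform(profile, (seq_len(n) - 1) / n * P)
}

# Manual two-way ANOVA mean squares for a complete subjects x repeats
# matrix (the hand plug-in oracle for the ICC).
manualMeanSquares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ssr <- k * sum((rowMeans(m) - g)^2)
  ssc <- n * sum((colMeans(m) - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  c(msr = ssr / (n - 1), msc = ssc / (k - 1),
    mse = sse / ((n - 1) * (k - 1)))
}

# a fixed asymmetric test cycle (trough-aligned pulse shape)
pulseLikeCycle <- function(n = 30, rise = 0.3, tau = 0.4) {
  u <- (seq_len(n) - 1) / n
  ifelse(u <= rise, 10 + 8 * 0.5 * (1 - cos(pi * u / rise)),
         10 + 8 * exp(-(u - rise) / tau))
}
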