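# Analytic Wiener first-passage oracle and small test utilities.

# CDF of the first passage time at either of two symmetric bounds +-b for a
# Wiener process with drift v, unit diffusion, started at 0.  Closed-form
# asymptotic probability minus the fast-decaying series tail (series
# representation of the absorption-time distribution on an interval).
wiener_fpt_cdf <- function(t, v, b, K = 500) {
  a <- 2 * b
  w <- 0.5
  lower <- function(t, v) {
    k <- 1:K
    mu <- k^2 * pi^2 / (2 * a^2) + v^2 / 2
    coefs <- (pi / a^2) * exp(-v * a * w) * k * sin(k * pi * w) / mu
    p_inf <- 1 / (1 + exp(2 * v * b))  # P(absorb at lower bound)
    vapply(t, function(tt) max(0, p_inf - sum(coefs * exp(-mu * tt))),
           numeric(1))
  }
  lower(t, v) + lower(t, -v)
}

# two-sided KS distance between a sample and a CDF function
ks_distance <- function(x, cdf_fun, ...) {
  x <- sort(x)
  n <- length(x)
  Fi <- cdf_fun(x, ...)
  max(abs(seq_len(n) / n - Fi), abs((seq_len(n) - 1) / n - Fi))
}

# single-segment timeline covering `ms` milliseconds
flat_timeline <- function(aoi, ms) {
  build_timeline(data.frame(aoi = aoi, onset = 0, offset = ms), ms)
}

# small deterministic trials table for data-model tests
toy_trials <- function() {
  addm_trials(data.frame(
    subject = rep(c("s1", "s2"), each = 4),
    trial = rep(1:4, 2),
    self = c(40, 70, 20, 60, 30, 80, 40, 90),
    other = c(70, 40, 90, 30, 60, 10, 80, 20),
    condition = rep(c("HIGH", "LOW"), 4),
    choice = c("ACCEPT", "REJECT", "ACCEPT", "MISSED",
               "REJECT", "ACCEPT", "ACCEPT", "REJECT"),
    rt = c(0.85, 1.2, 0.6, NA, 0.9, 2.5, 0.7, 3.1)
  ))
}
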