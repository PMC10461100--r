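# Shared fixtures: scenarios and hand-built recordings used across files.

# Deterministic scenario variants. `quiet` turns off every stochastic
# term so closed-form predictions hold exactly.
quiet_scenario <- function(...) {
  tci_scenario(noise_sd = 0, gain_cv = 0, repeat_gain_cv = 0,
               ssr_noise_sd = 0, blank_noise = FALSE, ...)
}

# A recording with the canonical protocol and a hand-set trace.
flat_recording <- function(level = 100, n = 100, ...) {
  recording(rep(level, n), stimulus_id = "odorant_01", ...)
}

# Kernel-predicted window amplitude (%) for activation a under a
# scenario, ignoring bleach attenuation.
predicted_amplitude <- function(scenario, a, window = c(17, 31)) {
  k <- response_kernel(scenario)
  100 * a * mean(k[window[1]:window[2]])
}

# Independent Pearson r^2 from raw sums (no call to stats::cor).
pearson_r2_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den2 <- (n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2)
  if (den2 <= 0) return(NA_real_)
  num^2 / den2
}
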