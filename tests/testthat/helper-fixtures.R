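# Shared fixture builders for the test suite. Everything is generated in
# code; no binary data.

# A fast, fully deterministic study configuration: no noise, no material
# or thickness scatter, near-instant settling after the initiation peak,
# and (optionally) vanishing blade wear so that Omega ~ 0.
noiseless_config <- function(seed = 1L, zero_wear = TRUE, ...) {
  args <- list(
    seed = seed,
    trace_noise_sd = 0,
    thickness_rel_sd = 0,
    material_scatter = FALSE,
    settle_length = 1e-7,
    wear_sdlog = 0,
    sampling_rate = 150,
    ...
  )
  if (zero_wear) {
    args$pristine_radius_mean <- 0
    args$pristine_radius_sd <- 0
    args$pristine_radius_min <- 0
    args$wear_radius_range <- c(1e-15, 1e-15)
  }
  do.call(synthetic_study_config, args)
}

# A simple plateau-with-peak first-pass trace built point by point:
# linear ramp to `peak` at `peak_x`, then exactly `plateau` afterwards.
ramp_plateau_trace <- function(peak = 40e-3, plateau = 30e-3,
                               peak_x = 0.8e-3, travel = 5e-3,
                               stage_speed = 0.3e-3, rate = 300,
                               pass_id = "first", noise_sd = 0,
                               trial_id = "fixture") {
  t <- seq(0, travel / stage_speed, by = 1 / rate)
  x <- t * stage_speed
  f <- ifelse(x <= peak_x, peak * x / peak_x, plateau)
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  force_trace(t, f, stage_speed, pass_id, trial_id)
}

# Constant-force trace (e.g. a second pass).
constant_trace <- function(level = 4e-3, travel = 5e-3,
                           stage_speed = 0.3e-3, rate = 300,
                           pass_id = "second", noise_sd = 0,
                           trial_id = "fixture") {
  t <- seq(0, travel / stage_speed, by = 1 / rate)
  f <- rep(level, length(t))
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  force_trace(t, f, stage_speed, pass_id, trial_id)
}
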