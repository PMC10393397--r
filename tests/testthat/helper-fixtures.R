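# Shared fixtures: a reduced ramp for fast unit tests (the full protocol is
# exercised in the acceptance tests) and a constructor for hand-made
# heart-rate series.

small_ramp <- function() ramp_protocol(start_C = 30, end_C = 56,
                                       rate_C_per_min = 0.5, sample_hz = 40)

default_truth <- function(...) {
  true_traits(r_tref = 40, e_act = 0.8, e_deact = 4, topt_C = 45,
              ult_C = 52, ...)
}

# Build an hr_series object directly from (temperature, rate) pairs.
make_series <- function(temp_C, hr_bpm, window_s = 60, step_s = 30) {
  n <- length(temp_C)
  stopifnot(length(hr_bpm) == n)
  structure(data.frame(time_start_s = step_s * (seq_len(n) - 1),
                       temp_mid_C = temp_C,
                       hr_bpm = hr_bpm,
                       n_beats = round(hr_bpm * window_s / 60)),
            class = c("hr_series", "data.frame"),
            window_s = window_s, step_s = step_s,
            t_end_s = step_s * (n - 1) + window_s)
}

# Noise-free trace of regular beats at a fixed rate, constant temperature.
regular_beat_trace <- function(bpm = 60, duration_s = 60, hz = 40,
                               pulse_mV = 1, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, duration_s, by = 1 / hz)
  n <- length(time)
  sig <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  beats <- seq(30 / bpm, duration_s, by = 60 / bpm)
  sd_p <- 0.0375
  for (b in beats) {
    idx <- which(abs(time - b) < 4 * sd_p)
    sig[idx] <- sig[idx] + pulse_mV * exp(-0.5 * ((time[idx] - b) / sd_p)^2)
  }
  cardiac_trace(time, sig, rep(30, n) + 1e-9 * seq_len(n), hz)
}

# A fast reduced-size cohort configuration for pipeline tests: fewer
# individuals and a quicker ramp (fewer samples per trace).
small_config <- function(n_individuals = 2) {
  run_config(n_individuals = n_individuals,
             ramp = ramp_protocol(30, 65, 0.5, 40))
}
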