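# Synthetic shore/mangrove temperature regimes: a diurnal sinusoid plus
# midday heat pulses with lognormal amplitudes, affinely calibrated so the
# series hits the preset mean and maximum exactly.

#' Environmental temperature preset
#'
#' @param name label for the regime.
#' @param mean_C target empirical mean temperature, degrees Celsius.
#' @param max_C target empirical maximum; must be `>= mean_C`.
#' @param period_h diurnal period in hours.
#' @param tidal_mod logical; modulate heat pulses on a semidiurnal (12.42 h)
#'   tidal cycle, as for tidally flushed mangrove substrata.
#' @return an object of class `env_preset`.
#' @export
environment_preset <- function(name, mean_C, max_C, period_h = 24,
                               tidal_mod = FALSE) {
  if (!is.numeric(mean_C) || !is.numeric(max_C) || max_C < mean_C)
    stop("invalid preset: need max_C >= mean_C")
  if (!is.numeric(period_h) || period_h <= 0)
    stop("invalid preset: period_h must be positive")
  structure(list(name = name, mean_C = mean_C, max_C = max_C,
                 period_h = period_h, tidal_mod = isTRUE(tidal_mod)),
            class = "env_preset")
}

#' Built-in temperature regimes
#'
#' `rocky_shore`: sun-exposed upper rocky shore (mean 31.8, max 51.3 degC).
#' `mangrove`: shaded mangrove trunk (mean 27.7, max 33.2 degC), tidally
#' modulated.  `constant_27`: degenerate flat regime at the holding
#' temperature.
#'
#' @param name one of `"rocky_shore"`, `"mangrove"`, `"constant_27"`.
#' @return an [environment_preset()].
#' @export
env_preset <- function(name = c("rocky_shore", "mangrove", "constant_27")) {
  name <- match.arg(name)
  switch(name,
    rocky_shore = environment_preset("rocky_shore", 31.8, 51.3),
    mangrove    = environment_preset("mangrove", 27.7, 33.2,
                                     tidal_mod = TRUE),
    constant_27 = environment_preset("constant_27", 27, 27))
}

#' Simulate a logged temperature series for a regime
#'
#' Generates `days` of temperatures at `step_min` intervals: a diurnal
#' sinusoid peaking in early afternoon plus half-day midday heat pulses
#' whose amplitudes are lognormal across days, with small sampling noise.
#' The assembled series is affinely rescaled so its empirical mean and
#' maximum equal the preset targets.
#'
#' @param preset an [environment_preset()].
#' @param days number of days (>= 1).
#' @param step_min logging interval in minutes; must divide a day evenly.
#' @param seed optional integer seed; the same seed reproduces the series
#'   exactly.
#' @return data frame of class `env_series` with columns `time_h`, `temp_C`.
#' @export
simulate_environment <- function(preset, days = 30, step_min = 10,
                                 seed = NULL) {
  if (!inherits(preset, "env_preset"))
    stop("invalid preset: expected an environment_preset")
  stopifnot(days >= 1)
  if ((24 * 60) %% step_min != 0)
    stop("step_min must divide a day evenly")
  with_seed(seed, {
    per_day <- (24 * 60) %/% step_min
    n <- days * per_day
    time_h <- (seq_len(n) - 1) * step_min / 60
    hod <- time_h %% 24
    day <- floor(time_h / 24) + 1
    base <- cos(2 * pi * (hod - 14) / preset$period_h)
    amp <- rlnorm(days, meanlog = 0, sdlog = 0.35)
    pulse <- exp(-0.5 * ((hod - 13.5) / 2.5)^2)
    if (preset$tidal_mod)
      pulse <- pulse * (0.7 + 0.3 * cos(2 * pi * time_h / 12.42))
    shape <- base + 2 * amp[day] * pulse + rnorm(n, 0, 0.05)
    span <- max(shape) - mean(shape)
    temp <- if (preset$max_C == preset$mean_C || span <= 0) {
      rep(preset$mean_C, n)
    } else {
      preset$mean_C + (preset$max_C - preset$mean_C) *
        (shape - mean(shape)) / span
    }
    structure(data.frame(time_h = time_h, temp_C = temp),
              class = c("env_series", "data.frame"),
              preset = preset)
  })
}

#' Summary statistics of a temperature series
#'
#' @param series an `env_series` (or any data frame with a `temp_C` column).
#' @return one-row data frame with `mean_C`, `max_C`, `min_C` and
#'   `delta_C = max_C - mean_C`, the offset between the thermal extreme and
#'   the average regime.
#' @export
summarize_environment <- function(series) {
  x <- series$temp_C
  data.frame(mean_C = mean(x), max_C = max(x), min_C = min(x),
             delta_C = max(x) - mean(x))
}
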