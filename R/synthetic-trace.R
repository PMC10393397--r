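# Generative inverse of the measurement chain: true thermal traits ->
# ramped heartbeat trace with sensor noise and a flatline above the true
# upper lethal temperature.

#' Ground-truth thermal traits for a simulated individual
#'
#' Parameterizes the generating Sharpe-Schoolfield curve, the true upper
#' lethal temperature and an optional metabolic-depression plateau (a
#' temperature-insensitive heart-rate ceiling below an onset temperature,
#' as resting intertidal gastropods show).
#'
#' @inheritParams ss_rate
#' @param th_K inactivation half-temperature in Kelvin; derived from
#'   `topt_C` when omitted.
#' @param topt_C optional optimal temperature used to derive `th_K`.
#' @param ult_C true upper lethal temperature (flatline), degrees Celsius;
#'   must exceed the optimum.
#' @param depression_cap optional heart-rate ceiling in bpm applied below
#'   `depression_onset_C`.
#' @param depression_onset_C temperature below which the cap applies.
#' @return an object of class `true_traits`.
#' @export
true_traits <- function(r_tref = 40, e_act = 0.8, e_deact = 4,
                        th_K = NULL, topt_C = 45, ult_C = 52,
                        depression_cap = NULL, depression_onset_C = 40,
                        tref_C = 30) {
  if (!(e_deact > e_act && e_act > 0))
    stop("need e_deact > e_act > 0 for a finite optimum")
  if (is.null(th_K)) th_K <- .ss_th_for_topt(topt_C, e_act, e_deact)
  p <- ss_params(r_tref, e_act, e_deact, th_K, tref_C)
  topt <- ss_topt(e_act, e_deact, th_K)
  if (ult_C <= topt)
    stop(sprintf("ult_C (%.1f) must exceed the optimum (%.1f degC)",
                 ult_C, topt))
  structure(list(params = p, topt_C = topt, ult_C = ult_C,
                 depression_cap = depression_cap,
                 depression_onset_C = depression_onset_C),
            class = "true_traits")
}

#' Heating-ramp protocol
#'
#' @param start_C,end_C ramp temperature bounds, degrees Celsius.
#' @param rate_C_per_min heating rate.
#' @param sample_hz logger sampling rate.
#' @return an object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start_C = 30, end_C = 65, rate_C_per_min = 0.25,
                          sample_hz = 40) {
  stopifnot(end_C > start_C, rate_C_per_min > 0, sample_hz > 0)
  structure(list(start_C = start_C, end_C = end_C,
                 rate_C_per_min = rate_C_per_min, sample_hz = sample_hz),
            class = "ramp_protocol")
}

# Instantaneous generating rate (bpm) at each grid temperature: SS curve,
# capped by the depression plateau below its onset, zero above the ULT.
.true_rate_grid <- function(traits, temp_C) {
  r <- .ss_rate_p(traits$params, temp_C)
  if (!is.null(traits$depression_cap)) {
    low <- temp_C < traits$depression_onset_C
    r[low] <- pmin(r[low], traits$depression_cap)
  }
  r[temp_C >= traits$ult_C] <- 0
  r
}

#' Simulate a ramped cardiac trace with known ground truth
#'
#' Beats form a quasi-regular renewal process whose instantaneous rate
#' follows the generating Sharpe-Schoolfield curve (optionally capped by a
#' depression plateau) and drops to zero above the true ULT.  Each beat is
#' a stereotyped Gaussian voltage pulse (~0.15 s wide) added to Gaussian
#' sensor noise; the temperature channel follows the ramp exactly.
#'
#' @param traits a [true_traits()] object.
#' @param ramp a [ramp_protocol()].
#' @param noise_sd sensor noise standard deviation, mV (>= 0).
#' @param seed optional integer seed.
#' @param pulse_mV pulse height, mV.
#' @param pulse_width_s nominal pulse width (~4 SD of the Gaussian bump).
#' @param interval_jitter relative SD of beat-to-beat interval jitter.
#' @param meta labels stored on the trace.
#' @return a [cardiac_trace()] carrying a `truth` attribute with the beat
#'   times, traits and ramp used.
#' @export
simulate_trace <- function(traits, ramp = ramp_protocol(), noise_sd = 0.2,
                           seed = NULL, pulse_mV = 1, pulse_width_s = 0.15,
                           interval_jitter = 0.05, meta = list()) {
  stopifnot(inherits(traits, "true_traits"), inherits(ramp, "ramp_protocol"),
            noise_sd >= 0)
  with_seed(seed, {
    hz <- ramp$sample_hz
    duration <- (ramp$end_C - ramp$start_C) / ramp$rate_C_per_min * 60
    n <- floor(duration * hz) + 1
    time <- (seq_len(n) - 1) / hz
    temp <- ramp$start_C + ramp$rate_C_per_min / 60 * time
    rate <- .true_rate_grid(traits, temp)

    # inhomogeneous renewal process: next interval = 60/rate at the current
    # beat, with multiplicative Gaussian jitter (floored at 20% of nominal)
    beats <- numeric(ceiling(duration * max(rate) / 60) + 16)
    nb <- 0L
    t_cur <- 0
    repeat {
      i <- floor(t_cur * hz) + 1
      if (i > n) break
      r <- rate[i]
      if (r <= 0) break
      gap <- (60 / r) * max(0.2, 1 + interval_jitter * rnorm(1))
      t_cur <- t_cur + gap
      if (t_cur > duration) break
      j <- floor(t_cur * hz) + 1
      if (j > n || rate[j] <= 0) break
      nb <- nb + 1L
      beats[nb] <- t_cur
    }
    beats <- beats[seq_len(nb)]

    sig <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    if (nb > 0) {
      sd_p <- pulse_width_s / 4
      half <- ceiling(3 * sd_p * hz)
      bi <- round(beats * hz) + 1
      for (o in seq.int(-half, half)) {
        idx <- bi + o
        ok <- idx >= 1 & idx <= n
        if (any(ok)) {
          dt <- time[idx[ok]] - beats[ok]
          sig[idx[ok]] <- sig[idx[ok]] +
            pulse_mV * exp(-0.5 * (dt / sd_p)^2)
        }
      }
    }
    tr <- cardiac_trace(time, sig, temp, hz, meta)
    attr(tr, "truth") <- list(beat_times = beats, traits = traits,
                              ramp = ramp, noise_sd = noise_sd,
                              pulse_mV = pulse_mV)
    tr
  })
}
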