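#' Sharpe-Schoolfield rate model (high-temperature inactivation form)
#'
#' Process-based thermal performance model combining Arrhenius activation
#' with reversible high-temperature enzyme inactivation.  The rate at body
#' temperature `T` (Kelvin) is
#' \deqn{r(T) = r_{tref} \, e^{-\frac{E}{k}(1/T - 1/T_{ref})} \Big/
#'       \left(1 + e^{\frac{E_h}{k}(1/T_h - 1/T)}\right)}
#' with `k` the Boltzmann constant (8.617333e-5 eV/K).  With
#' `e_deact > e_act > 0` the curve is positive, unimodal and has a single
#' interior maximum (the optimal temperature).
#'
#' @param temp_C body temperature(s), degrees Celsius.
#' @param r_tref rate at the reference temperature, beats per minute.
#' @param e_act activation energy E, eV; the steepness of the upslope
#'   (the "slope gradient" trait).
#' @param e_deact deactivation energy Eh, eV; must exceed `e_act`.
#' @param th_K temperature (Kelvin) at which the inactivation term halves
#'   the rate.
#' @param tref_C reference temperature, degrees Celsius.  Fixed at the ramp
#'   start (30) by default.
#' @return numeric vector of rates (bpm), same length as `temp_C`.
#' @examples
#' ss_rate(30, r_tref = 40, e_act = 0.8, e_deact = 4, th_K = 321)
#' @export
ss_rate <- function(temp_C, r_tref, e_act, e_deact, th_K, tref_C = 30) {
  t_K <- temp_C + 273.15
  tref_K <- tref_C + 273.15
  num <- r_tref * exp(-e_act / .k_eV * (1 / t_K - 1 / tref_K))
  den <- 1 + exp(e_deact / .k_eV * (1 / th_K - 1 / t_K))
  num / den
}

#' Closed-form optimal temperature of the Sharpe-Schoolfield curve
#'
#' For the high-temperature-inactivation form the interior maximum sits at
#' \deqn{T_{opt} = \frac{E_h T_h}{E_h + k T_h \ln(E_h/E - 1)}}
#' (all temperatures Kelvin).  Requires `e_deact > e_act > 0`.
#'
#' @inheritParams ss_rate
#' @return the optimal temperature in degrees Celsius.
#' @export
ss_topt <- function(e_act, e_deact, th_K) {
  stopifnot(e_act > 0, e_deact > e_act, th_K > 0)
  e_deact * th_K / (e_deact + .k_eV * th_K * log(e_deact / e_act - 1)) - 273.15
}

# Inverse of ss_topt(): the th_K that places the optimum at topt_C.
.ss_th_for_topt <- function(topt_C, e_act, e_deact) {
  stopifnot(e_act > 0, e_deact > e_act)
  topt_K <- topt_C + 273.15
  den <- e_deact - .k_eV * topt_K * log(e_deact / e_act - 1)
  stopifnot(den > 0)
  topt_K * e_deact / den
}

#' Sharpe-Schoolfield parameter set
#'
#' Light-weight validated container for one parameterization.
#'
#' @inheritParams ss_rate
#' @return an object of class `ss_params` (a named list).
#' @export
ss_params <- function(r_tref, e_act, e_deact, th_K, tref_C = 30) {
  stopifnot(is.numeric(r_tref), r_tref > 0,
            is.numeric(e_act), e_act > 0,
            is.numeric(e_deact), e_deact > e_act,
            is.numeric(th_K), th_K > 0)
  structure(list(r_tref = r_tref, e_act = e_act, e_deact = e_deact,
                 th_K = th_K, tref_C = tref_C),
            class = "ss_params")
}

# Evaluate an ss_params object on a temperature grid.
.ss_rate_p <- function(p, temp_C) {
  ss_rate(temp_C, p$r_tref, p$e_act, p$e_deact, p$th_K, p$tref_C)
}

#' @export
print.ss_params <- function(x, ...) {
  cat(sprintf(
    "Sharpe-Schoolfield parameters: r_tref=%.3g bpm, E=%.3g eV, Eh=%.3g eV, Th=%.2f K (Tref=%g degC)\n",
    x$r_tref, x$e_act, x$e_deact, x$th_K, x$tref_C))
  invisible(x)
}
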