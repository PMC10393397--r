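# Sharpe-Schoolfield fitting and thermal trait extraction.

#' Fit the Sharpe-Schoolfield model to a heart-rate series
#'
#' Multi-start nonlinear least squares (Levenberg-Marquardt).  Windows at or
#' after the flatline onset and windows with zero rate are excluded first:
#' flatlined beats are a different regime (death), not performance.  The
#' first start is a deterministic data-driven guess; the remaining
#' `n_starts - 1` are drawn from wide uniform boxes (E in [0.1, 2] eV, Eh in
#' [1, 10] eV, Th across the observed Kelvin range).  The best converged
#' start by residual sum of squares wins.
#'
#' @param series an [hr_series()].
#' @param n_starts number of initializations.
#' @param seed optional integer seed for the start draws.
#' @param tref_C reference temperature of the parameterization (fixed).
#' @param flatline optional `flatline_call`; windows from its onset on are
#'   excluded.
#' @return an object of class `ss_fit`: `params` ([ss_params()] or `NULL`),
#'   `fit_ok`, `degenerate` (E ~ 0 or Eh <= E), `rss`, `n_points`, and the
#'   fitting data in `data`.
#' @export
fit_ss <- function(series, n_starts = 20, seed = NULL, tref_C = 30,
                   flatline = NULL) {
  stopifnot(inherits(series, "hr_series"), n_starts >= 1)
  d <- as.data.frame(series)
  if (!is.null(flatline))
    d <- d[d$time_start_s < flatline$onset_time_s, , drop = FALSE]
  d <- d[d$hr_bpm > 0, , drop = FALSE]
  bad <- structure(list(params = NULL, fit_ok = FALSE, degenerate = NA,
                        rss = NA_real_, n_points = nrow(d), data = d),
                   class = "ss_fit")
  if (nrow(d) < 6) return(bad)

  t_K <- d$temp_mid_C + 273.15
  hr <- d$hr_bpm
  i_ref <- which.min(abs(d$temp_mid_C - tref_C))
  r0 <- max(hr[i_ref], 1)
  th0 <- t_K[which.max(hr)] + 2

  starts <- with_seed(seed, {
    s <- vector("list", n_starts)
    s[[1]] <- c(r_tref = r0, e_act = 0.65, e_deact = 4, th_K = th0)
    if (n_starts > 1) {
      for (i in 2:n_starts) {
        e <- runif(1, 0.1, 2)
        s[[i]] <- c(r_tref = r0 * runif(1, 0.6, 1.5),
                    e_act = e,
                    e_deact = runif(1, max(1, e + 0.5), 10),
                    th_K = runif(1, th0 - 6, max(t_K) + 6))
      }
    }
    s
  })

  lower <- c(1e-2, 1e-3, 0.05, min(t_K) - 20)
  upper <- c(1e4, 6, 15, max(t_K) + 30)
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        hr ~ ss_rate(temp_C, r_tref, e_act, e_deact, th_K, tref_C),
        data = data.frame(hr = hr, temp_C = d$temp_mid_C),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 120)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.finite(rss) && rss < best_rss) {
      best_rss <- rss
      best <- coef(fit)
    }
  }
  if (is.null(best)) return(bad)
  # degenerate when effectively rate-flat over the observed range (E ~ 0 or
  # a fitted curve with < 1% relative span) or when the unimodality
  # condition Eh > E fails
  fitted_range <- range(ss_rate(d$temp_mid_C, best[["r_tref"]],
                                best[["e_act"]], best[["e_deact"]],
                                best[["th_K"]], tref_C))
  degenerate <- best[["e_act"]] < 0.01 ||
    best[["e_deact"]] <= best[["e_act"]] ||
    (fitted_range[2] - fitted_range[1]) < 0.01 * fitted_range[2]
  params <- if (degenerate) {
    # keep the raw estimates inspectable even when flagged degenerate
    structure(list(r_tref = best[["r_tref"]], e_act = best[["e_act"]],
                   e_deact = best[["e_deact"]], th_K = best[["th_K"]],
                   tref_C = tref_C), class = "ss_params")
  } else {
    ss_params(best[["r_tref"]], best[["e_act"]], best[["e_deact"]],
              best[["th_K"]], tref_C)
  }
  structure(list(params = params, fit_ok = TRUE, degenerate = degenerate,
                 rss = best_rss, n_points = nrow(d), data = d),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  if (!x$fit_ok) {
    cat("Sharpe-Schoolfield fit: FAILED (", x$n_points, "usable windows )\n")
  } else {
    cat(sprintf("Sharpe-Schoolfield fit on %d windows, RSS = %.3g%s\n",
                x$n_points, x$rss,
                if (isTRUE(x$degenerate)) " [degenerate]" else ""))
    print(x$params)
  }
  invisible(x)
}

#' Quadratic curvature of the cTPC upslope
#'
#' Ordinary least-squares fit of `HR = c0 + c1*temp + c2*temp^2` to the
#' windows with temperatures below the optimum; the curvature statistic is
#' the second derivative `2 * c2`.
#'
#' @param series an [hr_series()].
#' @param topt_C the optimal temperature bounding the upslope.
#' @return list of class `upslope_fit` with `c0`, `c1`, `c2`,
#'   `curvature = 2 * c2` and `n_points`; curvature is `NA` with fewer than
#'   3 upslope points.
#' @export
upslope_curvature <- function(series, topt_C) {
  d <- as.data.frame(series)
  d <- d[d$temp_mid_C < topt_C, , drop = FALSE]
  if (nrow(d) < 3) {
    return(structure(list(c0 = NA_real_, c1 = NA_real_, c2 = NA_real_,
                          curvature = NA_real_, n_points = nrow(d)),
                     class = "upslope_fit"))
  }
  fit <- lm(hr_bpm ~ temp_mid_C + I(temp_mid_C^2), data = d)
  cf <- coef(fit)
  structure(list(c0 = unname(cf[1]), c1 = unname(cf[2]),
                 c2 = unname(cf[3]), curvature = 2 * unname(cf[3]),
                 n_points = nrow(d)),
            class = "upslope_fit")
}

#' Extract the five thermal traits from a fitted curve
#'
#' `Topt` is the argmax of the fitted curve on a 0.01 degC grid restricted
#' to the observed temperature range, `HRmax` the fitted rate there, the
#' slope gradient is the activation energy E, the slope curvature comes
#' from [upslope_curvature()], and the ULT from the flatline call (absent
#' when no call was made; the other traits are still returned).
#'
#' @param fit an `ss_fit` from [fit_ss()].
#' @param series the [hr_series()] used for fitting (for the curvature).
#' @param flatline optional `flatline_call`.
#' @return an object of class `cardiac_traits` (named list of the five
#'   traits plus `fit_ok` and `rss`).
#' @export
extract_traits <- function(fit, series = NULL, flatline = NULL) {
  stopifnot(inherits(fit, "ss_fit"))
  out <- list(slope_gradient_eV = NA_real_, slope_curvature = NA_real_,
              hr_max_bpm = NA_real_, t_opt_C = NA_real_,
              ult_C = if (is.null(flatline)) NA_real_ else flatline$ult_C,
              fit_ok = fit$fit_ok && !isTRUE(fit$degenerate),
              rss = fit$rss)
  if (!fit$fit_ok) return(structure(out, class = "cardiac_traits"))
  d <- fit$data
  grid <- seq(min(d$temp_mid_C), max(d$temp_mid_C), by = 0.01)
  r <- .ss_rate_p(fit$params, grid)
  i <- which.max(r)
  out$t_opt_C <- grid[i]
  out$hr_max_bpm <- r[i]
  out$slope_gradient_eV <- fit$params$e_act
  cv <- upslope_curvature(series %||% fit$data, out$t_opt_C)
  out$slope_curvature <- cv$curvature
  structure(out, class = "cardiac_traits")
}

#' @export
print.cardiac_traits <- function(x, ...) {
  cat(sprintf(paste0(
    "cardiac traits: slope gradient %.3g eV, curvature %.3g bpm/degC^2,\n",
    "  HRmax %.1f bpm, Topt %.2f degC, ULT %s degC (fit_ok=%s)\n"),
    x$slope_gradient_eV, x$slope_curvature, x$hr_max_bpm, x$t_opt_C,
    ifelse(is.na(x$ult_C), "NA", sprintf("%.2f", x$ult_C)), x$fit_ok))
  invisible(x)
}

#' @export
as.data.frame.cardiac_traits <- function(x, ...) {
  data.frame(slope_gradient_eV = x$slope_gradient_eV,
             slope_curvature = x$slope_curvature,
             hr_max_bpm = x$hr_max_bpm, t_opt_C = x$t_opt_C,
             ult_C = x$ult_C, fit_ok = x$fit_ok, rss = x$rss)
}

#' Full per-individual pipeline: trace to thermal traits
#'
#' Optional Bartlett pre-smoothing, beat detection, windowed heart-rate
#' series, flatline call, Sharpe-Schoolfield fit and trait extraction.
#'
#' @param trace a [cardiac_trace()].
#' @param smooth_window_s Bartlett pre-smoothing window, seconds; `NULL`
#'   analyses the raw trace.
#' @param min_prominence,refractory_s passed to [detect_beats()].
#' @param window_s,step_s passed to [hr_series()].
#' @param hr_floor,sustain_s passed to [detect_flatline()].
#' @param n_starts,seed passed to [fit_ss()].
#' @param tref_C reference temperature of the parameterization.
#' @return a `cardiac_traits` object with a `diagnostics` attribute holding
#'   the intermediate beats, series, flatline call and fit.
#' @export
trace_to_traits <- function(trace, smooth_window_s = 0.1,
                            min_prominence = NULL, refractory_s = 0.25,
                            window_s = 60, step_s = 30,
                            hr_floor = 5, sustain_s = 120,
                            n_starts = 20, seed = NULL, tref_C = 30) {
  tr <- if (is.null(smooth_window_s)) trace else
    bartlett_smooth(trace, smooth_window_s)
  beats <- detect_beats(tr, min_prominence = min_prominence,
                        refractory_s = refractory_s)
  series <- hr_series(beats, tr, window_s = window_s, step_s = step_s)
  fl <- detect_flatline(series, hr_floor = hr_floor, sustain_s = sustain_s)
  fit <- fit_ss(series, n_starts = n_starts, seed = seed, tref_C = tref_C,
                flatline = fl)
  traits <- extract_traits(fit, series = series, flatline = fl)
  attr(traits, "diagnostics") <- list(beats = beats, series = series,
                                      flatline = fl, fit = fit)
  traits
}
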