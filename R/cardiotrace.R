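# Trace signal processing: Bartlett smoothing, beat detection, windowed
# heart-rate series and flatline (upper-lethal-temperature) calls.

# Unit-sum triangular (Bartlett) kernel of odd length >= 3.
.bartlett_kernel <- function(len) {
  if (len < 3) stop("smoothing window shorter than 3 samples")
  if (len %% 2 == 0) len <- len + 1
  half <- (len - 1) / 2
  w <- 1 - abs(seq.int(-half, half)) / (half + 1)
  w / sum(w)
}

# Convolve with a unit-sum kernel; edge windows are renormalized over the
# in-range kernel mass so a constant input maps to itself everywhere.
.smooth_vec <- function(x, w) {
  n <- length(x)
  half <- (length(w) - 1) / 2
  y <- as.numeric(stats::filter(x, w, sides = 2))
  edge <- c(seq_len(min(half, n)), seq.int(max(n - half + 1, 1), n))
  edge <- unique(edge[edge >= 1 & edge <= n])
  for (i in edge) {
    j <- max(1, i - half):min(n, i + half)
    wi <- w[j - i + half + 1]
    y[i] <- sum(x[j] * wi) / sum(wi)
  }
  y
}

#' Triangular (Bartlett) smoothing of a cardiac trace
#'
#' Convolves the sensor signal with a unit-sum triangular kernel of the
#' requested duration.  Length is preserved; edge windows are renormalized;
#' the time and temperature channels are untouched.
#'
#' @param trace a [cardiac_trace()].
#' @param window_s kernel duration in seconds; must cover at least 3 samples
#'   and be shorter than the trace.
#' @return a smoothed `cardiac_trace`.
#' @export
bartlett_smooth <- function(trace, window_s) {
  stopifnot(inherits(trace, "cardiac_trace"), window_s > 0)
  dur <- max(trace$time_s) - min(trace$time_s)
  if (window_s >= dur) stop("smoothing window must be shorter than the trace")
  len <- round(window_s * trace$sample_hz)
  if (len < 3) stop("smoothing window shorter than 3 samples")
  w <- .bartlett_kernel(len)
  out <- trace
  out$signal_mV <- .smooth_vec(trace$signal_mV, w)
  out
}

#' Detect heartbeats in a cardiac trace
#'
#' Beats are local maxima of the baseline-detrended signal that stand at
#' least `min_prominence` above the rolling baseline, thinned so that no
#' two retained beats are closer than `refractory_s` (taller peaks win).
#' The baseline is a running median, which sparse positive pulses barely
#' perturb, and the default threshold is 4 x a robust noise scale taken
#' from the lower tail of the detrended signal (the tail pulses cannot
#' reach).
#'
#' @param trace a [cardiac_trace()].
#' @param min_prominence minimum height above the rolling baseline, mV.
#'   Defaults to 4 x the robust noise scale of the detrended signal.
#' @param refractory_s minimum separation between beats, seconds.
#' @param baseline_window_s duration of the running-median baseline used
#'   for detrending, seconds.
#' @return sorted numeric vector of beat times (seconds); empty for flat or
#'   sub-threshold traces.
#' @export
detect_beats <- function(trace, min_prominence = NULL, refractory_s = 0.25,
                         baseline_window_s = 2) {
  stopifnot(inherits(trace, "cardiac_trace"), refractory_s > 0)
  x <- trace$signal_mV
  n <- length(x)
  if (n < 3) return(numeric(0))
  base_len <- max(3, round(baseline_window_s * trace$sample_hz))
  if (base_len %% 2 == 0) base_len <- base_len + 1
  base_len <- min(base_len, if (n %% 2 == 1) n else n - 1)
  d <- x - stats::runmed(x, base_len)
  if (is.null(min_prominence)) {
    # one-sided robust sigma: median minus the 15.87% quantile equals the
    # noise SD for Gaussian noise, and positive pulses cannot deflate it
    sig <- median(d) - quantile(d, stats::pnorm(-1), names = FALSE)
    min_prominence <- 4 * sig
  }
  if (min_prominence <= 0) min_prominence <- .Machine$double.eps
  left <- c(-Inf, d[-n])
  right <- c(d[-1], -Inf)
  cand <- which(d >= min_prominence & d > left & d >= right)
  if (!length(cand)) return(numeric(0))
  # tallest-first greedy refractory thinning (keeps detection monotone in
  # the prominence threshold)
  ord <- cand[order(d[cand], decreasing = TRUE)]
  refr <- max(1L, round(refractory_s * trace$sample_hz))
  blocked <- logical(n)
  keep <- logical(length(ord))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!blocked[i]) {
      keep[ii] <- TRUE
      blocked[max(1L, i - refr):min(n, i + refr)] <- TRUE
    }
  }
  sort(trace$time_s[ord[keep]])
}

#' Windowed heart-rate series from detected beats
#'
#' Slides a window of `window_s` seconds in steps of `step_s` along the
#' trace; each window reports `hr_bpm = 60 * n_beats / window_s` and the
#' arithmetic mean body temperature of its samples.
#'
#' @param beats sorted beat times from [detect_beats()].
#' @param trace the [cardiac_trace()] the beats came from.
#' @param window_s window duration, seconds.
#' @param step_s step between window starts, seconds; `window_s >= step_s`.
#' @return a data frame of class `hr_series` with columns `time_start_s`,
#'   `temp_mid_C`, `hr_bpm`, `n_beats`; window geometry kept as attributes.
#' @export
hr_series <- function(beats, trace, window_s = 60, step_s = 30) {
  stopifnot(inherits(trace, "cardiac_trace"),
            window_s >= step_s, step_s > 0)
  t0 <- trace$time_s[1]
  tend <- trace$time_s[length(trace$time_s)]
  if (tend - t0 < window_s) stop("trace shorter than one window")
  n_win <- floor((tend - t0 - window_s) / step_s) + 1
  starts <- t0 + step_s * (seq_len(n_win) - 1)
  beats <- sort(beats)
  nb <- findInterval(starts + window_s - 1e-9, beats) -
    findInterval(starts - 1e-9, beats)
  # mean window temperature via cumulative sums over the regular grid
  hz <- trace$sample_hz
  cs <- c(0, cumsum(trace$temp_C))
  i0 <- pmax(1L, round((starts - t0) * hz) + 1L)
  i1 <- pmin(length(cs) - 1L, i0 + round(window_s * hz) - 1L)
  tmid <- (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1)
  out <- data.frame(time_start_s = starts,
                    temp_mid_C = tmid,
                    hr_bpm = 60 * nb / window_s,
                    n_beats = nb)
  structure(out, class = c("hr_series", "data.frame"),
            window_s = window_s, step_s = step_s, t_end_s = tend)
}

#' Call the flatline (upper lethal) temperature from a heart-rate series
#'
#' On a heating ramp, the ULT is the mean temperature of the first window of
#' a terminal run of windows with `hr_bpm < hr_floor` that lasts at least
#' `sustain_s` and persists to the end of the trace.  A sub-floor episode
#' followed by recovery is not a flatline.
#'
#' @param series an [hr_series()] from a heating ramp (non-decreasing
#'   window temperatures).
#' @param hr_floor heart-rate floor in bpm below which a window counts as
#'   flat.
#' @param sustain_s minimum duration of the terminal flat run, seconds.
#' @return a `flatline_call` (list with `ult_C`, `onset_time_s`,
#'   `criterion`) or `NULL` when no qualifying run exists.
#' @export
detect_flatline <- function(series, hr_floor = 5, sustain_s = 120) {
  stopifnot(inherits(series, "hr_series"), hr_floor > 0, sustain_s > 0)
  if (any(diff(series$temp_mid_C) < -1e-6))
    stop("flatline detection is defined on heating ramps only ",
         "(window temperatures must be non-decreasing)")
  below <- series$hr_bpm < hr_floor
  m <- length(below)
  if (!below[m]) return(NULL)
  run_start <- if (all(below)) 1L else max(which(!below)) + 1L
  window_s <- attr(series, "window_s")
  run_dur <- attr(series, "t_end_s") - series$time_start_s[run_start]
  if (run_dur < sustain_s) return(NULL)
  structure(list(ult_C = series$temp_mid_C[run_start],
                 onset_time_s = series$time_start_s[run_start],
                 criterion = sprintf(
                   "hr < %g bpm sustained >= %g s to trace end (window %g s)",
                   hr_floor, sustain_s, window_s)),
            class = "flatline_call")
}

#' @export
print.flatline_call <- function(x, ...) {
  cat(sprintf("flatline call: ULT = %.2f degC at t = %.0f s [%s]\n",
              x$ult_C, x$onset_time_s, x$criterion))
  invisible(x)
}

#' Write a heart-rate series as TSV
#'
#' Columns `temp_mid_C`, `hr_bpm`, `n_beats` (plus window start times).
#'
#' @param series an [hr_series()].
#' @param path output file.
#' @export
write_hr_series <- function(series, path) {
  stopifnot(inherits(series, "hr_series"))
  write.table(as.data.frame(series), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
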