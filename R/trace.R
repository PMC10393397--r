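#' Cardiac trace container
#'
#' A raw heartbeat recording for one individual: the sensor signal and the
#' synchronously logged body temperature on a common, strictly increasing
#' time axis.
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param signal_mV sensor signal in millivolts, same length as `time_s`.
#' @param temp_C body temperature in degrees Celsius, same length.
#' @param sample_hz nominal sampling rate in Hz.
#' @param meta optional named list of labels (individual, species, habitat).
#' @return an object of class `cardiac_trace`.
#' @export
cardiac_trace <- function(time_s, signal_mV, temp_C, sample_hz, meta = list()) {
  stopifnot(is.numeric(time_s), is.numeric(signal_mV), is.numeric(temp_C))
  n <- length(time_s)
  if (length(signal_mV) != n || length(temp_C) != n)
    stop("time, signal and temperature channels must have equal length")
  if (n >= 2 && any(diff(time_s) <= 0))
    stop("time must be strictly increasing")
  if (!is.numeric(sample_hz) || sample_hz <= 0)
    stop("sample_hz must be positive")
  structure(list(time_s = as.numeric(time_s),
                 signal_mV = as.numeric(signal_mV),
                 temp_C = as.numeric(temp_C),
                 sample_hz = sample_hz,
                 meta = meta),
            class = "cardiac_trace")
}

#' @export
print.cardiac_trace <- function(x, ...) {
  cat(sprintf("cardiac_trace: %d samples at %g Hz, %.1f s, temp %.1f-%.1f degC\n",
              length(x$time_s), x$sample_hz,
              max(x$time_s) - min(x$time_s),
              min(x$temp_C), max(x$temp_C)))
  if (length(x$meta)) {
    lab <- paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", ")
    cat(" ", lab, "\n")
  }
  invisible(x)
}

#' Read / write a cardiac trace as CSV
#'
#' Column layout is `time_s,signal_mV,temp_C`.
#'
#' @param path file path.
#' @param sample_hz sampling rate; inferred from the median time step when
#'   omitted.
#' @param meta passed to [cardiac_trace()].
#' @return `read_trace()` returns a `cardiac_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, sample_hz = NULL, meta = list()) {
  d <- read.csv(path)
  need <- c("time_s", "signal_mV", "temp_C")
  if (!all(need %in% names(d)))
    stop("trace file must have columns ", paste(need, collapse = ","))
  if (is.null(sample_hz))
    sample_hz <- 1 / stats::median(diff(d$time_s))
  cardiac_trace(d$time_s, d$signal_mV, d$temp_C, sample_hz, meta)
}

#' @rdname read_trace
#' @param trace a `cardiac_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cardiac_trace"))
  d <- data.frame(time_s = trace$time_s,
                  signal_mV = trace$signal_mV,
                  temp_C = trace$temp_C)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
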