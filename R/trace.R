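#' Construct a SensorTrace
#'
#' A `SensorTrace` is one device's uniformly sampled multichannel time
#' series: a strictly increasing time vector (seconds), a data frame of
#' named channels, per-channel units, and a logical missing-sample mask
#' (`TRUE` where the sample is missing; missing samples are `NA` in every
#' channel).
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing
#'   and nominally uniform.
#' @param channels data frame (or named list) of numeric signal vectors, all
#'   the same length as `time`. Accelerometer channels are in m/s^2,
#'   gyroscope channels in deg/s, insole pressures in normalized units.
#' @param units named character vector giving the unit of every channel.
#' @param device_id,body_location free-text labels identifying the device
#'   and where it was worn.
#' @param missing_mask logical vector marking missing samples; defaults to
#'   rows with any `NA`.
#'
#' @return an object of class `SensorTrace`.
#' @export
sensor_trace <- function(time, channels, units, device_id = "unknown",
                         body_location = "unknown", missing_mask = NULL) {
  channels <- as.data.frame(channels)
  stopifnot(is.numeric(time), nrow(channels) == length(time))
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("non-monotonic time", call. = FALSE)
  }
  if (is.null(missing_mask)) {
    missing_mask <- rowSums(is.na(channels)) > 0
  }
  stopifnot(length(missing_mask) == length(time))
  missing <- setdiff(names(channels), names(units))
  if (length(missing) > 0) {
    stop("missing unit declaration for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), channels = channels,
         units = units[names(channels)], device_id = device_id,
         body_location = body_location,
         missing_mask = as.logical(missing_mask)),
    class = "SensorTrace")
}

#' @export
print.SensorTrace <- function(x, ...) {
  cat(sprintf("<SensorTrace> %s @ %s\n", x$device_id, x$body_location))
  cat(sprintf("  %d samples, %.2f-%.2f s (~%.1f Hz), %d missing\n",
              length(x$time), min(x$time), max(x$time),
              trace_sample_rate(x), sum(x$missing_mask)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Nominal sample rate of a trace
#'
#' Estimated as the reciprocal of the median sample interval.
#'
#' @param trace a [sensor_trace()].
#' @return sample rate in Hz.
#' @export
trace_sample_rate <- function(trace) {
  if (length(trace$time) < 2) return(NA_real_)
  1 / stats::median(diff(trace$time))
}

#' Extract one channel of a trace
#'
#' @param trace a [sensor_trace()].
#' @param channel channel name.
#' @return numeric vector (missing samples are `NA`).
#' @export
trace_channel <- function(trace, channel) {
  if (!channel %in% names(trace$channels)) {
    stop("missing channel: ", channel, call. = FALSE)
  }
  trace$channels[[channel]]
}
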