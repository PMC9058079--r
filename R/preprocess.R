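#' Detect the leg-slap synchronization event
#'
#' Both sensor systems record a deliberate leg-slap at the start of every
#' trial; its high-magnitude medio-lateral (ML) acceleration transient is
#' used to put the two systems' clocks on a common origin. The slap is
#' located as the largest absolute ML-acceleration peak exceeding a
#' threshold inside a search window. When several samples exceed the
#' threshold, the global maximum wins: the slap is by protocol the dominant
#' transient of the window.
#'
#' @param x either a numeric ML-acceleration vector or a [sensor_trace()]
#'   (in which case `channel` is used and times come from the trace clock).
#' @param sample_rate sampling rate in Hz (ignored for traces).
#' @param threshold absolute acceleration threshold; default is 10x the
#'   median absolute deviation of the window's signal, a scale-free rule
#'   robust to the walking content of the trace.
#' @param search_window_s length-2 numeric window (s, trace clock) to search
#'   in; default is the whole trace.
#' @param channel channel name holding ML acceleration (trace input only).
#' @return slap time in seconds on the input's clock.
#' @export
detect_slap <- function(x, sample_rate = NULL, threshold = NULL,
                        search_window_s = NULL, channel = "accel_y") {
  if (inherits(x, "SensorTrace")) {
    tt <- x$time
    sig <- trace_channel(x, channel)
  } else {
    stopifnot(is.numeric(x), !is.null(sample_rate))
    tt <- (seq_along(x) - 1) / sample_rate
    sig <- x
  }
  keep <- !is.na(sig)
  if (!is.null(search_window_s)) {
    stopifnot(length(search_window_s) == 2)
    keep <- keep & tt >= search_window_s[1] & tt <= search_window_s[2]
  }
  if (!any(keep)) stop("sync not found: empty search window", call. = FALSE)
  a <- abs(sig[keep])
  if (is.null(threshold)) {
    threshold <- 10 * stats::mad(sig[keep], na.rm = TRUE)
  }
  stopifnot(threshold > 0)
  if (max(a) <= threshold) {
    stop("sync not found: no ML-acceleration peak above threshold",
         call. = FALSE)
  }
  tt[keep][which.max(a)]
}

#' Synchronize two traces via their slap times
#'
#' Shifts `trace_b`'s timestamps by `slap_a - slap_b` so both traces share
#' the clock of `trace_a`. Sample values are never resampled; only the time
#' vector moves.
#'
#' @param trace_a,trace_b [sensor_trace()] objects.
#' @param slap_a,slap_b slap event times on each trace's own clock (s).
#' @param crop if `TRUE`, both traces are cropped to their common time span
#'   after the shift.
#' @return list with elements `a`, `b` (synchronized traces) and
#'   `offset_s` (the shift applied to `trace_b`).
#' @export
synchronize <- function(trace_a, trace_b, slap_a, slap_b, crop = FALSE) {
  stopifnot(inherits(trace_a, "SensorTrace"), inherits(trace_b, "SensorTrace"),
            is.finite(slap_a), is.finite(slap_b))
  offset <- slap_a - slap_b
  # shifts accumulate against the original clock so that applying the
  # negative offset restores the original timestamps bit-for-bit
  base <- attr(trace_b, "sync_base")
  if (is.null(base)) base <- list(time = trace_b$time, offset = 0)
  base$offset <- base$offset + offset
  trace_b$time <- if (base$offset == 0) base$time else base$time + base$offset
  attr(trace_b, "sync_base") <- base
  if (max(trace_b$time) < min(trace_a$time) ||
      min(trace_b$time) > max(trace_a$time)) {
    stop("traces do not overlap after synchronization", call. = FALSE)
  }
  if (crop) {
    lo <- max(min(trace_a$time), min(trace_b$time))
    hi <- min(max(trace_a$time), max(trace_b$time))
    crop1 <- function(tr) {
      i <- tr$time >= lo & tr$time <= hi
      tr$time <- tr$time[i]
      tr$channels <- tr$channels[i, , drop = FALSE]
      tr$missing_mask <- tr$missing_mask[i]
      attr(tr, "sync_base") <- NULL
      tr
    }
    trace_a <- crop1(trace_a); trace_b <- crop1(trace_b)
  }
  list(a = trace_a, b = trace_b, offset_s = offset)
}

# Modified-Akima (makima) interpolation: piecewise cubic Hermite with
# endpoint slopes chosen as a weighted mean of neighbouring secant slopes,
# weights w1 = |d[i+1] - d[i]| + |d[i+1] + d[i]|/2 (and symmetrically w2),
# which keeps the interpolant shape-preserving and free of the overshoot of
# an unmodified cubic spline. Requires >= 2 support points; with exactly 2
# it degenerates to the connecting line.
makima_interp <- function(x, y, xi) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  if (n == 2) {
    return(y[1] + (y[2] - y[1]) * (xi - x[1]) / (x[2] - x[1]))
  }
  h <- diff(x)
  delta <- diff(y) / h
  # extend secant slopes by quadratic extrapolation at both ends
  d_ext <- c(3 * delta[1] - 2 * delta[2],
             2 * delta[1] - delta[2],
             delta,
             2 * delta[n - 1] - delta[n - 2],
             3 * delta[n - 1] - 2 * delta[n - 2])
  # d_ext index i+2 corresponds to delta[i]
  slopes <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- d_ext[i]; dm1 <- d_ext[i + 1]
    dp0 <- d_ext[i + 2]; dp1 <- d_ext[i + 3]
    w1 <- abs(dp1 - dp0) + abs(dp1 + dp0) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    slopes[i] <- if (w1 + w2 == 0) (dm1 + dp0) / 2 else
      (w1 * dm1 + w2 * dp0) / (w1 + w2)
  }
  # Hermite evaluation
  k <- pmin(pmax(findInterval(xi, x), 1L), n - 1L)
  s <- (xi - x[k]) / h[k]
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[k] + h10 * h[k] * slopes[k] + h01 * y[k + 1] +
    h11 * h[k] * slopes[k + 1]
}

#' Fill short gaps of missing samples
#'
#' Missing spans no longer than `max_gap_s` are reconstructed channel by
#' channel with modified Akima cubic Hermite interpolation, a
#' shape-preserving piecewise cubic that will not overshoot between support
#' points. Longer gaps, and gaps touching a trace boundary (no
#' extrapolation), are left missing and reported. Observed samples are never
#' modified.
#'
#' @param trace a [sensor_trace()].
#' @param max_gap_s longest gap that may be filled (s). Interpolating across
#'   longer spans would fabricate gait structure, so the default stays well
#'   below a stride period.
#' @return the trace with fillable gaps interpolated, its mask updated, and
#'   an attribute `unfilled` (data frame of start/end times of gaps left
#'   missing).
#' @export
fill_gaps <- function(trace, max_gap_s = 0.2) {
  stopifnot(inherits(trace, "SensorTrace"))
  m <- trace$missing_mask
  if (!any(m)) {
    attr(trace, "unfilled") <- data.frame(start_s = numeric(0),
                                          end_s = numeric(0))
    return(trace)
  }
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gaps <- data.frame(start = starts[r$values], end = ends[r$values])
  n <- length(m)
  unfilled <- list()
  for (gi in seq_len(nrow(gaps))) {
    i0 <- gaps$start[gi]; i1 <- gaps$end[gi]
    dur <- trace$time[i1] - trace$time[i0] + 1 / trace_sample_rate(trace)
    boundary <- i0 == 1 || i1 == n
    if (boundary || dur > max_gap_s) {
      if (boundary) {
        warning("gap at trace boundary left missing (no extrapolation)",
                call. = FALSE)
      }
      unfilled[[length(unfilled) + 1]] <-
        data.frame(start_s = trace$time[i0], end_s = trace$time[i1])
      next
    }
    idx <- i0:i1
    # local support: makima needs only a few points either side of the gap
    left <- which(!m[seq_len(i0 - 1)])
    left <- utils::tail(left, 8)
    right <- which(!m[(i1 + 1):n]) + i1
    right <- utils::head(right, 8)
    sup <- c(left, right)
    for (ch in names(trace$channels)) {
      y <- trace$channels[[ch]]
      ok <- sup[!is.na(y[sup])]
      if (length(ok) < 2) next
      trace$channels[[ch]][idx] <-
        makima_interp(trace$time[ok], y[ok], trace$time[idx])
    }
    trace$missing_mask[idx] <- FALSE
  }
  attr(trace, "unfilled") <- if (length(unfilled))
    do.call(rbind, unfilled) else
      data.frame(start_s = numeric(0), end_s = numeric(0))
  trace
}
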