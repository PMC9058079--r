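#' Zero-phase Butterworth smoothing of angular velocity
#'
#' Fourth-order Butterworth low-pass at 12 Hz, applied forward and backward
#' (`signal::filtfilt`) so that event timestamps are not lagged by the
#' filter's phase response. The effective magnitude response is the
#' single-pass response squared.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate in Hz; must exceed 24 Hz so the 12 Hz
#'   corner is below Nyquist.
#' @param cutoff_hz corner frequency (Hz).
#' @param order filter order (per pass).
#' @return smoothed signal, same length as `x`.
#' @export
lowpass <- function(x, sample_rate, cutoff_hz = 12, order = 4) {
  stopifnot(sample_rate > 2 * cutoff_hz)
  if (anyNA(x)) stop("lowpass input contains NA; fill gaps first",
                     call. = FALSE)
  warmup <- 3 * (2 * order + 1)
  if (length(x) <= warmup) {
    stop("signal shorter than filter warm-up length", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  filtfilt_sym(bf$b, bf$a, x)
}

# Forward-backward filtering with odd-reflection end padding and
# held-at-first-value initial conditions (valid for unit-DC-gain filters),
# suppressing the start/end transients of naive filtfilt.
filtfilt_sym <- function(b, a, x) {
  n <- length(x)
  pad <- max(length(a), length(b)) - 1
  nfact <- 3 * pad
  stopifnot(n > nfact)
  ext <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[n] - x[(n - 1):(n - nfact)])
  run <- function(v) {
    as.numeric(signal::filter(b, a, v, init.x = rep(v[1], pad),
                              init.y = rep(v[1], pad)))
  }
  y <- rev(run(rev(run(ext))))
  y[(nfact + 1):(nfact + n)]
}

#' Detect mid-swing peaks in smoothed sagittal angular velocity
#'
#' Mid-swing shows as the dominant positive peak of shank angular velocity
#' in each stride. Peaks are local maxima above a per-trial adaptive
#' threshold (0.4 x the 95th percentile of the positive part of the signal,
#' a scale-free stand-in for trial-specific thresholding), kept greedily by
#' descending amplitude under a minimum separation of 0.4 s (a physiologic
#' cadence bound that suppresses double peaks).
#'
#' @param smoothed signal from [lowpass()].
#' @param sample_rate Hz.
#' @param min_separation_s minimum distance between retained peaks (s).
#' @param threshold absolute threshold; default adaptive as above.
#' @return strictly increasing 0-based sample indices (possibly empty).
#' @export
detect_midswing <- function(smoothed, sample_rate, min_separation_s = 0.4,
                            threshold = NULL) {
  if (is.null(threshold)) {
    pos <- smoothed[smoothed > 0]
    if (length(pos) == 0) return(integer(0))
    threshold <- 0.4 * stats::quantile(pos, 0.95, names = FALSE)
  }
  d <- diff(smoothed)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L  # local maxima (1-based)
  cand <- cand[smoothed[cand] > threshold]
  if (length(cand) == 0) return(integer(0))
  min_sep <- round(min_separation_s * sample_rate)
  keep <- logical(length(smoothed))
  taken <- integer(0)
  for (i in cand[order(smoothed[cand], decreasing = TRUE)]) {
    if (length(taken) == 0 || all(abs(taken - i) >= min_sep)) {
      taken <- c(taken, i)
    }
  }
  sort(taken) - 1L
}

#' Detect toe-off valleys preceding each mid-swing
#'
#' Toe-off is the lowest valley right before the mid-swing peak. For each
#' mid-swing the minimum is searched from the later of (previous mid-swing,
#' mid-swing - `max_lookback_s`) up to (but excluding) the mid-swing.
#' Strides whose search window is empty (mid-swing at the trace start) are
#' dropped.
#'
#' @param smoothed signal from [lowpass()].
#' @param midswing_idx 0-based indices from [detect_midswing()].
#' @param sample_rate Hz.
#' @param max_lookback_s cap on the backward search (s), bounding the
#'   "previous valley" search in pathological signals.
#' @return integer vector aligned with `midswing_idx`; `NA` where the
#'   stride was dropped.
#' @export
detect_toeoff <- function(smoothed, midswing_idx, sample_rate,
                          max_lookback_s = 0.8) {
  lookback <- round(max_lookback_s * sample_rate)
  out <- rep(NA_integer_, length(midswing_idx))
  for (k in seq_along(midswing_idx)) {
    ms <- midswing_idx[k] + 1L                     # 1-based
    lo <- max(1L, ms - lookback)
    if (k > 1 && !is.na(midswing_idx[k - 1])) {
      lo <- max(lo, midswing_idx[k - 1] + 2L)      # strictly after prev peak
    }
    hi <- ms - 1L
    if (lo > hi) next                              # dropped: window empty
    w <- smoothed[lo:hi]
    out[k] <- lo + which.min(w) - 1L - 1L          # back to 0-based
  }
  out
}

#' Detect heel-strike zero-crossings after each mid-swing
#'
#' Heel strike is taken as the first sample at or after the mid-swing peak
#' where the smoothed angular velocity crosses from positive to <= 0.
#' Strides with no crossing before the next mid-swing (or trace end) are
#' dropped.
#'
#' @param smoothed signal from [lowpass()].
#' @param midswing_idx 0-based indices from [detect_midswing()].
#' @return integer vector aligned with `midswing_idx`; `NA` where dropped.
#' @export
detect_heelstrike <- function(smoothed, midswing_idx) {
  n <- length(smoothed)
  out <- rep(NA_integer_, length(midswing_idx))
  for (k in seq_along(midswing_idx)) {
    ms <- midswing_idx[k] + 1L
    hi <- if (k < length(midswing_idx)) midswing_idx[k + 1] else n - 1L
    i <- ms
    while (i <= hi + 1L && i <= n && smoothed[i] > 0) i <- i + 1L
    if (i <= n && i <= hi + 1L && smoothed[i] <= 0) out[k] <- i - 1L
  }
  out
}

#' Detect the full gait-event set of one foot
#'
#' Runs [lowpass()], [detect_midswing()], [detect_toeoff()] and
#' [detect_heelstrike()] and assembles complete strides, discarding any
#' stride missing an event and asserting the within-stride ordering
#' toe-off < mid-swing < heel-strike.
#'
#' @param x sagittal-plane angular velocity (deg/s), mid-swing positive.
#' @param sample_rate Hz.
#' @param ... passed to [detect_midswing()].
#' @return a `GaitEvents` data frame with 0-based columns `toeoff`,
#'   `midswing`, `heelstrike`; attribute `n_dropped` counts incomplete
#'   strides.
#' @export
detect_gait_events <- function(x, sample_rate, ...) {
  sm <- lowpass(x, sample_rate)
  ms <- detect_midswing(sm, sample_rate, ...)
  to <- detect_toeoff(sm, ms, sample_rate)
  hs <- detect_heelstrike(sm, ms)
  ok <- !is.na(to) & !is.na(hs)
  ev <- data.frame(toeoff = to[ok], midswing = ms[ok], heelstrike = hs[ok])
  stopifnot(all(ev$toeoff < ev$midswing), all(ev$midswing < ev$heelstrike))
  attr(ev, "n_dropped") <- sum(!ok)
  ev
}

#' Split bilateral strides into walking segments
#'
#' Walking segments (WS) are stretches of continuous walking between
#' experimenter-imposed turns. The mid-swing times of both feet are merged
#' and split wherever consecutive mid-swings are separated by at least
#' `gap_s` (turns take >= 2 s). Segments are numbered WS1, WS2, ... in
#' order; segments with fewer than `min_strides` bilateral strides are
#' discarded (first/last steps around a turn are too variable for a
#' meaningful regression).
#'
#' @param events_left,events_right `GaitEvents` data frames from
#'   [detect_gait_events()], on a common clock.
#' @param sample_rate Hz of the underlying traces.
#' @param gap_s minimum stride-time gap that separates segments (s).
#' @param min_strides minimum bilateral stride count of a kept segment.
#' @return a `WalkingSegment` data frame with columns `ws` (1-based index),
#'   `start_idx`, `end_idx` (0-based, half-open), `start_s`, `end_s`,
#'   `n_strides`; attribute `strides` holds per-foot stride membership
#'   (list of logical vectors per segment), attribute `n_discarded` the
#'   number of too-short segments dropped.
#' @export
segment_walking <- function(events_left, events_right, sample_rate,
                            gap_s = 2, min_strides = 3) {
  ms <- c(events_left$midswing, events_right$midswing)
  foot <- rep(c("left", "right"), c(nrow(events_left), nrow(events_right)))
  row <- c(seq_len(nrow(events_left)), seq_len(nrow(events_right)))
  if (length(ms) == 0) {
    out <- data.frame(ws = integer(0), start_idx = integer(0),
                      end_idx = integer(0), start_s = numeric(0),
                      end_s = numeric(0), n_strides = integer(0))
    attr(out, "strides") <- list()
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  o <- order(ms)
  ms <- ms[o]; foot <- foot[o]; row <- row[o]
  gap_samples <- gap_s * sample_rate
  brk <- which(diff(ms) >= gap_samples)
  grp <- cumsum(c(0L, seq_along(ms)[-1] %in% (brk + 1L)))
  segs <- list(); strides <- list(); discarded <- 0L
  for (gi in unique(grp)) {
    sel <- grp == gi
    if (sum(sel) < min_strides) { discarded <- discarded + 1L; next }
    evs <- list(left = events_left[row[sel][foot[sel] == "left"], ,
                                   drop = FALSE],
                right = events_right[row[sel][foot[sel] == "right"], ,
                                     drop = FALSE])
    all_idx <- unlist(lapply(evs, function(e) unlist(e)), use.names = FALSE)
    k <- length(segs) + 1L
    segs[[k]] <- data.frame(ws = k,
                            start_idx = min(all_idx),
                            end_idx = max(all_idx) + 1L,
                            n_strides = sum(sel))
    strides[[k]] <- evs
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(ws = integer(0), start_idx = integer(0),
               end_idx = integer(0), n_strides = integer(0))
  out$start_s <- out$start_idx / sample_rate
  out$end_s <- out$end_idx / sample_rate
  out <- out[, c("ws", "start_idx", "end_idx", "start_s", "end_s",
                 "n_strides")]
  attr(out, "strides") <- strides
  attr(out, "n_discarded") <- discarded
  out
}
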