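#' Insole sensor layout
#'
#' The insoles carry 16 pressure sensors, modelled as a 4 x 4 grid of cell
#' centers spanning the normalized insole plane (both axes -0.5..0.5). In
#' device coordinates x is posterior-to-anterior positive; the y axes of
#' the two insoles are mirror images of each other, so [step_cop()] flips
#' the right foot's lateral axis into a common anatomical frame
#' (lateral-to-medial positive on both feet).
#'
#' @return data frame with columns `sensor` (`p01`..`p16`), `x`, `y`.
#' @export
insole_layout <- function() .insole_grid()

#' Centre of pressure of a single pressure frame
#'
#' Standard CoP definition: the pressure-weighted centroid of the sensor
#' positions.
#'
#' @param pressures numeric vector of 16 non-negative pressures.
#' @param layout sensor positions, default [insole_layout()].
#' @return list `cop_x`, `cop_y`, `total_force`; the CoP components are
#'   `NA` for an all-zero frame (swing phase, no contact).
#' @export
sample_cop <- function(pressures, layout = insole_layout()) {
  stopifnot(length(pressures) == nrow(layout))
  if (any(pressures < 0, na.rm = TRUE)) {
    stop("negative pressure", call. = FALSE)
  }
  total <- sum(pressures)
  if (!is.finite(total) || total <= 0) {
    return(list(cop_x = NA_real_, cop_y = NA_real_, total_force = 0))
  }
  list(cop_x = sum(pressures * layout$x) / total,
       cop_y = sum(pressures * layout$y) / total,
       total_force = total)
}

# Vectorized per-sample CoP over an insole trace: returns data frame
# cop_x, cop_y (device frame), force for every sample.
.trace_cop <- function(insole, layout = insole_layout()) {
  press <- as.matrix(insole$channels[, layout$sensor, drop = FALSE])
  force <- rowSums(press)
  with_contact <- is.finite(force) & force > 0
  cop_x <- cop_y <- rep(NA_real_, nrow(press))
  cop_x[with_contact] <- (press[with_contact, , drop = FALSE] %*%
                            layout$x) / force[with_contact]
  cop_y[with_contact] <- (press[with_contact, , drop = FALSE] %*%
                            layout$y) / force[with_contact]
  data.frame(cop_x = cop_x, cop_y = cop_y, force = force)
}

#' Stance-phase CoP average of one step
#'
#' A step's stance phase runs from a foot's heel strike to that same foot's
#' next toe-off. Within the stance window the per-sample CoP is averaged
#' weighted by total force, using only samples whose total force exceeds a
#' contact threshold. The right foot's lateral axis is mirrored so that
#' positive is medial on both feet (anatomical frame).
#'
#' @param insole insole [sensor_trace()] with channels `p01`..`p16`.
#' @param stance_idx 0-based half-open sample range `c(start, end)` of the
#'   stance window on the insole trace.
#' @param foot `"left"` or `"right"`.
#' @param contact_threshold minimum total force; default 5% of the trace's
#'   95th-percentile total force.
#' @param trace_cop optional precomputed [.trace_cop()] table (internal
#'   speed-up when iterating over many steps).
#' @return list `cop_lm`, `cop_pa` (anatomical frame), `n_samples`; `NA`
#'   measures when no loaded samples fall in the window (step skipped).
#' @export
step_cop <- function(insole, stance_idx, foot = c("left", "right"),
                     contact_threshold = NULL, trace_cop = NULL) {
  foot <- match.arg(foot)
  if (is.null(trace_cop)) trace_cop <- .trace_cop(insole)
  if (is.null(contact_threshold)) {
    contact_threshold <- 0.05 *
      stats::quantile(trace_cop$force, 0.95, na.rm = TRUE, names = FALSE)
  }
  i <- seq(stance_idx[1] + 1L, stance_idx[2])
  w <- trace_cop[i, ]
  ok <- is.finite(w$force) & w$force > contact_threshold & !is.na(w$cop_x)
  if (!any(ok)) {
    return(list(cop_lm = NA_real_, cop_pa = NA_real_, n_samples = 0L))
  }
  f <- w$force[ok]
  lm_dev <- sum(w$cop_y[ok] * f) / sum(f)
  pa <- sum(w$cop_x[ok] * f) / sum(f)
  list(cop_lm = if (foot == "right") -lm_dev else lm_dev,
       cop_pa = pa, n_samples = sum(ok))
}

#' Per-foot walking-segment CoP summary
#'
#' Step CoP values are averaged unweighted across the steps of a walking
#' segment (two-stage averaging: force-weighted within a step, plain mean
#' across steps).
#'
#' @param insole insole [sensor_trace()].
#' @param events `GaitEvents` for this foot on the insole trace's index
#'   base (from [detect_gait_events()] on the insole's embedded gyro).
#' @param segment one row of a [segment_walking()] result.
#' @param foot `"left"` or `"right"`.
#' @param ... passed to [step_cop()].
#' @return list `cop_lm`, `cop_pa`, `sd_lm`, `sd_pa`, `n_steps`; all-`NA`
#'   measures when the segment holds no valid step for this foot. A single
#'   step yields sd 0 by convention.
#' @export
ws_cop <- function(insole, events, segment, foot, ...) {
  tc <- .trace_cop(insole)
  # steps inside the segment: heel strike -> next same-foot toe-off
  in_seg <- events$midswing >= segment$start_idx &
    events$midswing < segment$end_idx
  ev <- events[in_seg, , drop = FALSE]
  vals_lm <- c(); vals_pa <- c()
  if (nrow(ev) >= 2) {
    for (k in seq_len(nrow(ev) - 1)) {
      sc <- step_cop(insole, c(ev$heelstrike[k], ev$toeoff[k + 1]),
                     foot = foot, trace_cop = tc, ...)
      if (sc$n_samples > 0) {
        vals_lm <- c(vals_lm, sc$cop_lm)
        vals_pa <- c(vals_pa, sc$cop_pa)
      }
    }
  }
  if (length(vals_lm) == 0) {
    return(list(cop_lm = NA_real_, cop_pa = NA_real_, sd_lm = NA_real_,
                sd_pa = NA_real_, n_steps = 0L))
  }
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  list(cop_lm = mean(vals_lm), cop_pa = mean(vals_pa),
       sd_lm = sd0(vals_lm), sd_pa = sd0(vals_pa),
       n_steps = length(vals_lm))
}

#' Left-right CoP symmetry
#'
#' The lateral-medial symmetry statistic is the left foot's mean lateral
#' CoP minus the right foot's, both in the anatomical frame. A
#' disequilibrium to the left gives a negative value, to the right a
#' positive value.
#'
#' @param left_mean,right_mean per-foot mean lateral CoP for one walking
#'   segment.
#' @return left minus right; `NA` if either side is missing (the trial is
#'   then excluded from CoP analyses).
#' @export
cop_sym <- function(left_mean, right_mean) {
  if (is.na(left_mean) || is.na(right_mean)) return(NA_real_)
  left_mean - right_mean
}
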