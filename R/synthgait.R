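#' Simulation configuration for synthetic walking trials
#'
#' Bundles every tunable of the synthetic trial generator. Defaults emulate
#' the measurement setup the pipeline targets: 100 Hz chest/ankle IMUs and
#' 16-sensor pressure insoles, 2-minute walks split into walking segments
#' (WS) by experimenter-imposed turns of at least 2 s, a leg-slap
#' synchronization impulse before walking, slow heading drift plus
#' step-locked upper-body twist oscillation in the chest yaw, and
#' stance-phase heel-to-toe plantar loading with a controllable lateral
#' centre-of-pressure offset.
#'
#' @param sample_rate_hz sampling rate of every simulated device (Hz).
#' @param cadence_hz stride rate per foot (strides/s).
#' @param walk_duration_s total walking time across all segments (s).
#' @param n_segments number of walking segments (>= 1).
#' @param turn_gap_s stride-free gap between segments while the subject is
#'   turned; must be >= 2 s so segments are separable.
#' @param drift_deg_per_s heading drift rate in deg/s; positive = leftward
#'   chest rotation. `NULL` means "use the condition default" (see
#'   [condition_params()]).
#' @param drift_decay_tau_s exponential decay time constant of the drift
#'   rate across the walk (s); `Inf` (default) disables decay.
#' @param yaw_osc_amp_deg,yaw_osc_freq_hz amplitude (deg) and frequency (Hz)
#'   of the upper-body twist oscillation superimposed on the yaw.
#' @param cop_offset lateral centre-of-pressure asymmetry between the feet
#'   in insole-normalized units (the injected `cop_sym`; insole coordinates
#'   span -0.5..0.5). Negative = weight shifted leftward. `NULL` means
#'   condition default.
#' @param noise_sd named list of per-channel-group noise standard
#'   deviations: `gyro` (ankle/insole gyro, deg/s), `chest_gyro` (deg/s),
#'   `accel` (m/s^2), `pressure` (normalized units).
#' @param slap_time_s time of the leg-slap synchronization impulse (s).
#' @param lead_in_s still period before the first segment starts (s).
#' @param insole_clock_offset_s constant clock offset added to the insole
#'   system's timestamps, to be recovered by synchronization.
#' @param missing_gaps optional list of `c(start_s, length_s)` spans marked
#'   missing (NA) in every trace.
#' @param seed integer RNG seed; required, the trial is a pure function of
#'   (config, condition).
#'
#' @return an object of class `SimConfig` (a validated list).
#' @export
sim_config <- function(sample_rate_hz = 100, cadence_hz = 0.9,
                       walk_duration_s = 120, n_segments = 5,
                       turn_gap_s = 3, drift_deg_per_s = NULL,
                       drift_decay_tau_s = Inf, yaw_osc_amp_deg = 10,
                       yaw_osc_freq_hz = 0.9, cop_offset = NULL,
                       noise_sd = list(gyro = 5, chest_gyro = 0.5,
                                       accel = 0.2, pressure = 0.005),
                       slap_time_s = 2.5, lead_in_s = 5,
                       insole_clock_offset_s = 0, missing_gaps = NULL,
                       seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(sample_rate_hz > 0, cadence_hz > 0, walk_duration_s > 0,
            n_segments >= 1, drift_decay_tau_s > 0)
  if (turn_gap_s < 2) {
    stop("turn_gap_s must be >= 2 s (shorter gaps are not turns)",
         call. = FALSE)
  }
  if (yaw_osc_freq_hz >= sample_rate_hz / 2) {
    stop("yaw_osc_freq_hz violates the Nyquist limit", call. = FALSE)
  }
  defaults <- list(gyro = 5, chest_gyro = 0.5, accel = 0.2, pressure = 0.005)
  noise_sd <- utils::modifyList(defaults, as.list(noise_sd))
  structure(
    list(sample_rate_hz = sample_rate_hz, cadence_hz = cadence_hz,
         walk_duration_s = walk_duration_s, n_segments = as.integer(n_segments),
         turn_gap_s = turn_gap_s, drift_deg_per_s = drift_deg_per_s,
         drift_decay_tau_s = drift_decay_tau_s,
         yaw_osc_amp_deg = yaw_osc_amp_deg,
         yaw_osc_freq_hz = yaw_osc_freq_hz, cop_offset = cop_offset,
         noise_sd = noise_sd, slap_time_s = slap_time_s,
         lead_in_s = lead_in_s,
         insole_clock_offset_s = insole_clock_offset_s,
         missing_gaps = missing_gaps, seed = as.integer(seed)),
    class = "SimConfig")
}

#' Condition labels and their default generator parameters
#'
#' The repeated-measures design has four conditions: `baseline` (sitting
#' upright before walking) and three 5-minute lying adaptation positions
#' (`supine`, right-ear-down `RED`, left-ear-down `LED`). Defaults encode a
#' small overall leftward walking bias, a stronger leftward drift after LED
#' adaptation, a rightward drift after RED, and lateral weight shifts of the
#' opposite sign (leftward heading goes with leftward weight shift, i.e.
#' negative `cop_sym`).
#'
#' @param condition one of `"baseline"`, `"supine"`, `"RED"`, `"LED"`.
#' @return list with elements `drift_deg_per_s` and `cop_offset`.
#' @export
condition_params <- function(condition) {
  params <- list(
    baseline = list(drift_deg_per_s = 0.1,  cop_offset = 0.00),
    supine   = list(drift_deg_per_s = 0.2,  cop_offset = 0.00),
    RED      = list(drift_deg_per_s = -0.4, cop_offset = 0.05),
    LED      = list(drift_deg_per_s = 0.6,  cop_offset = -0.05))
  if (!condition %in% names(params)) {
    stop("invalid condition label: ", condition, call. = FALSE)
  }
  params[[condition]]
}

#' Condition labels in design order
#' @export
gait_conditions <- function() c("baseline", "supine", "RED", "LED")

# Stride waveform geometry, all relative to the stride period T.
# The sagittal-plane ankle angular velocity of one stride is a sum of three
# Gaussian lobes: a negative toe-off valley, a dominant positive mid-swing
# peak, and a negative landing lobe whose amplitude is solved so that the
# analytic waveform crosses zero exactly at the heel-strike time (with a
# transversal slope), keeping every event an exact oracle label.
.stride_shape <- function(T, peak = 300, valley = 100) {
  s <- list(t_to = 0.135 * T, t_ms = 0.360 * T, t_hs = 0.495 * T,
            t_land = 0.570 * T,
            sd_to = 0.045 * T, sd_ms = 0.072 * T, sd_land = 0.090 * T,
            a_to = valley, a_ms = peak)
  at_hs <- s$a_ms * exp(-((s$t_hs - s$t_ms) / s$sd_ms)^2 / 2) -
    s$a_to * exp(-((s$t_hs - s$t_to) / s$sd_to)^2 / 2)
  s$a_land <- at_hs / exp(-((s$t_hs - s$t_land) / s$sd_land)^2 / 2)
  s
}

# Add amp * exp(-((t-center)/sd)^2/2) into sig over a +/-6 sd window.
.add_gauss <- function(sig, fs, n, center, sd, amp) {
  i0 <- max(1L, floor((center - 6 * sd) * fs) + 1L)
  i1 <- min(n, ceiling((center + 6 * sd) * fs) + 1L)
  if (i0 > i1) return(sig)
  tt <- (seq(i0, i1) - 1) / fs
  sig[i0:i1] <- sig[i0:i1] + amp * exp(-((tt - center) / sd)^2 / 2)
  sig
}

# Stride start times for one foot within one segment.
.stride_starts <- function(seg_start, seg_dur, T, offset, hs_frac = 0.495) {
  k_max <- floor((seg_dur - offset - hs_frac * T) / T)
  if (k_max < 0) return(numeric(0))
  seg_start + offset + (0:k_max) * T
}

# 4x4 insole sensor grid (normalized device coordinates, cell centers).
.insole_grid <- function() {
  g <- c(-0.375, -0.125, 0.125, 0.375)
  data.frame(sensor = sprintf("p%02d", 1:16),
             x = rep(g, times = 4), y = rep(g, each = 4))
}

# Distribute a total force at CoP (x, y) onto the 4x4 grid by bilinear
# weights over the enclosing cell; the pressure-weighted centroid of the
# result equals (x, y) exactly.
.bilinear_pressures <- function(x, y, force) {
  g <- c(-0.375, -0.125, 0.125, 0.375)
  eps <- 1e-9
  x <- pmin(pmax(x, g[1] + eps), g[4] - eps)
  y <- pmin(pmax(y, g[1] + eps), g[4] - eps)
  ix <- pmin(findInterval(x, g), 3L)
  iy <- pmin(findInterval(y, g), 3L)
  wx <- (x - g[ix]) / 0.25
  wy <- (y - g[iy]) / 0.25
  out <- matrix(0, nrow = length(x), ncol = 16)
  idx <- function(i, j) (j - 1L) * 4L + i   # row-major by y: p = (iy-1)*4+ix
  for (di in 0:1) for (dj in 0:1) {
    w <- (if (di == 0) 1 - wx else wx) * (if (dj == 0) 1 - wy else wy)
    cols <- idx(ix + di, iy + dj)
    out[cbind(seq_along(x), cols)] <- out[cbind(seq_along(x), cols)] + force * w
  }
  out
}

#' Simulate one walking trial with exact ground truth
#'
#' Generates a chest IMU trace, two ankle IMU traces and two insole traces
#' (16 pressure channels plus an embedded IMU each) for a single trial of
#' one condition, together with the ground-truth labels needed to verify
#' every pipeline stage: per-foot event times, walking-segment bounds, the
#' true per-segment yaw slope and centre-of-pressure symmetry, and the
#' leg-slap time.
#'
#' The ankle sagittal angular velocity is a periodic stride template with an
#' analytically placed toe-off valley, mid-swing peak and heel-strike
#' zero-crossing, zeroed during turn gaps. Chest gyro/accel are consistent
#' with the orientation yaw(t) = integrated drift + twist oscillation,
#' pitch = roll = 0, gravity in the accelerometer (no linear walking
#' acceleration). Insole pressure shows heel-to-toe stance loading with the
#' lateral CoP component shifted by half the configured `cop_offset` on each
#' foot (opposite signs), so that left-minus-right symmetry equals
#' `cop_offset` exactly. A medio-lateral acceleration impulse at
#' `slap_time_s`, 10x the walking ML-acceleration maximum, appears in the
#' left-ankle and left-insole traces.
#'
#' @param config a [sim_config()].
#' @param condition condition label, see [gait_conditions()].
#' @return list with elements `chest`, `ankle_left`, `ankle_right`,
#'   `insole_left`, `insole_right` (all [sensor_trace()]) and `truth`
#'   (a `GroundTruth` list: `events` per foot, `segment_bounds`,
#'   `true_yaw_slope_per_ws`, `true_cop_sym`, `slap_time_s`,
#'   `insole_clock_offset_s`, `drift_deg_per_s`).
#' @export
simulate_trial <- function(config, condition = "baseline") {
  stopifnot(inherits(config, "SimConfig"))
  cond <- condition_params(condition)
  drift <- if (is.null(config$drift_deg_per_s)) cond$drift_deg_per_s else
    config$drift_deg_per_s
  cop_off <- if (is.null(config$cop_offset)) cond$cop_offset else
    config$cop_offset

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  fs <- config$sample_rate_hz
  T <- 1 / config$cadence_hz
  seg_dur <- config$walk_duration_s / config$n_segments
  seg_start <- config$lead_in_s +
    (seq_len(config$n_segments) - 1) * (seg_dur + config$turn_gap_s)
  seg_end <- seg_start + seg_dur
  total <- seg_end[config$n_segments] + 2
  n <- floor(total * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  shape <- .stride_shape(T)

  # --- per-foot gait events and sagittal angular velocity -------------------
  feet <- list(left = 0, right = T / 2)
  events <- list(); gyro_sag <- list()
  for (foot in names(feet)) {
    starts <- unlist(lapply(seq_len(config$n_segments), function(j) {
      .stride_starts(seg_start[j], seg_dur, T, feet[[foot]])
    }))
    sig <- numeric(n)
    for (s0 in starts) {
      sig <- .add_gauss(sig, fs, n, s0 + shape$t_to, shape$sd_to, -shape$a_to)
      sig <- .add_gauss(sig, fs, n, s0 + shape$t_ms, shape$sd_ms, shape$a_ms)
      sig <- .add_gauss(sig, fs, n, s0 + shape$t_land, shape$sd_land,
                        -shape$a_land)
    }
    events[[foot]] <- data.frame(toeoff = starts + shape$t_to,
                                 midswing = starts + shape$t_ms,
                                 heelstrike = starts + shape$t_hs)
    gyro_sag[[foot]] <- sig
  }

  # --- chest orientation ----------------------------------------------------
  tw <- pmax(t - config$lead_in_s, 0)     # walking-time coordinate
  tau <- config$drift_decay_tau_s
  if (is.finite(tau)) {
    drift_yaw <- drift * tau * (1 - exp(-tw / tau))
    drift_rate <- drift * exp(-tw / tau) * (t >= config$lead_in_s)
  } else {
    drift_yaw <- drift * tw
    drift_rate <- drift * (t >= config$lead_in_s)
  }
  w_osc <- 2 * pi * config$yaw_osc_freq_hz
  osc_phase <- stats::runif(1, 0, 2 * pi)  # twist phase is arbitrary
  osc_rate <- config$yaw_osc_amp_deg * w_osc * cos(w_osc * tw + osc_phase)
  chest_gyro_x <- drift_rate + osc_rate

  # true yaw slope per WS: OLS slope of the drift component over the segment
  true_slope <- vapply(seq_len(config$n_segments), function(j) {
    i <- which(t >= seg_start[j] & t < seg_end[j])
    stats::cov(t[i], drift_yaw[i]) / stats::var(t[i])
  }, numeric(1))

  # --- walking ML acceleration and the slap impulse -------------------------
  walking <- rep(FALSE, n)
  for (j in seq_len(config$n_segments)) {
    walking[t >= seg_start[j] & t < seg_end[j]] <- TRUE
  }
  ml_walk <- 1.0 * sin(2 * pi * config$cadence_hz * tw) * walking
  slap_amp <- 10 * max(abs(ml_walk), 1)
  slap <- slap_amp * exp(-((t - config$slap_time_s) / 0.02)^2 / 2)

  nz <- config$noise_sd
  g <- 9.80665
  mk_imu <- function(sag, ml_extra, gyro_noise, device, location) {
    sensor_trace(
      time = t,
      channels = data.frame(
        gyro_x = stats::rnorm(n, 0, gyro_noise),
        gyro_y = sag + stats::rnorm(n, 0, gyro_noise),
        gyro_z = stats::rnorm(n, 0, gyro_noise),
        accel_x = g + stats::rnorm(n, 0, nz$accel),
        accel_y = ml_walk + ml_extra + stats::rnorm(n, 0, nz$accel),
        accel_z = stats::rnorm(n, 0, nz$accel)),
      units = c(gyro_x = "deg/s", gyro_y = "deg/s", gyro_z = "deg/s",
                accel_x = "m/s2", accel_y = "m/s2", accel_z = "m/s2"),
      device_id = device, body_location = location)
  }

  chest <- sensor_trace(
    time = t,
    channels = data.frame(
      gyro_x = chest_gyro_x + stats::rnorm(n, 0, nz$chest_gyro),
      gyro_y = stats::rnorm(n, 0, nz$chest_gyro),
      gyro_z = stats::rnorm(n, 0, nz$chest_gyro),
      accel_x = g + stats::rnorm(n, 0, nz$accel),
      accel_y = stats::rnorm(n, 0, nz$accel),
      accel_z = stats::rnorm(n, 0, nz$accel)),
    units = c(gyro_x = "deg/s", gyro_y = "deg/s", gyro_z = "deg/s",
              accel_x = "m/s2", accel_y = "m/s2", accel_z = "m/s2"),
    device_id = "sim-imu-chest", body_location = "chest")

  ankle_left <- mk_imu(gyro_sag$left, slap, nz$gyro,
                       "sim-imu-ankle-L", "ankle_left")
  ankle_right <- mk_imu(gyro_sag$right, 0, nz$gyro,
                        "sim-imu-ankle-R", "ankle_right")

  # --- insoles --------------------------------------------------------------
  # Anatomical lateral offsets: leftward weight shift (cop_off < 0) moves the
  # left foot's CoP lateral and the right foot's medial. With medial positive
  # on both feet (anatomical frame), left = +cop_off/2, right = -cop_off/2,
  # so left - right = cop_off. Device frames mirror the right foot's axis.
  mk_insole <- function(foot, sag, ml_extra) {
    y_anat <- if (foot == "left") cop_off / 2 else -cop_off / 2
    y_dev <- if (foot == "left") y_anat else -y_anat
    press <- matrix(0, nrow = n, ncol = 16)
    ev <- events[[foot]]
    for (j in seq_len(config$n_segments)) {
      in_seg <- ev$midswing >= seg_start[j] & ev$midswing < seg_end[j]
      hs <- ev$heelstrike[in_seg]; to <- ev$toeoff[in_seg]
      # stance windows: segment start -> first toe-off, then each
      # heel-strike -> next toe-off, last heel-strike -> segment end
      a <- c(seg_start[j], hs)
      b <- c(to, seg_end[j])
      for (k in seq_along(a)) {
        i <- which(t >= a[k] & t <= b[k])
        if (length(i) < 2) next
        u <- (t[i] - a[k]) / (b[k] - a[k])
        force <- sin(pi * u)
        copx <- -0.3 + 0.6 * u
        press[i, ] <- press[i, ] +
          .bilinear_pressures(copx, rep(y_dev, length(i)), force)
      }
    }
    press <- press + matrix(stats::rnorm(n * 16, 0, nz$pressure), n, 16)
    press[press < 0] <- 0
    chans <- as.data.frame(press)
    names(chans) <- sprintf("p%02d", 1:16)
    chans$gyro_y <- sag + stats::rnorm(n, 0, nz$gyro)
    chans$accel_y <- ml_walk + ml_extra + stats::rnorm(n, 0, nz$accel)
    units <- c(stats::setNames(rep("norm", 16), sprintf("p%02d", 1:16)),
               gyro_y = "deg/s", accel_y = "m/s2")
    sensor_trace(time = t + config$insole_clock_offset_s, channels = chans,
                 units = units, device_id = paste0("sim-insole-", foot),
                 body_location = paste0("insole_", foot))
  }
  insole_left <- mk_insole("left", gyro_sag$left, slap)
  insole_right <- mk_insole("right", gyro_sag$right, 0)

  out <- list(chest = chest, ankle_left = ankle_left,
              ankle_right = ankle_right, insole_left = insole_left,
              insole_right = insole_right)

  if (!is.null(config$missing_gaps)) {
    for (gap in config$missing_gaps) {
      for (nm in names(out)) {
        tt <- out[[nm]]$time - (if (grepl("insole", nm))
          config$insole_clock_offset_s else 0)
        i <- which(tt >= gap[1] & tt < gap[1] + gap[2])
        if (length(i)) {
          out[[nm]]$channels[i, ] <- NA_real_
          out[[nm]]$missing_mask[i] <- TRUE
        }
      }
    }
  }

  out$truth <- list(
    events = events,
    segment_bounds = data.frame(start_s = seg_start, end_s = seg_end),
    true_yaw_slope_per_ws = true_slope,
    true_cop_sym = rep(cop_off, config$n_segments),
    slap_time_s = config$slap_time_s,
    insole_clock_offset_s = config$insole_clock_offset_s,
    drift_deg_per_s = drift)
  out$condition <- condition
  out$config <- config
  out
}

#' Simulate a repeated-measures study of full sensor trials
#'
#' Every subject receives a persistent random heading bias (drawn once, sd =
#' `between_subject_sd`) added to all condition drifts, plus independent
#' per-trial drift and CoP jitter; the condition order is randomized per
#' subject. The whole study is a pure function of the seed.
#'
#' @param config a [sim_config()] used as the template for every trial (its
#'   `drift_deg_per_s`/`cop_offset`/`seed` are overridden per trial).
#' @param n_subjects number of subjects (>= 2).
#' @param n_reps repetitions of each condition per subject.
#' @param between_subject_sd sd of the per-subject heading bias (deg/s).
#' @param trial_drift_sd per-trial drift jitter sd (deg/s).
#' @param trial_cop_sd per-trial CoP-offset jitter sd (normalized units).
#' @param seed study-level RNG seed.
#' @param handler optional `function(trial, meta)` called with each
#'   simulated trial; when supplied, trials are not accumulated in memory
#'   (used by [make_fixture()] to stream trials to disk).
#' @return list with `trials` (list of [simulate_trial()] results, each with
#'   `participant`/`repetition` added; `NULL`s when `handler` is used) and
#'   `truth` (data frame of per-trial injected parameters).
#' @export
simulate_study <- function(config, n_subjects, n_reps,
                           between_subject_sd = 0.2, trial_drift_sd = 0.2,
                           trial_cop_sd = 0.01, seed, handler = NULL) {
  stopifnot(n_subjects >= 2, n_reps >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conds <- gait_conditions()
  subj_bias <- stats::rnorm(n_subjects, 0, between_subject_sd)
  plan <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    order_s <- c("baseline", sample(conds[-1]))
    do.call(rbind, lapply(order_s, function(cn) {
      data.frame(participant = sprintf("S%02d", s), condition = cn,
                 repetition = seq_len(n_reps))
    }))
  }))
  plan$drift <- vapply(plan$condition, function(cn)
    condition_params(cn)$drift_deg_per_s, numeric(1)) +
    subj_bias[as.integer(factor(plan$participant))] +
    stats::rnorm(nrow(plan), 0, trial_drift_sd)
  plan$cop_offset <- vapply(plan$condition, function(cn)
    condition_params(cn)$cop_offset, numeric(1)) +
    stats::rnorm(nrow(plan), 0, trial_cop_sd)
  plan$trial_seed <- sample.int(.Machine$integer.max - 1, nrow(plan))

  trials <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cfg <- config
    cfg$drift_deg_per_s <- plan$drift[i]
    cfg$cop_offset <- plan$cop_offset[i]
    cfg$seed <- plan$trial_seed[i]
    tr <- simulate_trial(cfg, plan$condition[i])
    tr$participant <- plan$participant[i]
    tr$repetition <- plan$repetition[i]
    if (is.null(handler)) {
      trials[[i]] <- tr
    } else {
      handler(tr, plan[i, ])
    }
  }
  list(trials = trials, truth = plan)
}

#' Simulate a study table of per-segment gait measures
#'
#' Draws yaw slopes and CoP symmetries directly at the measure level (no
#' sensor traces), following the same mixed-effects structure the study
#' model assumes: condition effect x optional per-segment decay + subject
#' random intercept + residual. Used for inference-layer calibration
#' (type-I error, power, correlation direction) where simulating raw 100 Hz
#' traces would add nothing but runtime.
#'
#' @param n_subjects,n_reps design size.
#' @param cond_yaw,cond_cop named per-condition true effects (deg/s and
#'   normalized units).
#' @param between_subject_sd,residual_sd subject and residual sd of the yaw
#'   slope (deg/s).
#' @param cop_between_sd,cop_residual_sd same for the CoP symmetry.
#' @param ws_decay length-3 multiplier of the condition effects across
#'   walking segments 1-3 (default: no decay).
#' @param seed RNG seed.
#' @return a `StudyTable` data frame with columns `participant`, `trial`,
#'   `repetition`, `walkingSegment`, `measure` (`"yaw_slope"` or
#'   `"cop_sym"`), `value`.
#' @export
simulate_measures_study <- function(n_subjects = 25, n_reps = 3,
                                    cond_yaw = c(baseline = 0.1, supine = 0.2,
                                                 RED = -0.4, LED = 0.6),
                                    cond_cop = c(baseline = 0, supine = 0,
                                                 RED = 0.05, LED = -0.05),
                                    between_subject_sd = 0.2,
                                    residual_sd = 0.2,
                                    cop_between_sd = 0.02,
                                    cop_residual_sd = 0.02,
                                    ws_decay = c(1, 1, 1), seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conds <- gait_conditions()
  d <- expand.grid(participant = sprintf("S%02d", seq_len(n_subjects)),
                   trial = conds, repetition = seq_len(n_reps),
                   walkingSegment = 1:3, stringsAsFactors = FALSE)
  by <- stats::rnorm(n_subjects, 0, between_subject_sd)
  bc <- stats::rnorm(n_subjects, 0, cop_between_sd)
  si <- as.integer(factor(d$participant))
  dec <- ws_decay[d$walkingSegment]
  yaw <- cond_yaw[d$trial] * dec + by[si] +
    stats::rnorm(nrow(d), 0, residual_sd)
  cop <- cond_cop[d$trial] * dec + bc[si] +
    stats::rnorm(nrow(d), 0, cop_residual_sd)
  out <- rbind(
    data.frame(d, measure = "yaw_slope", value = as.numeric(yaw)),
    data.frame(d, measure = "cop_sym", value = as.numeric(cop)))
  rownames(out) <- NULL
  out
}
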