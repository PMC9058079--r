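# Quaternion helpers (w, x, y, z). Body axes: x = cranio-caudal (up when
# standing), y = medio-lateral, z = posterior-anterior. Euler angles are
# intrinsic yaw (about x) -> pitch (about y) -> roll (about z); yaw is
# positive for leftward chest rotation, matching the gyro x sign.

quat_mul <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_from_rotvec <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(c(1, v / 2))
  axis <- v / ang
  c(cos(ang / 2), sin(ang / 2) * axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Euler extraction for R = Rx(yaw) %*% Ry(pitch) %*% Rz(roll); errors near
# gimbal lock (|pitch| -> 90 deg), which normal walking never approaches.
quat_to_euler <- function(q) {
  R <- quat_to_matrix(q)
  sp <- R[1, 3]
  if (abs(sp) > 1 - 1e-8) stop("gimbal lock: |pitch| at 90 deg", call. = FALSE)
  c(yaw = atan2(-R[2, 3], R[3, 3]),
    pitch = asin(sp),
    roll = atan2(-R[1, 2], R[1, 1])) * 180 / pi
}

#' Fuse gyroscope and accelerometer data into an orientation series
#'
#' Strapdown gyro integration with a complementary gravity correction:
#' each step integrates the body-frame angular velocity into the attitude
#' quaternion, then rotates the estimate slightly so that the predicted
#' gravity direction tracks the (normalized) accelerometer vector. The
#' correction axis is perpendicular to gravity, so the accelerometer
#' influences only the tilt (pitch/roll) components; yaw is pure gyro
#' integration from the identity orientation (sensors are reset in a
#' neutral standing pose before each trial, and no magnetometer is used).
#'
#' @param gyro n x 3 matrix of angular velocity in deg/s (body axes
#'   x = cranio-caudal, y = medio-lateral, z = posterior-anterior).
#' @param accel n x 3 accelerometer matrix (any consistent unit; only the
#'   direction is used). Near-zero-norm samples are skipped (gyro-only
#'   step).
#' @param sample_rate Hz.
#' @param tilt_tau_s time constant of the gravity correction (s); static
#'   tilt errors decay as exp(-t / tilt_tau_s).
#' @return an `OrientationSeries` list: `quat` (n x 4, unit rows), `euler`
#'   (n x 3, degrees: yaw, pitch, roll), `time_step_s`.
#' @export
fuse <- function(gyro, accel, sample_rate, tilt_tau_s = 1) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  stopifnot(ncol(gyro) == 3, ncol(accel) == 3,
            nrow(gyro) == nrow(accel), sample_rate > 0)
  n <- nrow(gyro)
  dt <- 1 / sample_rate
  alpha <- dt / (tilt_tau_s + dt)
  gyr <- gyro * pi / 180
  q <- c(1, 0, 0, 0)
  quat <- matrix(0, n, 4)
  euler <- matrix(0, n, 3)
  colnames(euler) <- c("yaw", "pitch", "roll")
  up <- c(1, 0, 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      q <- quat_mul(q, quat_from_rotvec(gyr[i, ] * dt))
    }
    a <- accel[i, ]
    an <- sqrt(sum(a^2))
    if (is.finite(an) && an > 1e-6) {
      g_meas <- a / an
      g_pred <- crossprod(quat_to_matrix(q), up)[, 1]  # world up in body frame
      corr <- alpha * c(g_meas[2] * g_pred[3] - g_meas[3] * g_pred[2],
                        g_meas[3] * g_pred[1] - g_meas[1] * g_pred[3],
                        g_meas[1] * g_pred[2] - g_meas[2] * g_pred[1])
      q <- quat_mul(q, quat_from_rotvec(corr))
    }
    q <- q / sqrt(sum(q^2))
    quat[i, ] <- q
    euler[i, ] <- quat_to_euler(q)
  }
  structure(list(quat = quat, euler = euler, time_step_s = dt),
            class = "OrientationSeries")
}

#' Unwrap an angle series across +/-180 degree jumps
#'
#' @param deg angle series in degrees.
#' @return unwrapped series (continuous, no wrap jumps).
#' @export
unwrap_deg <- function(deg) {
  signal::unwrap(deg * pi / 180) * 180 / pi
}

#' Per-segment linear regression of the heading angle
#'
#' The heading (yaw) of the chest oscillates with each step but trends with
#' the walked curvature; its ordinary least-squares slope against time over
#' one walking segment ("yaw slope", deg/s) is the study's heading-bias
#' measure. Positive slope = turning left. Yaw is unwrapped before the
#' regression so wrap-arounds cannot corrupt the fit.
#'
#' @param orientation an `OrientationSeries` from [fuse()].
#' @param segment one row of a [segment_walking()] result (or any list with
#'   `ws`, `start_idx`, `end_idx`, 0-based half-open sample indices).
#' @return a `YawSlope` list: `ws`, `slope` (deg/s), `intercept` (deg),
#'   `n_samples`, `residual_sd`.
#' @export
yaw_slope <- function(orientation, segment) {
  i0 <- segment$start_idx + 1L
  i1 <- segment$end_idx
  stopifnot(i0 >= 1, i1 <= nrow(orientation$euler))
  if (i1 - i0 + 1L < 2L) stop("segment shorter than 2 samples", call. = FALSE)
  yaw <- unwrap_deg(orientation$euler[i0:i1, "yaw"])
  tt <- (seq(i0, i1) - 1) * orientation$time_step_s
  fit <- stats::lm.fit(cbind(1, tt), yaw)
  res_sd <- if (length(yaw) > 2) stats::sd(fit$residuals) else 0
  list(ws = segment$ws, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_samples = length(yaw), residual_sd = res_sd)
}
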