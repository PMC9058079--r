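# Shared helpers for building small synthetic inputs in code.

FS <- 100

# Analytic two-pass Butterworth magnitude at frequency f (Hz): the digital
# filter is a bilinear-transform design, so the single-pass magnitude is
# 1/sqrt(1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order)); forward-backward
# filtering squares it.
butter2_gain <- function(f, fs = 100, fc = 12, order = 4) {
  (1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order)))^2
}

# A compact trial configuration: 40 s of walking in 2 segments keeps most
# tests fast while preserving the full trial structure.
quick_cfg <- function(seed, ...) {
  args <- list(...)
  defaults <- list(walk_duration_s = 40, n_segments = 2, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

noise_free <- list(gyro = 0, chest_gyro = 0, accel = 0, pressure = 0)

# Detect both feet's events and the walking segments of a trial.
detect_trial_events <- function(trial) {
  ev_l <- detect_gait_events(trace_channel(trial$ankle_left, "gyro_y"), FS)
  ev_r <- detect_gait_events(trace_channel(trial$ankle_right, "gyro_y"), FS)
  list(left = ev_l, right = ev_r,
       ws = segment_walking(ev_l, ev_r, FS))
}

# Fraction of true mid-swing events matched by a detection within tol_s,
# and the count of detections not matching any true event.
event_recall <- function(detected_idx, true_times_s, tol_s = 0.1) {
  det_t <- detected_idx / FS
  hit <- vapply(true_times_s, function(tt) any(abs(det_t - tt) <= tol_s),
                logical(1))
  spurious <- sum(vapply(det_t, function(dt)
    all(abs(true_times_s - dt) > tol_s), logical(1)))
  list(recall = mean(hit), spurious = spurious)
}

# Per-segment yaw slopes of a trial via the full orientation path.
trial_yaw_slopes <- function(trial, max_ws = 3) {
  ev <- detect_trial_events(trial)
  ori <- fuse(as.matrix(trial$chest$channels[, c("gyro_x", "gyro_y", "gyro_z")]),
              as.matrix(trial$chest$channels[, c("accel_x", "accel_y", "accel_z")]),
              FS)
  n <- min(max_ws, nrow(ev$ws))
  vapply(seq_len(n), function(w) yaw_slope(ori, ev$ws[w, ])$slope,
         numeric(1))
}

# Per-segment CoP symmetry of a trial via the insole path (no clock offset).
trial_cop_sym <- function(trial, max_ws = 3) {
  ev_l <- detect_gait_events(trace_channel(trial$insole_left, "gyro_y"), FS)
  ev_r <- detect_gait_events(trace_channel(trial$insole_right, "gyro_y"), FS)
  ws <- segment_walking(ev_l, ev_r, FS)
  n <- min(max_ws, nrow(ws))
  vapply(seq_len(n), function(w) {
    cl <- ws_cop(trial$insole_left, ev_l, ws[w, ], foot = "left")
    cr <- ws_cop(trial$insole_right, ev_r, ws[w, ], foot = "right")
    cop_sym(cl$cop_lm, cr$cop_lm)
  }, numeric(1))
}
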