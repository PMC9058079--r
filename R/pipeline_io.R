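#' Write a SensorTrace to CSV
#'
#' The interchange dialect is plain CSV with a small metadata block of
#' `# key: value` comment lines (device, body location, per-channel units),
#' then a header row `time_s,<channel>,...` and one row per sample. Missing
#' samples are empty cells.
#'
#' @param trace a [sensor_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# device_id: ", trace$device_id),
    paste0("# body_location: ", trace$body_location),
    paste0("# units: ",
           paste(names(trace$units), trace$units, sep = "=",
                 collapse = ","))), con)
  df <- cbind(time_s = trace$time, trace$channels)
  df[trace$missing_mask, -1] <- NA
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a SensorTrace from CSV
#'
#' Validates the dialect written by [write_trace()]: a `time_s` column with
#' strictly increasing timestamps, the channels the schema role requires,
#' and a unit declaration for every channel. Missing cells become masked
#' samples.
#'
#' @param path CSV file path.
#' @param schema `"imu"` (requires 3-axis gyro + accel), `"insole"`
#'   (requires `p01`..`p16`, `gyro_y`, `accel_y`) or `"any"`.
#' @return a [sensor_trace()].
#' @export
read_trace <- function(path, schema = c("any", "imu", "insole")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10)
  meta_lines <- grep("^# ", hdr, value = TRUE)
  meta <- list(device_id = "unknown", body_location = "unknown", units = "")
  for (ln in meta_lines) {
    if (!grepl("^# [^:]+: ", ln)) next
    key <- sub("^# ([^:]+): .*$", "\\1", ln)
    val <- sub("^# [^:]+: (.*)$", "\\1", ln)
    meta[[key]] <- val
  }
  units <- character(0)
  if (nzchar(meta$units)) {
    pairs <- strsplit(strsplit(meta$units, ",")[[1]], "=")
    units <- stats::setNames(vapply(pairs, `[`, "", 2),
                             vapply(pairs, `[`, "", 1))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("missing channel: time_s", call. = FALSE)
  }
  required <- switch(schema,
    imu = c("gyro_x", "gyro_y", "gyro_z", "accel_x", "accel_y", "accel_z"),
    insole = c(sprintf("p%02d", 1:16), "gyro_y", "accel_y"),
    any = character(0))
  absent <- setdiff(required, names(df))
  if (length(absent)) {
    stop("missing channel: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  tt <- df$time_s
  if (any(diff(tt) <= 0)) stop("non-monotonic time", call. = FALSE)
  chans <- df[, setdiff(names(df), "time_s"), drop = FALSE]
  declared <- setdiff(names(chans), names(units))
  if (length(declared)) {
    stop("unit mismatch: no unit declared for ",
         paste(declared, collapse = ", "), call. = FALSE)
  }
  sensor_trace(time = tt, channels = chans, units = units,
               device_id = meta$device_id,
               body_location = meta$body_location)
}

#' Read and validate a trial manifest
#'
#' A manifest is a CSV with one row per trial: `participant`, `condition`,
#' `repetition`, and relative paths `chest`, `ankle_left`, `ankle_right`,
#' `insole_left`, `insole_right`, plus an optional `truth` sidecar path.
#' (participant, condition, repetition) keys must be unique. Missing insole
#' files are tolerated (the trial is then excluded from CoP analyses only);
#' missing IMU files are an error.
#'
#' @param path manifest CSV path; trace paths are resolved relative to it.
#' @return data frame with absolute paths and a `dir` attribute.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "repetition", "chest",
            "ankle_left", "ankle_right", "insole_left", "insole_right")
  absent <- setdiff(need, names(man))
  if (length(absent)) {
    stop("manifest lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(man$participant, man$condition, man$repetition)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, condition, repetition) in manifest",
         call. = FALSE)
  }
  dir <- dirname(normalizePath(path))
  for (col in c("chest", "ankle_left", "ankle_right", "insole_left",
                "insole_right", intersect("truth", names(man)))) {
    man[[col]] <- ifelse(is.na(man[[col]]) | man[[col]] == "", NA,
                         file.path(dir, man[[col]]))
  }
  for (col in c("chest", "ankle_left", "ankle_right")) {
    bad <- !is.na(man[[col]]) & !file.exists(man[[col]])
    if (any(bad)) {
      stop("manifest references missing file(s): ",
           paste(man[[col]][bad], collapse = ", "), call. = FALSE)
    }
  }
  attr(man, "dir") <- dir
  man
}

#' Process one trial's traces into per-segment gait measures
#'
#' Runs the single-trial part of the pipeline: leg-slap synchronization of
#' the insole system onto the IMU clock, gap repair, per-system gait-event
#' detection and walking-segment separation, chest orientation fusion with
#' per-segment yaw-slope regression, and stance-phase CoP symmetry per
#' segment.
#'
#' @param trial list with [sensor_trace()] elements `chest`, `ankle_left`,
#'   `ankle_right` and optionally `insole_left`, `insole_right` (as
#'   produced by [simulate_trial()] or read from a manifest row).
#' @param max_ws number of walking segments to report (the analysis uses
#'   the first three).
#' @param max_gap_s passed to [fill_gaps()].
#' @return list `measures` (data frame `ws`, `yaw_slope`, `cop_sym`),
#'   `sync_offset_s`, `n_ws_imu`, `n_ws_insole`, `log` (character vector
#'   of per-trial notes: dropped strides/segments, exclusions).
#' @export
process_trial <- function(trial, max_ws = 3, max_gap_s = 0.2) {
  log <- character(0)
  fs <- trace_sample_rate(trial$chest)

  has_insoles <- !is.null(trial$insole_left) && !is.null(trial$insole_right)
  insoles <- NULL
  if (has_insoles) {
    sync <- tryCatch({
      slap_imu <- detect_slap(trial$ankle_left, channel = "accel_y")
      slap_ins <- detect_slap(trial$insole_left, channel = "accel_y")
      offset <- slap_imu - slap_ins
      list(offset = offset)
    }, error = function(e) e)
    if (inherits(sync, "error")) {
      log <- c(log, paste("sync failed:", conditionMessage(sync)))
      has_insoles <- FALSE
    } else {
      shift <- function(tr) { tr$time <- tr$time + sync$offset; tr }
      insoles <- list(left = shift(trial$insole_left),
                      right = shift(trial$insole_right))
      log <- c(log, sprintf("sync offset %.4f s", sync$offset))
    }
  } else {
    log <- c(log, "insole trace(s) missing: trial excluded from CoP analyses")
  }

  fill <- function(tr) suppressWarnings(fill_gaps(tr, max_gap_s = max_gap_s))
  chest <- fill(trial$chest)
  ankle_l <- fill(trial$ankle_left)
  ankle_r <- fill(trial$ankle_right)
  if (has_insoles) insoles <- lapply(insoles, fill)

  # --- IMU system: events, segments, yaw slopes ----------------------------
  interp_na <- function(x) {  # long unfilled gaps: linear bridge for filtering
    if (!anyNA(x)) return(x)
    i <- which(!is.na(x))
    stats::approx(i, x[i], xout = seq_along(x), rule = 2)$y
  }
  ev_l <- detect_gait_events(interp_na(trace_channel(ankle_l, "gyro_y")), fs)
  ev_r <- detect_gait_events(interp_na(trace_channel(ankle_r, "gyro_y")), fs)
  nd <- attr(ev_l, "n_dropped") + attr(ev_r, "n_dropped")
  if (nd > 0) log <- c(log, sprintf("%d incomplete stride(s) dropped", nd))
  ws_imu <- segment_walking(ev_l, ev_r, fs)
  if (attr(ws_imu, "n_discarded") > 0) {
    log <- c(log, sprintf("%d short segment(s) discarded (IMU)",
                          attr(ws_imu, "n_discarded")))
  }

  yaw <- rep(NA_real_, max_ws)
  if (nrow(ws_imu) > 0) {
    ori <- fuse(
      cbind(interp_na(trace_channel(chest, "gyro_x")),
            interp_na(trace_channel(chest, "gyro_y")),
            interp_na(trace_channel(chest, "gyro_z"))),
      cbind(interp_na(trace_channel(chest, "accel_x")),
            interp_na(trace_channel(chest, "accel_y")),
            interp_na(trace_channel(chest, "accel_z"))),
      fs)
    for (w in seq_len(min(max_ws, nrow(ws_imu)))) {
      yaw[w] <- yaw_slope(ori, ws_imu[w, ])$slope
    }
  } else {
    log <- c(log, "no walking segments found (IMU): trial excluded")
  }

  # --- insole system: events, segments, CoP symmetry -----------------------
  cop <- rep(NA_real_, max_ws)
  n_ws_ins <- 0L
  if (has_insoles) {
    iev_l <- detect_gait_events(
      interp_na(trace_channel(insoles$left, "gyro_y")), fs)
    iev_r <- detect_gait_events(
      interp_na(trace_channel(insoles$right, "gyro_y")), fs)
    ws_ins <- segment_walking(iev_l, iev_r, fs)
    n_ws_ins <- nrow(ws_ins)
    for (w in seq_len(min(max_ws, nrow(ws_ins)))) {
      cl <- ws_cop(insoles$left, iev_l, ws_ins[w, ], foot = "left")
      cr <- ws_cop(insoles$right, iev_r, ws_ins[w, ], foot = "right")
      cop[w] <- cop_sym(cl$cop_lm, cr$cop_lm)
      if (is.na(cop[w])) {
        log <- c(log, sprintf("WS%d: missing CoP on one foot", w))
      }
    }
  }

  list(measures = data.frame(ws = seq_len(max_ws), yaw_slope = yaw,
                             cop_sym = cop),
       sync_offset_s = if (has_insoles) sync$offset else NA_real_,
       n_ws_imu = nrow(ws_imu), n_ws_insole = n_ws_ins, log = log)
}

# Load the five traces of one manifest row (NULL for absent insoles).
.load_trial <- function(row) {
  tr <- list(chest = read_trace(row$chest, "imu"),
             ankle_left = read_trace(row$ankle_left, "imu"),
             ankle_right = read_trace(row$ankle_right, "imu"))
  for (side in c("left", "right")) {
    p <- row[[paste0("insole_", side)]]
    tr[[paste0("insole_", side)]] <-
      if (!is.na(p) && file.exists(p)) read_trace(p, "insole") else NULL
  }
  tr
}

#' Run the full study pipeline
#'
#' Processes every trial of a manifest (or an in-memory trial list) through
#' [process_trial()], assembles the long-format study table of the first
#' three walking segments' yaw slopes and CoP symmetries, removes extreme
#' points (3 x IQR rule per condition x segment cell), fits the
#' mixed-effects model per measure, computes Tukey-adjusted pairwise
#' condition contrasts per segment, and the baseline-corrected yaw-CoP
#' Pearson correlation. Every exclusion is logged with its trial key.
#'
#' @param manifest path to a manifest CSV, a data frame from
#'   [read_manifest()], or a list of in-memory trials each carrying
#'   `participant`, `condition`, `repetition`.
#' @param max_ws number of walking segments analysed.
#' @return a `gait_report` list: `study_table`, `assumptions`, `models`
#'   (per measure), `emms`, `contrasts` (6 contrasts x `max_ws` segments x
#'   2 measures), `correlation`, `exclusions`, `log`.
#' @export
run_pipeline <- function(manifest, max_ws = 3) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  log <- character(0); rows <- list()
  get_trial <- function(i) {
    if (is.data.frame(manifest)) {
      row <- manifest[i, ]
      tr <- .load_trial(row)
      tr$participant <- row$participant
      tr$condition <- row$condition
      tr$repetition <- row$repetition
      tr
    } else manifest[[i]]
  }
  n_trials <- if (is.data.frame(manifest)) nrow(manifest) else
    length(manifest)
  for (i in seq_len(n_trials)) {
    tr <- get_trial(i)
    key <- sprintf("%s/%s/rep%s", tr$participant, tr$condition,
                   tr$repetition)
    res <- tryCatch(process_trial(tr, max_ws = max_ws),
                    error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, sprintf("%s: trial excluded (%s)", key,
                            conditionMessage(res)))
      next
    }
    log <- c(log, sprintf("%s: %s", key, res$log))
    m <- res$measures
    rows[[length(rows) + 1]] <- rbind(
      data.frame(participant = tr$participant, trial = tr$condition,
                 repetition = tr$repetition, walkingSegment = m$ws,
                 measure = "yaw_slope", value = m$yaw_slope),
      data.frame(participant = tr$participant, trial = tr$condition,
                 repetition = tr$repetition, walkingSegment = m$ws,
                 measure = "cop_sym", value = m$cop_sym))
  }
  study <- do.call(rbind, rows)
  rownames(study) <- NULL
  filtered <- filter_extremes(study)
  if (attr(filtered, "n_removed") > 0) {
    log <- c(log, sprintf("%d extreme point(s) removed (3xIQR rule)",
                          attr(filtered, "n_removed")))
  }
  models <- emms <- contrasts <- assumptions <- list()
  for (ms in c("yaw_slope", "cop_sym")) {
    assumptions[[ms]] <- tryCatch(assumption_tests(filtered, ms),
                                  error = function(e) NULL)
    models[[ms]] <- suppressWarnings(fit_lme(filtered, ms))
    emms[[ms]] <- emm_table(models[[ms]])
    contrasts[[ms]] <- pairwise_emm(models[[ms]])
  }
  corrected <- baseline_correct(filtered, ws = 1)
  correlation <- tryCatch(correlate_measures(corrected),
                          error = function(e) NULL)
  structure(list(study_table = study, filtered_table = filtered,
                 assumptions = assumptions, models = models, emms = emms,
                 contrasts = contrasts, corrected = corrected,
                 correlation = correlation, log = log),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  cat(sprintf("  study table: %d rows (%d after extreme-point removal)\n",
              nrow(x$study_table), nrow(x$filtered_table)))
  if (!is.null(x$correlation)) {
    cat(sprintf("  yaw~CoP correlation (WS1, baseline-corrected): r = %.3f, p = %.2g, n = %d\n",
                x$correlation$r, x$correlation$p.value, x$correlation$n))
  }
  for (ms in names(x$contrasts)) {
    c1 <- x$contrasts[[ms]]
    led_red <- c1[c1$contrast %in% c("LED - RED", "RED - LED") &
                    c1$walkingSegment == 1, ]
    if (nrow(led_red)) {
      cat(sprintf("  %s LED-RED @WS1: diff = %.3f, Tukey p = %.2g %s\n", ms,
                  led_red$estimate, led_red$p.value, led_red$stars))
    }
  }
  invisible(x)
}

#' Write the report tables to disk
#'
#' @param report a `gait_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$study_table,
                   file.path(out_dir, "study_table.csv"), row.names = FALSE)
  for (ms in names(report$contrasts)) {
    utils::write.csv(report$contrasts[[ms]],
                     file.path(out_dir, paste0("contrasts_", ms, ".csv")),
                     row.names = FALSE)
    utils::write.csv(report$emms[[ms]],
                     file.path(out_dir, paste0("emms_", ms, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    correlation = report$correlation,
    df_method = report$models[[1]]$df_method,
    n_rows = nrow(report$study_table),
    n_removed = attr(report$filtered_table, "n_removed"),
    log = report$log)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Write a small synthetic study fixture to disk
#'
#' Generates a reproducible study (default 4 subjects x 4 conditions x 2
#' repetitions of 60 s walks), writes every trial's five traces as CSV in
#' its own directory together with a ground-truth JSON sidecar, and a
#' `manifest.csv` tying them together.
#'
#' @param out_dir writable directory.
#' @param seed study seed.
#' @param n_subjects,n_reps design size.
#' @param walk_duration_s,n_segments trial shape.
#' @return path to the written manifest CSV.
#' @export
make_fixture <- function(out_dir, seed, n_subjects = 4, n_reps = 2,
                         walk_duration_s = 60, n_segments = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(walk_duration_s = walk_duration_s,
                    n_segments = n_segments, seed = seed)
  man <- list()
  writer <- function(tr, meta) {
    tdir <- sprintf("%s_%s_rep%d", tr$participant, tr$condition,
                    tr$repetition)
    dir.create(file.path(out_dir, tdir), showWarnings = FALSE)
    paths <- list()
    for (nm in c("chest", "ankle_left", "ankle_right", "insole_left",
                 "insole_right")) {
      rel <- file.path(tdir, paste0(nm, ".csv"))
      write_trace(tr[[nm]], file.path(out_dir, rel))
      paths[[nm]] <- rel
    }
    truth_rel <- file.path(tdir, "truth.json")
    jsonlite::write_json(tr$truth, file.path(out_dir, truth_rel),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    man[[length(man) + 1]] <<- data.frame(
      participant = tr$participant, condition = tr$condition,
      repetition = tr$repetition, chest = paths$chest,
      ankle_left = paths$ankle_left, ankle_right = paths$ankle_right,
      insole_left = paths$insole_left, insole_right = paths$insole_right,
      truth = truth_rel)
  }
  simulate_study(cfg, n_subjects = n_subjects, n_reps = n_reps,
                 seed = seed, handler = writer)
  man <- do.call(rbind, man)
  man_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  man_path
}
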