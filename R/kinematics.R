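#' Velocity/acceleration profile of a reaching trial
#'
#' Differentiates the raw cursor samples with central differences on each
#' axis (one-sided at the ends), converts to physical units, and combines
#' the axes: `speed` is the Euclidean norm of `(vx, vy)` in cm/s and
#' `accel` the central-difference derivative of speed in cm/s^2 (signed;
#' negative while decelerating). No smoothing is applied by default - at
#' 100 Hz the logger data are already coarse - but an odd moving-average
#' window can be requested.
#'
#' @param trial A `trajectory_trial` (>= 3 samples, strictly increasing
#'   timestamps).
#' @param px_to_cm Pixel pitch, cm/px.
#' @param smooth_window Odd integer; 1 (default) disables smoothing.
#' @return A list of class `velocity_profile`: `t_ms`, `vx`, `vy`, `speed`
#'   (cm/s), `accel` (cm/s^2), `peak_speed_index`, `px_to_cm`.
#' @export
compute_profile <- function(trial, px_to_cm = screen_geometry()$px_to_cm,
                            smooth_window = 1L) {
  t_ms <- trial$t_ms
  if (length(t_ms) < 3L)
    stop("trial unscorable: fewer than 3 samples", call. = FALSE)
  if (any(diff(t_ms) <= 0))
    stop("invalid input: timestamps must be strictly increasing",
         call. = FALSE)
  x <- trial$x_px * px_to_cm
  y <- trial$y_px * px_to_cm
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L)
      stop("`smooth_window` must be odd", call. = FALSE)
    x <- moving_average(x, smooth_window)
    y <- moving_average(y, smooth_window)
  }
  t_s <- t_ms / 1000
  vx <- central_diff(x, t_s)
  vy <- central_diff(y, t_s)
  speed <- sqrt(vx^2 + vy^2)
  accel <- central_diff(speed, t_s)
  structure(list(t_ms = t_ms, vx = vx, vy = vy, speed = speed,
                 accel = accel, peak_speed_index = which.max(speed),
                 px_to_cm = px_to_cm),
            class = "velocity_profile")
}

# Central differences in the interior, one-sided at the endpoints.
central_diff <- function(v, t) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

moving_average <- function(v, w) {
  half <- (w - 1L) %/% 2L
  out <- stats::filter(v, rep(1 / w, w), sides = 2)
  out <- as.numeric(out)
  # shrink the window at the edges instead of dropping samples
  n <- length(v)
  for (i in seq_len(half)) {
    out[i] <- mean(v[1:(i + half)])
    out[n - i + 1L] <- mean(v[(n - i + 1L - half):n])
  }
  out
}

#' Extract kinematic features from a scored profile
#'
#' Movement onset is the first sample whose speed reaches
#' `threshold_frac` (2% by default) of the peak speed; movement offset is
#' the first sample at or after the peak whose speed falls back to that
#' threshold (the last sample if it never does). Reaction time is measured
#' from stimulus offset to movement onset (`rt_reference = "onset"`
#' switches to stimulus onset). Accuracy is the Euclidean distance in cm
#' from the cursor at movement offset to the target centre. Peak
#' acceleration/deceleration are the extrema of the signed speed
#' derivative over `[onset, offset]`.
#'
#' @param profile A [compute_profile()] result.
#' @param trial The corresponding `trajectory_trial`.
#' @param threshold_frac Fraction of peak speed (default 0.02).
#' @param rt_reference `"offset"` (default, the task convention: stimuli
#'   last 100 ms) or `"onset"`.
#' @return A one-row data frame of class `kinematic_features`:
#'   `peak_velocity` (cm/s), `peak_acceleration`, `peak_deceleration`
#'   (cm/s^2, signed <= 0), `reaction_time` (ms), `accuracy` (cm),
#'   `onset_index`, `offset_index`, `peak_speed_index`.
#' @export
extract_features <- function(profile, trial, threshold_frac = 0.02,
                             rt_reference = c("offset", "onset")) {
  rt_reference <- match.arg(rt_reference)
  out <- as.data.frame(extract_features_impl(profile, trial, threshold_frac,
                                             rt_reference))
  class(out) <- c("kinematic_features", "data.frame")
  out
}

extract_features_impl <- function(profile, trial, threshold_frac,
                                  rt_reference) {
  peak <- max(profile$speed)
  if (!is.finite(peak) || peak <= 0)
    stop("trial unscorable: zero peak speed (no movement)", call. = FALSE)
  thr <- threshold_frac * peak
  ipk <- profile$peak_speed_index
  onset <- which(profile$speed >= thr)[1]
  after <- ipk - 1L + which(profile$speed[ipk:length(profile$speed)] <= thr)
  offset <- if (length(after)) after[1] else length(profile$speed)
  seg <- onset:offset
  ref_ms <- if (rt_reference == "offset") trial$stimulus_offset_ms
            else trial$stimulus_onset_ms
  acc_cm <- sqrt((trial$x_px[offset] - trial$target_x_px)^2 +
                 (trial$y_px[offset] - trial$target_y_px)^2) *
    profile$px_to_cm
  list(peak_velocity = peak,
       peak_acceleration = max(profile$accel[seg]),
       peak_deceleration = min(profile$accel[seg]),
       reaction_time = profile$t_ms[onset] - ref_ms,
       accuracy = acc_cm,
       onset_index = onset, offset_index = offset, peak_speed_index = ipk)
}

#' Screen a trial for erratic movement
#'
#' Automated surrogate for visual trial inspection: counts direction
#' reversals along each axis. The velocity component is split into runs of
#' constant sign; runs whose net displacement exceeds `min_excursion` are
#' kept, and the reversal count is the number of kept runs minus one. The
#' trial is flagged when either axis exceeds `max_reversals`.
#'
#' @param trial A `trajectory_trial`.
#' @param profile Its [compute_profile()] result.
#' @param max_reversals Allowed reversals per axis (default 2).
#' @param min_excursion Minimum run displacement to count, cm (default 0.5).
#' @return List with `anomalous` (logical), `reasons` (character vector of
#'   machine-readable codes, e.g. `"x_reversals=4"`), and the per-axis
#'   counts.
#' @export
flag_anomalous <- function(trial, profile, max_reversals = 2L,
                           min_excursion = 0.5) {
  count_axis <- function(pos_cm) {
    d <- diff(pos_cm)
    d <- d[d != 0]
    if (length(d) == 0L) return(0L)
    r <- rle(sign(d))
    # net displacement of each constant-sign run
    cs <- cumsum(d)
    ends <- cumsum(r$lengths)
    disp <- abs(cs[ends] - c(0, cs[ends[-length(ends)]]))
    max(0L, sum(disp >= min_excursion) - 1L)
  }
  rx <- count_axis(trial$x_px * profile$px_to_cm)
  ry <- count_axis(trial$y_px * profile$px_to_cm)
  reasons <- character(0)
  if (rx > max_reversals) reasons <- c(reasons, sprintf("x_reversals=%d", rx))
  if (ry > max_reversals) reasons <- c(reasons, sprintf("y_reversals=%d", ry))
  list(anomalous = length(reasons) > 0L, reasons = reasons,
       x_reversals = rx, y_reversals = ry)
}

#' Score every trial of a cohort
#'
#' Runs [compute_profile()], [extract_features()] and [flag_anomalous()]
#' on each trial and returns one row per trial.
#'
#' @param cohort A `trajectory_cohort` or list of `trajectory_trial`.
#' @param px_to_cm Pixel pitch.
#' @param threshold_frac,rt_reference See [extract_features()].
#' @param max_reversals,min_excursion See [flag_anomalous()].
#' @return Data frame with participant/phase/trial/cs_type/position, the
#'   kinematic features, and `anomalous` + `anomaly_reasons`.
#' @export
score_kinematics <- function(cohort,
                             px_to_cm = screen_geometry()$px_to_cm,
                             threshold_frac = 0.02,
                             rt_reference = "offset",
                             max_reversals = 2L, min_excursion = 0.5) {
  trials <- if (inherits(cohort, "trajectory_cohort")) cohort$trials else cohort
  rows <- lapply(trials, function(tr) {
    prof <- compute_profile(tr, px_to_cm)
    fe <- extract_features_impl(prof, tr, threshold_frac, rt_reference)
    fl <- flag_anomalous(tr, prof, max_reversals, min_excursion)
    c(list(participant = if (is.null(tr$participant_id)) 1L
                         else tr$participant_id,
           phase = tr$phase, trial = tr$trial_index,
           cs_type = tr$cs_type, position = tr$position),
      fe,
      list(anomalous = fl$anomalous,
           anomaly_reasons = paste(fl$reasons, collapse = ";")))
  })
  # assemble column-wise: one data.frame call instead of one per trial
  nm <- names(rows[[1]])
  out <- as.data.frame(lapply(stats::setNames(nm, nm), function(cn)
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE)
  out
}

KINEMATIC_MEASURES <- c("peak_velocity", "peak_acceleration",
                        "peak_deceleration", "reaction_time", "accuracy")

#' Aggregate per-trial features into condition means
#'
#' Averages unflagged trials within each participant x phase x CS type x
#' position cell, for every kinematic measure. Cells left empty by the
#' anomaly screen yield `NA` (with a warning naming the participant and
#' cell), never a silent zero. Exclusion counts are reported per
#' participant and phase.
#'
#' @param features Output of [score_kinematics()].
#' @return List with `cell_means` (long data frame: participant, phase,
#'   cs_type, position, measure, mean, n_trials) and `exclusions`
#'   (participant, phase, n_excluded, n_trials).
#' @export
aggregate_conditions <- function(features) {
  f <- features
  key <- list(participant = f$participant, phase = f$phase,
              cs_type = f$cs_type, position = f$position)
  keep <- !f$anomalous
  cells <- unique(data.frame(key, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- f$participant == cells$participant[i] &
      f$phase == cells$phase[i] &
      f$cs_type == cells$cs_type[i] &
      f$position == cells$position[i]
    used <- sel & keep
    n_used <- sum(used)
    vals <- if (n_used == 0L) {
      warning(sprintf("participant %s, %s %s/%s: all trials excluded",
                      cells$participant[i], cells$phase[i],
                      cells$cs_type[i], cells$position[i]), call. = FALSE)
      rep(NA_real_, length(KINEMATIC_MEASURES))
    } else {
      vapply(KINEMATIC_MEASURES, function(m) mean(f[[m]][used]), 0)
    }
    data.frame(cells[i, , drop = FALSE],
               measure = KINEMATIC_MEASURES, mean = unname(vals),
               n_trials = n_used, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  cell_means <- do.call(rbind, rows)
  excl <- stats::aggregate(cbind(n_excluded = f$anomalous,
                                 n_trials = rep(1L, nrow(f))),
                           by = list(participant = f$participant,
                                     phase = f$phase), FUN = sum)
  list(cell_means = cell_means, exclusions = excl)
}
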