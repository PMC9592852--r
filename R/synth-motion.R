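#' Motion-simulation parameters
#'
#' Parameters of the synthetic 100 Hz cursor-trajectory generator. The
#' generator produces one continuous reach per trial along a straight path
#' from the start point to the target, with a minimum-jerk time course, so
#' peak speed and peak acceleration have the closed forms `1.875 * D / T`
#' and `~5.7735 * D / T^2` for movement distance `D` and duration `T`.
#'
#' @param base_movement_time Named numeric, movement duration in seconds
#'   for the low/middle/high targets (CS- reference).
#' @param cs_plus_vigor_gain Fractional invigoration for CS+ trials:
#'   the movement time is scaled by `1 - gain`, so peak speed scales by
#'   `1 / (1 - gain)` (0.03 = 3% faster).
#' @param rt_mean,rt_sd Movement-start latency from stimulus onset, ms
#'   (truncated positive normal). Note the task's reaction time is
#'   conventionally reported from stimulus offset, 100 ms later.
#' @param mt_cv Trial-to-trial coefficient of variation of movement time
#'   (lognormal multiplier).
#' @param endpoint_noise_sd Endpoint scatter, cm.
#' @param path_noise_sd Additive per-sample position noise, cm.
#' @param sample_rate Cursor sampling rate, Hz.
#' @param anomaly_rate Probability of injecting an erratic trial (several
#'   alternating lateral excursions), used to exercise the anomaly screen.
#' @param anomaly_amplitude_cm Lateral excursion amplitude of injected
#'   erratic trials, cm.
#' @param tail_s Stationary recording tail after movement end, s.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(base_movement_time = c(low = 0.50, middle = 0.55,
                                                 high = 0.60),
                          cs_plus_vigor_gain = 0.03,
                          rt_mean = 330, rt_sd = 50,
                          mt_cv = 0.10,
                          endpoint_noise_sd = 0.3,
                          path_noise_sd = 0.02,
                          sample_rate = 100,
                          anomaly_rate = 0,
                          anomaly_amplitude_cm = 2,
                          tail_s = 0.1) {
  stopifnot(all(base_movement_time > 0), sample_rate > 0,
            anomaly_rate >= 0, anomaly_rate < 1, rt_mean > 0)
  if (is.null(names(base_movement_time)))
    names(base_movement_time) <- c("low", "middle", "high")
  p <- list(base_movement_time = base_movement_time,
            cs_plus_vigor_gain = cs_plus_vigor_gain,
            rt_mean = rt_mean, rt_sd = rt_sd, mt_cv = mt_cv,
            endpoint_noise_sd = endpoint_noise_sd,
            path_noise_sd = path_noise_sd,
            sample_rate = sample_rate,
            anomaly_rate = anomaly_rate,
            anomaly_amplitude_cm = anomaly_amplitude_cm,
            tail_s = tail_s)
  class(p) <- "motion_params"
  p
}

#' Minimum-jerk position along a straight segment
#'
#' Displacement fraction `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` with
#' `tau = t / T`; `t` outside `[0, T]` is clamped to the endpoints.
#'
#' @param t Time(s), same units as `T`; vectorised.
#' @param T_move Movement duration (> 0).
#' @param start,end Numeric length-2 points.
#' @return A length(t) x 2 matrix of positions.
#' @export
minimum_jerk_position <- function(t, T_move, start, end) {
  stopifnot(T_move > 0, length(start) == 2L, length(end) == 2L)
  tau <- pmin(pmax(t / T_move, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  cbind(start[1] + s * (end[1] - start[1]),
        start[2] + s * (end[2] - start[2]))
}

# Closed-form profile peaks of the minimum-jerk segment.
min_jerk_peak_speed <- function(D, T_move) 1.875 * D / T_move
min_jerk_peak_accel <- function(D, T_move) {
  tau <- (360 - sqrt(360^2 - 4 * 360 * 60)) / 720  # argmax of s''(tau)
  (60 * tau - 180 * tau^2 + 120 * tau^3) * D / T_move^2
}

#' Simulate one reaching trial
#'
#' Timeline (ms since stimulus onset): the stimulus appears at 0 and lasts
#' `stim_duration_s` from the trial spec; the cursor stays on the start
#' point until a latency drawn from the truncated normal
#' `(rt_mean, rt_sd)`, then executes a minimum-jerk reach whose duration is
#' the position's base movement time, scaled by `1 - cs_plus_vigor_gain`
#' for CS+ trials and by a lognormal trial-to-trial factor (`mt_cv`).
#' Gaussian path noise is added to every sample and the endpoint is
#' perturbed by `endpoint_noise_sd`. With probability `anomaly_rate` the
#' trial is made erratic: three alternating lateral excursions are
#' superimposed on the path.
#'
#' @param spec One row of a reaching-phase `trial_schedule`.
#' @param params A [motion_params()] object.
#' @param px_to_cm Pixel pitch used to express noise in px; defaults to the
#'   standard screen.
#' @param vigor_gain Optional participant-specific override of
#'   `params$cs_plus_vigor_gain`.
#' @return A list of class `trajectory_trial`: `t_ms`, `x_px`, `y_px`,
#'   `stimulus_onset_ms` (0), `stimulus_offset_ms`, plus the spec fields
#'   and the injected `latency_ms`/`movement_time_s`/`anomalous_injected`
#'   ground truth.
#' @export
simulate_reach <- function(spec, params = motion_params(),
                           px_to_cm = screen_geometry()$px_to_cm,
                           vigor_gain = NULL) {
  if (spec$stim_duration_s > 1)
    stop("`spec` must belong to a reaching phase", call. = FALSE)
  gain <- if (is.null(vigor_gain)) params$cs_plus_vigor_gain else vigor_gain
  lay <- task_layout()
  start <- lay$start
  target <- c(spec$target_x_px, spec$target_y_px)

  latency_ms <- rnorm_pos(1L, params$rt_mean, params$rt_sd)
  T_move <- unname(params$base_movement_time[spec$position])
  if (spec$cs_type == "CS+") T_move <- T_move * (1 - gain)
  if (params$mt_cv > 0)
    T_move <- T_move * stats::rlnorm(1L, -params$mt_cv^2 / 2, params$mt_cv)

  dt_ms <- 1000 / params$sample_rate
  total_ms <- latency_ms + 1000 * (T_move + params$tail_s)
  t_ms <- seq(0, total_ms, by = dt_ms)

  end <- target
  if (params$endpoint_noise_sd > 0)
    end <- end + stats::rnorm(2L, 0, params$endpoint_noise_sd / px_to_cm)

  pos <- minimum_jerk_position((t_ms - latency_ms) / 1000, T_move, start, end)

  anomalous <- params$anomaly_rate > 0 &&
    stats::runif(1L) < params$anomaly_rate
  if (anomalous) {
    # three alternating left/right excursions during the movement
    tau <- pmin(pmax((t_ms - latency_ms) / 1000 / T_move, 0), 1)
    wiggle <- sin(3 * pi * tau) * (params$anomaly_amplitude_cm / px_to_cm)
    pos[, 1] <- pos[, 1] + wiggle * sin(pi * tau)  # zero at both ends
  }
  if (params$path_noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(length(pos), 0,
                                     params$path_noise_sd / px_to_cm),
                        ncol = 2L)

  out <- list(t_ms = t_ms, x_px = pos[, 1], y_px = pos[, 2],
              stimulus_onset_ms = 0,
              stimulus_offset_ms = 1000 * spec$stim_duration_s,
              phase = spec$phase, trial_index = spec$trial_index,
              cs_type = spec$cs_type, position = spec$position,
              target_x_px = spec$target_x_px, target_y_px = spec$target_y_px,
              latency_ms = latency_ms, movement_time_s = T_move,
              anomalous_injected = anomalous)
  class(out) <- "trajectory_trial"
  out
}

#' Simulate a cohort of reaching participants
#'
#' Applies [simulate_reach()] to every trial of every schedule for
#' `n_participants` participants, with per-participant random effects: a
#' lognormal movement-time multiplier (`subject_mt_cv`) and a normal
#' deviation of the CS+ vigor gain (`subject_gain_sd`), unless explicit
#' per-participant `vigor_gains` are supplied (used by the pipeline to
#' plant a cross-participant coupling between sympathetic and kinematic
#' conditioned responses). Deterministic given `seed`.
#'
#' @param schedules A `trial_schedule` or list of them (reaching phases).
#' @param params [motion_params()].
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed.
#' @param subject_mt_cv,subject_gain_sd Random-effect scales.
#' @param vigor_gains Optional numeric vector of length `n_participants`.
#' @param px_to_cm Pixel pitch.
#' @return List of class `trajectory_cohort`: `trials` (list of
#'   `trajectory_trial`, each carrying `participant_id`), `vigor_gains`,
#'   `n_participants`.
#' @export
simulate_cohort <- function(schedules, params = motion_params(),
                            n_participants = 1, seed = 1,
                            subject_mt_cv = 0.15, subject_gain_sd = 0.02,
                            vigor_gains = NULL,
                            px_to_cm = screen_geometry()$px_to_cm) {
  stopifnot(n_participants >= 1)
  if (inherits(schedules, "trial_schedule")) schedules <- list(schedules)
  with_seed(seed, {
    mt_mult <- stats::rlnorm(n_participants, -subject_mt_cv^2 / 2,
                             subject_mt_cv)
    if (is.null(vigor_gains))
      vigor_gains <- stats::rnorm(n_participants,
                                  params$cs_plus_vigor_gain, subject_gain_sd)
    trials <- vector("list",
                     n_participants * sum(vapply(schedules, nrow, 0L)))
    k <- 0L
    for (p in seq_len(n_participants)) {
      pp <- params
      pp$base_movement_time <- params$base_movement_time * mt_mult[p]
      for (sched in schedules) {
        for (i in seq_len(nrow(sched))) {
          tr <- simulate_reach(sched[i, ], pp, px_to_cm = px_to_cm,
                               vigor_gain = vigor_gains[p])
          tr$participant_id <- p
          k <- k + 1L
          trials[[k]] <- tr
        }
      }
    }
  })
  structure(list(trials = trials, vigor_gains = vigor_gains,
                 n_participants = n_participants, seed = seed),
            class = "trajectory_cohort")
}

#' Long-format trajectory I/O
#'
#' Mirrors mouse-tracking logger exports: one row per sample with columns
#' `participant`, `phase`, `trial`, `cs_type`, `position`, `t_ms`, `x_px`,
#' `y_px`, plus `stimulus_offset_ms` carried per trial.
#'
#' @param cohort A `trajectory_cohort` (or list of `trajectory_trial`).
#' @param path CSV path.
#' @return `trajectories_to_df` returns the long data frame;
#'   `write_trajectories_csv` returns `path` invisibly;
#'   `read_trajectories_csv` returns a list of `trajectory_trial`.
#' @export
trajectories_to_df <- function(cohort) {
  trials <- if (inherits(cohort, "trajectory_cohort")) cohort$trials else cohort
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant = if (is.null(tr$participant_id)) 1L else tr$participant_id,
               phase = tr$phase, trial = tr$trial_index,
               cs_type = tr$cs_type, position = tr$position,
               target_x_px = tr$target_x_px, target_y_px = tr$target_y_px,
               stimulus_offset_ms = tr$stimulus_offset_ms,
               t_ms = tr$t_ms, x_px = tr$x_px, y_px = tr$y_px,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname trajectories_to_df
#' @export
write_trajectories_csv <- function(cohort, path) {
  utils::write.csv(trajectories_to_df(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trajectories_to_df
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "phase", "trial", "cs_type", "position",
            "target_x_px", "target_y_px", "stimulus_offset_ms",
            "t_ms", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df_to_trials(df)
}

df_to_trials <- function(df) {
  key <- interaction(df$participant, df$phase, df$trial, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t_ms), ]
    structure(list(t_ms = d$t_ms, x_px = d$x_px, y_px = d$y_px,
                   stimulus_onset_ms = 0,
                   stimulus_offset_ms = d$stimulus_offset_ms[1],
                   phase = d$phase[1], trial_index = d$trial[1],
                   cs_type = d$cs_type[1], position = d$position[1],
                   target_x_px = d$target_x_px[1],
                   target_y_px = d$target_y_px[1],
                   participant_id = d$participant[1]),
              class = "trajectory_trial")
  })
}
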