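#' Skin-conductance simulation parameters
#'
#' The synthetic electrodermal signal is a tonic level plus a slow
#' random-walk drift, event-related phasic responses, and white measurement
#' noise. Each CS presentation triggers a phasic response of biexponential
#' (Bateman) shape starting `latency_s` after CS onset, with amplitude
#' drawn from a truncated normal whose mean depends on the CS type. The
#' default amplitude means (0.60 vs 0.26 microsiemens) are typical
#' conditioned-response group means for this paradigm, so simulated
#' cohorts land near published effect sizes.
#'
#' @param sample_rate Acquisition rate, Hz (default 1250).
#' @param tonic_level Baseline conductance, microsiemens.
#' @param drift_sd Random-walk innovation SD, microsiemens per sqrt(s).
#' @param amp_cs_plus,amp_cs_minus Mean phasic amplitude per CS type,
#'   microsiemens.
#' @param amp_sd Trial-to-trial amplitude SD, microsiemens.
#' @param latency_s CS onset to response-trough delay, s; the default
#'   (1.5 s) sits inside the 0.5-4.5 s scoring validity window so noiseless
#'   responses are always scoreable.
#' @param rise_tau,decay_tau Shape constants of the Bateman kernel, s
#'   (`rise_tau < decay_tau`).
#' @param noise_sd White measurement-noise SD, microsiemens.
#' @param habituation Optional linear amplitude decay per trial (fraction
#'   of the mean amplitude; 0 disables).
#' @return A list of class `scr_params`.
#' @export
scr_params <- function(sample_rate = 1250,
                       tonic_level = 5,
                       drift_sd = 0.005,
                       amp_cs_plus = 0.60, amp_cs_minus = 0.26,
                       amp_sd = 0.15,
                       latency_s = 1.5,
                       rise_tau = 0.75, decay_tau = 2,
                       noise_sd = 0.005,
                       habituation = 0) {
  stopifnot(sample_rate > 0, amp_cs_plus >= 0, amp_cs_minus >= 0,
            rise_tau < decay_tau, rise_tau > 0)
  p <- list(sample_rate = sample_rate, tonic_level = tonic_level,
            drift_sd = drift_sd, amp_cs_plus = amp_cs_plus,
            amp_cs_minus = amp_cs_minus, amp_sd = amp_sd,
            latency_s = latency_s, rise_tau = rise_tau,
            decay_tau = decay_tau, noise_sd = noise_sd,
            habituation = habituation)
  class(p) <- "scr_params"
  p
}

#' Biexponential phasic response kernel
#'
#' `k(t) = exp(-t/decay_tau) - exp(-t/rise_tau)` for `t >= 0` (0
#' otherwise), normalized to unit peak; the peak sits at
#' `log(decay_tau/rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)`.
#'
#' @param t Time since response onset, s (vectorised).
#' @param rise_tau,decay_tau Shape constants, s (`rise_tau < decay_tau`).
#' @return Unitless amplitudes with unit peak.
#' @export
phasic_kernel <- function(t, rise_tau = 0.75, decay_tau = 2) {
  stopifnot(rise_tau > 0, rise_tau < decay_tau)
  k <- ifelse(t >= 0, exp(-t / decay_tau) - exp(-t / rise_tau), 0)
  k / phasic_kernel_peak(rise_tau, decay_tau)$value
}

phasic_kernel_peak <- function(rise_tau, decay_tau) {
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  list(t = t_peak,
       value = exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau))
}

#' Simulate a continuous skin-conductance trace for a Pavlovian phase
#'
#' Event times follow the schedule's pre-stimulus jitters, 6 s stimulus
#' durations and inter-trial intervals. Per-trial phasic amplitudes are
#' `Normal(amp_cs_type, amp_sd)` truncated at zero; the response starts
#' `latency_s` after CS onset. Deterministic given `seed`.
#'
#' @param schedule A Pavlovian `trial_schedule`.
#' @param params [scr_params()].
#' @param seed Integer seed.
#' @param amp_means Optional named override of the amplitude means, e.g.
#'   `c("CS+" = 0.7, "CS-" = 0.2)` (used for participant random effects).
#' @return A list of class `scr_trace`: `t_s`, `conductance_uS`,
#'   `sample_rate`, and `events` (data frame `cs_onset_s`, `cs_type`,
#'   `trial_index`, plus injected ground-truth `amplitude_uS`).
#' @export
simulate_scr_trace <- function(schedule, params = scr_params(), seed = 1,
                               amp_means = NULL) {
  if (!all(schedule$phase == "pavlovian"))
    stop("`schedule` must be a pavlovian phase", call. = FALSE)
  if (is.null(amp_means))
    amp_means <- c("CS+" = params$amp_cs_plus, "CS-" = params$amp_cs_minus)
  fs <- params$sample_rate
  n_tr <- nrow(schedule)

  # event timeline
  onsets <- numeric(n_tr)
  t0 <- 0
  for (i in seq_len(n_tr)) {
    t0 <- t0 + schedule$pre_stim_s[i]
    onsets[i] <- t0
    t0 <- t0 + schedule$stim_duration_s[i] + schedule$iti_s[i]
  }
  total_s <- t0 + 10  # room to score the last trial
  n <- floor(total_s * fs) + 1L
  t_s <- (seq_len(n) - 1L) / fs

  with_seed(seed, {
    amps <- rnorm_pos(n_tr, amp_means[schedule$cs_type], params$amp_sd)
    if (params$habituation > 0)
      amps <- amps * pmax(0, 1 - params$habituation * (seq_len(n_tr) - 1L))
    if (params$amp_sd == 0) amps <- unname(amp_means[schedule$cs_type])
    g <- rep(params$tonic_level, n)
    if (params$drift_sd > 0)
      g <- g + cumsum(stats::rnorm(n, 0, params$drift_sd / sqrt(fs)))
    # add each phasic response over a finite support window
    kern_len <- ceiling((params$latency_s + 8 * params$decay_tau) * fs)
    for (i in seq_len(n_tr)) {
      i0 <- floor((onsets[i] + params$latency_s) * fs) + 1L
      idx <- i0:min(i0 + kern_len, n)
      tt <- t_s[idx] - (onsets[i] + params$latency_s)
      g[idx] <- g[idx] + amps[i] * phasic_kernel(tt, params$rise_tau,
                                                 params$decay_tau)
    }
    if (params$noise_sd > 0)
      g <- g + stats::rnorm(n, 0, params$noise_sd)
  })

  structure(list(t_s = t_s, conductance_uS = g, sample_rate = fs,
                 events = data.frame(cs_onset_s = onsets,
                                     cs_type = schedule$cs_type,
                                     trial_index = schedule$trial_index,
                                     amplitude_uS = amps,
                                     stringsAsFactors = FALSE)),
            class = "scr_trace")
}

#' Skin-conductance trace I/O
#'
#' Signal CSV has columns `t_s`, `conductance_uS`; events CSV has
#' `cs_onset_s`, `cs_type` (and optionally `trial_index`).
#'
#' @param trace An `scr_trace`.
#' @param signal_path,events_path CSV paths.
#' @return `read_scr_csv` returns an `scr_trace`; the writer returns
#'   `signal_path` invisibly.
#' @export
write_scr_csv <- function(trace, signal_path, events_path) {
  utils::write.csv(data.frame(t_s = trace$t_s,
                              conductance_uS = trace$conductance_uS),
                   signal_path, row.names = FALSE)
  ev <- trace$events
  ev$amplitude_uS <- NULL  # ground truth never leaves the simulator
  utils::write.csv(ev, events_path, row.names = FALSE)
  invisible(signal_path)
}

#' @rdname write_scr_csv
#' @export
read_scr_csv <- function(signal_path, events_path) {
  sig <- utils::read.csv(signal_path)
  if (!all(c("t_s", "conductance_uS") %in% names(sig)))
    stop("signal file must have columns t_s, conductance_uS", call. = FALSE)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  if (!all(c("cs_onset_s", "cs_type") %in% names(ev)))
    stop("events file must have columns cs_onset_s, cs_type", call. = FALSE)
  if (is.null(ev$trial_index)) ev$trial_index <- seq_len(nrow(ev))
  n <- nrow(sig)
  fs <- (n - 1) / (sig$t_s[n] - sig$t_s[1])
  if (abs(fs - round(fs)) < 1e-3) fs <- round(fs)  # undo CSV rounding
  structure(list(t_s = sig$t_s, conductance_uS = sig$conductance_uS,
                 sample_rate = fs, events = ev),
            class = "scr_trace")
}
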