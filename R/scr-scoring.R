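#' Preprocess a continuous skin-conductance trace
#'
#' Anti-aliased decimation to `target_rate` (200 Hz by default): a
#' zero-phase 4th-order Butterworth low-pass at 80% of the target Nyquist
#' frequency, followed by linear interpolation onto the uniform target
#' grid. When `lowpass_10hz = TRUE` (for signals not already filtered at
#' acquisition) an additional zero-phase 10 Hz Butterworth low-pass is
#' applied first.
#'
#' @param trace An `scr_trace`.
#' @param target_rate Output rate, Hz; must not exceed the input rate.
#' @param lowpass_10hz Apply the 10 Hz low-pass (default `FALSE`:
#'   acquisition-filtered input assumed).
#' @return An `scr_trace` at `target_rate` with the same events.
#' @export
preprocess_scr <- function(trace, target_rate = 200, lowpass_10hz = FALSE) {
  fs <- trace$sample_rate
  if (fs < target_rate)
    stop("invalid input: input rate (", fs, " Hz) below target rate (",
         target_rate, " Hz)", call. = FALSE)
  g <- trace$conductance_uS
  if (lowpass_10hz) {
    bf <- signal::butter(4, 10 / (fs / 2), type = "low")
    g <- zero_phase_filter(bf, g)
  }
  if (fs > target_rate) {
    bf <- signal::butter(4, 0.8 * (target_rate / 2) / (fs / 2), type = "low")
    g <- zero_phase_filter(bf, g)
    t_new <- seq(trace$t_s[1], trace$t_s[length(trace$t_s)],
                 by = 1 / target_rate)
    g <- stats::approx(trace$t_s, g, xout = t_new)$y
  } else {
    t_new <- trace$t_s
  }
  structure(list(t_s = t_new, conductance_uS = g,
                 sample_rate = target_rate, events = trace$events),
            class = "scr_trace")
}

# Zero-phase filtering with odd-reflection edge padding, so constant or
# slowly varying signals are not distorted by the filter's zero initial
# conditions at either end.
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 1000L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

# Alternating significant extrema of a signal. Plateaus are absorbed into
# the following movement; adjacent extrema closer than `prominence` in
# amplitude are merged away (zigzag simplification), so measurement
# ripples do not fragment a deflection.
significant_extrema <- function(g, prominence) {
  s <- sign(diff(g))
  nz <- which(s != 0)
  if (length(nz) == 0L)
    return(list(index = integer(), type = character()))
  filled <- s
  if (length(nz) < length(s)) {
    # carry the last nonzero slope forward across flats
    idx <- cumsum(s != 0)
    filled <- c(0, s[nz])[idx + 1L]
  }
  # slope-sign changes mark the extrema
  chg <- filled != 0 & c(TRUE, filled[-length(filled)] != filled[-1])
  ext_idx <- which(chg)
  ext_type <- ifelse(filled[ext_idx] > 0, "min", "max")
  if (filled[length(filled)] > 0) {       # closing maximum at the end
    ext_idx <- c(ext_idx, length(g))
    ext_type <- c(ext_type, "max")
  }
  if (length(ext_idx) && ext_type[1] == "max") {
    ext_idx <- c(1L, ext_idx); ext_type <- c("min", ext_type)
  }
  # Merge sub-prominence wiggles: a segment between adjacent extrema may
  # be removed only when it is a locally smallest counter-movement (not
  # larger than either neighbouring segment) - removing such a pair merges
  # two same-direction segments into a larger valid one, so a gradual rise
  # carried by many small ripples consolidates instead of vanishing.
  # Locally smallest removals are disjoint, so they batch per pass.
  while (length(ext_idx) >= 2L) {
    amp <- abs(diff(g[ext_idx]))
    m <- length(amp)
    ok <- amp < prominence &
      amp <= c(Inf, amp[-m]) & amp <= c(amp[-1], Inf)
    bad <- which(ok)
    if (length(bad) == 0L) break
    drop <- integer(0)
    last <- 0L
    for (j in bad) {           # greedy left-to-right, pairs must not overlap
      if (j > last) { drop <- c(drop, j, j + 1L); last <- j + 1L }
    }
    ext_idx <- ext_idx[-drop]
    ext_type <- ext_type[-drop]
  }
  list(index = ext_idx, type = ext_type)
}

#' Score one CS presentation trough-to-peak
#'
#' Finds candidate deflections (local trough paired with the highest
#' subsequent local maximum within the rise window, so residual ripples on
#' a rise do not truncate it) on the preprocessed signal and applies the
#' validity rules in
#' order: the deflection must start between `window[1]` and `window[2]` s
#' after CS onset (inclusive bounds), the trough-to-peak rise must last at
#' most `max_rise` s, and the amplitude must exceed `min_amp`
#' microsiemens. The deflection start is bracketed between the raw signal
#' minimum and the foot of the rise (the last pre-peak sample within a
#' small tolerance of the minimum) - slow baseline drift can place the
#' minimum long before the phasic response begins - and either landing in
#' the window satisfies the window rule; the amplitude is always measured
#' from the minimum itself.
#' Trials failing any rule score zero, with the first failing rule as the
#' reason; when several deflections qualify the largest amplitude wins,
#' ties going to the earliest trough.
#'
#' @param trace A (preprocessed) `scr_trace`.
#' @param cs_onset CS onset, s from trace start.
#' @param window Validity window for the trough onset, s after CS onset.
#' @param max_rise Maximum trough-to-peak rise time, s.
#' @param min_amp Minimum amplitude, microsiemens (amplitude must be
#'   strictly greater).
#' @return A one-row data frame of class `scr_score`: `amplitude_uS`
#'   (0 when invalid), `trough_t_s`, `peak_t_s` (`NA` when zero-scored),
#'   `valid`, `zero_reason` in
#'   `c("none", "no_deflection", "outside_window", "too_long", "too_small")`.
#' @export
score_scr_trial <- function(trace, cs_onset, window = c(0.5, 4.5),
                            max_rise = 5, min_amp = 0.02) {
  out <- as.data.frame(score_scr_trial_impl(trace, cs_onset, window,
                                            max_rise, min_amp))
  class(out) <- c("scr_score", "data.frame")
  out
}

score_scr_trial_impl <- function(trace, cs_onset, window, max_rise,
                                 min_amp) {
  t_end <- cs_onset + window[2] + max_rise
  nt <- length(trace$t_s)
  if (trace$t_s[nt] < t_end - 1e-9)
    stop("trial unscorable: trace ends before the scoring window",
         call. = FALSE)
  # uniform sampling: locate the window arithmetically
  fs <- trace$sample_rate
  i0 <- max(1L, as.integer(ceiling((cs_onset - trace$t_s[1]) * fs - 1e-9)) + 1L)
  i1 <- min(nt, as.integer(floor((t_end - trace$t_s[1]) * fs + 1e-9)) + 1L)
  sel <- i0:i1
  g <- trace$conductance_uS[sel]
  tt <- trace$t_s[sel]

  zero <- function(reason)
    list(amplitude_uS = 0, trough_t_s = NA_real_, peak_t_s = NA_real_,
         valid = FALSE, zero_reason = reason)

  ext <- significant_extrema(g, prominence = min_amp / 2)
  # pair each trough with the highest subsequent maximum inside the rise
  # window (residual ripples must not truncate a deflection); when no
  # maximum falls inside the window, the first one beyond it stands in so
  # the rise-time rule can reject the pair explicitly
  mins <- which(ext$type == "min")
  maxs <- which(ext$type == "max")
  mins <- mins[vapply(mins, function(j) any(maxs > j), TRUE)]
  if (length(mins) == 0L) return(zero("no_deflection"))
  picked <- vapply(mins, function(j) {
    after <- maxs[maxs > j]
    in_rise <- after[tt[ext$index[after]] - tt[ext$index[j]] <=
                       max_rise + 1e-9]
    if (length(in_rise)) in_rise[which.max(g[ext$index[in_rise]])]
    else after[1]
  }, 0L)
  # A deflection's start is bracketed by the raw signal minimum and the
  # foot of the rise (last pre-peak sample within a small tolerance of the
  # minimum): slow baseline drift can place the minimum well before the
  # phasic response begins. Either point landing inside the validity
  # window counts as an in-window onset; the amplitude is always measured
  # from the minimum itself.
  ti <- ext$index[mins]
  pi <- ext$index[picked]
  amp <- g[pi] - g[ti]
  foot_i <- mapply(function(a, b, A) {
    tol <- min(min_amp / 2, A / 4)
    seg <- g[a:b]
    a - 1L + max(which(seg <= seg[1] + tol))
  }, ti, pi, amp)
  raw_t <- tt[ti]
  foot_t <- tt[foot_i]
  peak_t <- tt[pi]

  in_win <- function(t) {
    lat <- t - cs_onset
    lat >= window[1] - 1e-9 & lat <= window[2] + 1e-9
  }
  keep <- in_win(raw_t) | in_win(foot_t)
  if (!any(keep)) return(zero("outside_window"))
  # report the raw minimum when it is in the window, the foot otherwise
  trough_t <- ifelse(in_win(raw_t), raw_t, foot_t)[keep]
  peak_t <- peak_t[keep]; amp <- amp[keep]
  keep <- (peak_t - trough_t) <= max_rise + 1e-9
  if (!any(keep)) return(zero("too_long"))
  trough_t <- trough_t[keep]; peak_t <- peak_t[keep]; amp <- amp[keep]
  best <- which(amp == max(amp))
  best <- best[which.min(trough_t[best])]
  if (!(amp[best] > min_amp)) return(zero("too_small"))
  list(amplitude_uS = amp[best], trough_t_s = trough_t[best],
       peak_t_s = peak_t[best], valid = TRUE, zero_reason = "none")
}

#' Score all CS presentations of a trace
#'
#' Convenience wrapper: [preprocess_scr()] (unless the trace is already at
#' `target_rate`) then [score_scr_trial()] for each event.
#'
#' @param trace An `scr_trace` with an `events` table.
#' @param target_rate Scoring rate, Hz.
#' @param lowpass_10hz Apply the 10 Hz low-pass during preprocessing; use
#'   for signals not already filtered at acquisition (the synthetic
#'   generator's output is unfiltered).
#' @param window,max_rise,min_amp Validity rules, as in
#'   [score_scr_trial()].
#' @return Data frame: one row per event with `trial_index`, `cs_type`,
#'   and the `scr_score` columns.
#' @export
score_scr_phase <- function(trace, target_rate = 200, lowpass_10hz = FALSE,
                            window = c(0.5, 4.5), max_rise = 5,
                            min_amp = 0.02) {
  if (trace$sample_rate > target_rate || lowpass_10hz)
    trace <- preprocess_scr(trace, target_rate, lowpass_10hz = lowpass_10hz)
  rows <- lapply(trace$events$cs_onset_s, score_scr_trial_impl,
                 trace = trace, window = window, max_rise = max_rise,
                 min_amp = min_amp)
  data.frame(trial_index = trace$events$trial_index,
             cs_type = trace$events$cs_type,
             amplitude_uS = vapply(rows, `[[`, 0, "amplitude_uS"),
             trough_t_s = vapply(rows, `[[`, 0, "trough_t_s"),
             peak_t_s = vapply(rows, `[[`, 0, "peak_t_s"),
             valid = vapply(rows, `[[`, TRUE, "valid"),
             zero_reason = vapply(rows, `[[`, "", "zero_reason"),
             stringsAsFactors = FALSE)
}

#' Per-participant SCR condition means and CS differential
#'
#' Zero-scored trials enter the means as zeros (they are scored, not
#' missing). The differential is the CS type marginal difference
#' `mean(CS+) - mean(CS-)`.
#'
#' @param scores Output of [score_scr_phase()].
#' @param schedule The Pavlovian `trial_schedule` (supplies positions).
#' @return List with `cell_means` (cs_type, position, mean_amplitude_uS,
#'   n_trials), `cs_means` (marginals) and `differential_uS`.
#' @export
participant_scr_summary <- function(scores, schedule) {
  m <- merge(scores,
             schedule[, c("trial_index", "position")], by = "trial_index")
  cells <- stats::aggregate(list(mean_amplitude_uS = m$amplitude_uS),
                            by = list(cs_type = m$cs_type,
                                      position = m$position), FUN = mean)
  cells$n_trials <- stats::aggregate(list(n = m$amplitude_uS),
                                     by = list(cs_type = m$cs_type,
                                               position = m$position),
                                     FUN = length)$n
  cs <- stats::aggregate(list(mean_amplitude_uS = m$amplitude_uS),
                         by = list(cs_type = m$cs_type), FUN = mean)
  diff_uS <- cs$mean_amplitude_uS[cs$cs_type == "CS+"] -
    cs$mean_amplitude_uS[cs$cs_type == "CS-"]
  list(cell_means = cells, cs_means = cs, differential_uS = diff_uS)
}
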