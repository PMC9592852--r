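# Independent oracles and fixture builders, kept deliberately separate from
# the implementation paths they check.

# Peak of the minimum-jerk speed profile by numerical maximisation of the
# displacement-fraction derivative s'(tau) = 30 tau^2 (1 - tau)^2.
oracle_min_jerk_peak_speed <- function(D, T_move) {
  f <- function(tau) 30 * tau^2 * (1 - tau)^2
  opt <- optimize(f, c(0, 1), maximum = TRUE)
  D / T_move * opt$objective
}

# Peak of the second derivative s''(tau), numerically.
oracle_min_jerk_peak_accel <- function(D, T_move) {
  f <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3
  opt <- optimize(f, c(0, 1), maximum = TRUE)
  D / T_move^2 * opt$objective
}

# Continuous time (relative to movement start) at which speed first reaches
# `frac` of its peak: solve 30 tau^2 (1-tau)^2 = frac * 1.875.
oracle_threshold_crossing <- function(frac, T_move) {
  g <- function(tau) 30 * tau^2 * (1 - tau)^2 - frac * 1.875
  uniroot(g, c(1e-9, 0.5), tol = 1e-12)$root * T_move
}

# Greenhouse-Geisser epsilon straight from the eigenvalues of the
# double-centred covariance matrix (direct-formula route).
oracle_gg_epsilon <- function(scores) {
  S <- cov(scores)
  k <- ncol(S)
  J <- diag(k) - matrix(1 / k, k, k)
  lam <- eigen(J %*% S %*% J, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

# A deterministic noiseless reaching trial with known latency and duration.
make_noiseless_trial <- function(position = "middle", cs_type = "CS-",
                                 latency_ms = 330, T_move = 0.5,
                                 sample_rate = 100, seed = 1) {
  sched <- generate_reaching_schedule(1, seed = seed)
  spec <- sched[sched$position == position, ][1, ]
  spec$cs_type <- cs_type
  bt <- c(low = T_move, middle = T_move, high = T_move)
  params <- motion_params(base_movement_time = bt, cs_plus_vigor_gain = 0,
                          rt_mean = latency_ms, rt_sd = 0, mt_cv = 0,
                          endpoint_noise_sd = 0, path_noise_sd = 0,
                          sample_rate = sample_rate, anomaly_rate = 0)
  set.seed(seed)
  simulate_reach(spec, params)
}

# Synthetic single-response SCR trace on a flat baseline, sampled at `fs`,
# with one biexponential response of amplitude `amp` starting `latency_s`
# after a CS onset at `onset_s`. Built directly (not via the generator) so
# the scorer tests do not depend on the simulator.
make_single_response_trace <- function(amp, latency_s = 1.5, onset_s = 5,
                                       fs = 200, total_s = 30, tonic = 5,
                                       rise_tau = 0.75, decay_tau = 2) {
  t_s <- seq(0, total_s, by = 1 / fs)
  t0 <- onset_s + latency_s
  g <- rep(tonic, length(t_s))
  idx <- t_s >= t0
  g[idx] <- tonic + amp * phasic_kernel(t_s[idx] - t0, rise_tau, decay_tau)
  structure(list(t_s = t_s, conductance_uS = g, sample_rate = fs,
                 events = data.frame(cs_onset_s = onset_s, cs_type = "CS+",
                                     trial_index = 1L)),
            class = "scr_trace")
}

px_cm <- screen_geometry()$px_to_cm
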