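test_that("profiles reject degenerate input and handle uniform motion", {
  tr <- list(t_ms = c(0, 10), x_px = c(0, 0), y_px = c(0, 1))
  expect_error(compute_profile(tr), "fewer than 3")
  tr2 <- list(t_ms = c(0, 10, 10, 20), x_px = rep(0, 4), y_px = 0:3)
  expect_error(compute_profile(tr2), "strictly increasing")

  # uniform 100 px/s along y at 0.05 cm/px is 5 cm/s with zero acceleration
  t_ms <- seq(0, 1000, by = 10)
  tr3 <- list(t_ms = t_ms, x_px = rep(0, length(t_ms)), y_px = t_ms / 10)
  prof <- compute_profile(tr3, px_to_cm = 0.05)
  expect_equal(prof$speed, rep(5, length(t_ms)), tolerance = 1e-10)
  expect_equal(max(abs(prof$accel)), 0, tolerance = 1e-8)

  # stationary cursor: speed identically zero, trial unscorable
  tr4 <- list(t_ms = t_ms, x_px = rep(1, length(t_ms)),
              y_px = rep(2, length(t_ms)),
              stimulus_offset_ms = 100, target_x_px = 0, target_y_px = 0)
  prof4 <- compute_profile(tr4, px_to_cm = 0.05)
  expect_true(all(prof4$speed == 0))
  expect_error(extract_features(prof4, tr4), "zero peak speed")
})

test_that("noiseless minimum-jerk trials score at their closed forms", {
  latency <- 330; T_move <- 0.5
  tr <- make_noiseless_trial(position = "high", latency_ms = latency,
                             T_move = T_move)
  prof <- compute_profile(tr)
  fe <- extract_features(prof, tr)
  D <- sqrt(sum((c(tr$target_x_px, tr$target_y_px) - c(0, -416))^2)) * px_cm

  expect_equal(fe$peak_velocity, oracle_min_jerk_peak_speed(D, T_move),
               tolerance = 0.02)
  expect_equal(fe$peak_acceleration, oracle_min_jerk_peak_accel(D, T_move),
               tolerance = 0.05)
  # time-symmetric profile: deceleration peak mirrors acceleration peak
  expect_equal(fe$peak_deceleration, -fe$peak_acceleration,
               tolerance = 0.02 * fe$peak_acceleration)
  # reaction time: offset-referenced, within one sample of the continuous
  # 2%-of-peak crossing
  t_cross <- latency + 1000 * oracle_threshold_crossing(0.02, T_move)
  expect_lte(abs(fe$reaction_time - (t_cross - 100)), 10)
  # endpoint lands on the target
  expect_lt(fe$accuracy, 0.1)
  expect_true(fe$onset_index <= fe$peak_speed_index)
  expect_true(fe$peak_speed_index <= fe$offset_index)
})

test_that("offset falls back to the last sample when speed stays high", {
  tr <- make_noiseless_trial(position = "middle", T_move = 0.5)
  prof <- compute_profile(tr)
  # truncate right after the speed peak so it never falls back to 2%
  cut <- prof$peak_speed_index + 1L
  tr_cut <- tr
  tr_cut$t_ms <- tr$t_ms[1:cut]
  tr_cut$x_px <- tr$x_px[1:cut]
  tr_cut$y_px <- tr$y_px[1:cut]
  prof_cut <- compute_profile(tr_cut)
  fe <- extract_features(prof_cut, tr_cut)
  expect_equal(fe$offset_index, cut)
})

test_that("features scale correctly with the pixel pitch", {
  tr <- make_noiseless_trial(position = "middle", T_move = 0.5)
  f1 <- extract_features(compute_profile(tr, px_to_cm = px_cm), tr)
  f2 <- extract_features(compute_profile(tr, px_to_cm = 2 * px_cm), tr)
  expect_equal(f2$peak_velocity, 2 * f1$peak_velocity)
  expect_equal(f2$reaction_time, f1$reaction_time)
})

test_that("reaction time is monotone in the onset threshold", {
  tr <- make_noiseless_trial(position = "low", T_move = 0.4)
  prof <- compute_profile(tr)
  rts <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.5),
                function(f) extract_features(prof, tr,
                                             threshold_frac = f)$reaction_time)
  expect_true(all(diff(rts) >= 0))
})

test_that("the anomaly screen flags erratic reaches and only those", {
  tr <- make_noiseless_trial(position = "high", T_move = 0.5)
  prof <- compute_profile(tr)
  fl <- flag_anomalous(tr, prof)
  expect_false(fl$anomalous)
  expect_equal(fl$x_reversals, 0)

  # simulator-injected erratic trial: alternating lateral excursions
  sched <- generate_reaching_schedule(1, seed = 1)
  spec <- sched[sched$position == "high", ][1, ]
  params <- motion_params(rt_sd = 0, mt_cv = 0, endpoint_noise_sd = 0,
                          path_noise_sd = 0, anomaly_rate = 0.999,
                          anomaly_amplitude_cm = 2)
  set.seed(2)
  bad <- simulate_reach(spec, params)
  expect_true(bad$anomalous_injected)
  flb <- flag_anomalous(bad, compute_profile(bad))
  expect_true(flb$anomalous)
  expect_gt(flb$x_reversals, 2)

  # one small corrective wiggle below the excursion floor is tolerated
  wig <- tr
  i <- seq(30, 40)
  wig$x_px <- tr$x_px
  wig$x_px[i] <- wig$x_px[i] + sin(seq(0, pi, length.out = length(i))) *
    (0.3 / px_cm)
  flw <- flag_anomalous(wig, compute_profile(wig), min_excursion = 0.5)
  expect_false(flw$anomalous)
})

test_that("condition aggregation averages unflagged trials and reports gaps", {
  f <- expand.grid(participant = 1, phase = "baseline",
                   trial = 1:20, cs_type = c("CS+", "CS-"),
                   position = "low", stringsAsFactors = FALSE)
  f$peak_velocity <- 300
  f$peak_acceleration <- 20
  f$peak_deceleration <- -20
  f$reaction_time <- 230
  f$accuracy <- 8
  f$anomalous <- FALSE
  f$anomaly_reasons <- ""

  agg <- aggregate_conditions(f)
  cm <- agg$cell_means
  expect_true(all(cm$mean[cm$measure == "peak_velocity"] == 300))
  expect_true(all(cm$n_trials == 20))

  # one flagged trial: mean over the remaining 19
  f2 <- f
  f2$peak_velocity[f2$cs_type == "CS+" & f2$trial == 1] <- 1000
  f2$anomalous[f2$cs_type == "CS+" & f2$trial == 1] <- TRUE
  agg2 <- aggregate_conditions(f2)
  cm2 <- agg2$cell_means
  expect_equal(cm2$mean[cm2$measure == "peak_velocity" &
                          cm2$cs_type == "CS+"], 300)
  expect_equal(cm2$n_trials[cm2$measure == "peak_velocity" &
                              cm2$cs_type == "CS+"][1], 19)
  expect_equal(agg2$exclusions$n_excluded, 1)

  # a fully excluded cell yields NA with a warning, never a silent zero
  f3 <- f
  f3$anomalous[f3$cs_type == "CS-"] <- TRUE
  expect_warning(agg3 <- aggregate_conditions(f3), "all trials excluded")
  cm3 <- agg3$cell_means
  expect_true(all(is.na(cm3$mean[cm3$cs_type == "CS-"])))
})
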