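test_that("minimum-jerk position honours its boundary conditions", {
  start <- c(0, -416); end <- c(0, 224)
  expect_equal(minimum_jerk_position(0, 0.5, start, end)[1, ],
               start, ignore_attr = TRUE)
  expect_equal(minimum_jerk_position(0.5, 0.5, start, end)[1, ],
               end, ignore_attr = TRUE)
  # quintic is symmetric: midpoint in time is midpoint in space
  expect_equal(minimum_jerk_position(0.25, 0.5, start, end)[1, ],
               (start + end) / 2, ignore_attr = TRUE)
  # out-of-range times clamp to the endpoints
  expect_equal(minimum_jerk_position(-1, 0.5, start, end)[1, ],
               start, ignore_attr = TRUE)
  expect_equal(minimum_jerk_position(2, 0.5, start, end)[1, ],
               end, ignore_attr = TRUE)
})

test_that("noiseless trajectories reach the closed-form speed peak", {
  # D = 15.9 cm over T = 0.5 s peaks at 1.875 D / T = 59.6 cm/s
  expect_equal(oracle_min_jerk_peak_speed(15.9, 0.5), 1.875 * 15.9 / 0.5,
               tolerance = 1e-6)
  for (pos in c("low", "middle", "high")) {
    tr <- make_noiseless_trial(position = pos, T_move = 0.5)
    prof <- compute_profile(tr)
    D <- sqrt((tr$target_x_px - 0)^2 + (tr$target_y_px - (-416))^2) * px_cm
    expect_equal(max(prof$speed), oracle_min_jerk_peak_speed(D, 0.5),
                 tolerance = 0.02)
  }
})

test_that("the CS+ vigor gain scales peak speed as 1 / (1 - g)", {
  sched <- generate_reaching_schedule(1, seed = 1)
  spec_minus <- sched[sched$position == "middle" & sched$cs_type == "CS-", ]
  spec_plus <- sched[sched$position == "middle" & sched$cs_type == "CS+", ]
  peak <- function(spec, g) {
    params <- motion_params(cs_plus_vigor_gain = g, rt_sd = 0, mt_cv = 0,
                            endpoint_noise_sd = 0, path_noise_sd = 0)
    set.seed(1)
    max(compute_profile(simulate_reach(spec, params))$speed)
  }
  # null effect: identical peaks when the gain is off
  expect_equal(peak(spec_plus, 0), peak(spec_minus, 0))
  # 3% gain speeds the CS+ reach up by 1/(1 - 0.03)
  g <- 0.03
  expect_equal(peak(spec_plus, g) / peak(spec_minus, g), 1 / (1 - g),
               tolerance = 0.005)
})

test_that("peak speed and acceleration increase with target distance", {
  peaks <- sapply(c("low", "middle", "high"), function(pos) {
    prof <- compute_profile(make_noiseless_trial(position = pos,
                                                 T_move = 0.5))
    c(speed = max(prof$speed), accel = max(prof$accel))
  })
  expect_true(all(diff(peaks["speed", ]) > 0))
  expect_true(all(diff(peaks["accel", ]) > 0))
})

test_that("cohort simulation is seed-reproducible and countable", {
  sched <- generate_reaching_schedule(1, seed = 2, phase = "test_safety")
  params <- motion_params()
  one <- simulate_cohort(sched, params, n_participants = 1, seed = 5)
  expect_length(one$trials, 6)
  co1 <- simulate_cohort(sched, params, n_participants = 3, seed = 7)
  co2 <- simulate_cohort(sched, params, n_participants = 3, seed = 7)
  expect_identical(trajectories_to_df(co1), trajectories_to_df(co2))
  expect_length(co1$trials, 18)
  # byte-identical CSV export under the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(co1, p1)
  write_trajectories_csv(co2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("trajectory CSVs round-trip through the long format", {
  sched <- generate_reaching_schedule(1, seed = 3, phase = "test_threat")
  co <- simulate_cohort(sched, motion_params(), n_participants = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(co, path)
  back <- read_trajectories_csv(path)
  expect_length(back, 12)
  f1 <- score_kinematics(co)
  f2 <- score_kinematics(back)
  ord <- function(d) d[order(d$participant, d$phase, d$trial), ]
  expect_equal(ord(f2)$peak_velocity, ord(f1)$peak_velocity,
               tolerance = 1e-8)
  expect_error(read_trajectories_csv(
    withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")), "missing")
})
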