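test_that("preprocessing decimates without distorting the passband", {
  fs <- 1250
  t_s <- seq(0, 60, by = 1 / fs)
  # flat trace stays flat at the same level
  flat <- structure(list(t_s = t_s, conductance_uS = rep(5, length(t_s)),
                         sample_rate = fs, events = NULL),
                    class = "scr_trace")
  out <- preprocess_scr(flat, 200)
  expect_equal(out$sample_rate, 200)
  expect_equal(range(out$conductance_uS), c(5, 5), tolerance = 1e-6)

  # a 2 Hz component survives decimation within 1%
  sine <- flat
  sine$conductance_uS <- 5 + 0.5 * sin(2 * pi * 2 * t_s)
  out2 <- preprocess_scr(sine, 200)
  mid <- out2$conductance_uS[out2$t_s > 5 & out2$t_s < 55]
  expect_equal((max(mid) - min(mid)) / 2, 0.5, tolerance = 0.01)

  # a 50 Hz component is attenuated by >= 20 dB when the low-pass is on
  hum <- flat
  hum$conductance_uS <- 5 + 0.5 * sin(2 * pi * 50 * t_s)
  out3 <- preprocess_scr(hum, 200, lowpass_10hz = TRUE)
  mid3 <- out3$conductance_uS[out3$t_s > 5 & out3$t_s < 55]
  atten_db <- 20 * log10(0.5 / max(abs(mid3 - 5)))
  expect_gte(atten_db, 20)

  low <- structure(list(t_s = seq(0, 1, by = 0.01),
                        conductance_uS = rep(5, 101), sample_rate = 100,
                        events = NULL), class = "scr_trace")
  expect_error(preprocess_scr(low, 200), "below target rate")
})

test_that("trough-to-peak scoring applies the validity rules in order", {
  # flat trace: nothing to score
  flat <- make_single_response_trace(amp = 0)
  expect_equal(score_scr_trial(flat, 5)$zero_reason, "no_deflection")
  expect_equal(score_scr_trial(flat, 5)$amplitude_uS, 0)

  # clean 0.5 uS response at 1.5 s latency is valid and exact
  tr <- make_single_response_trace(amp = 0.5, latency_s = 1.5)
  sc <- score_scr_trial(tr, 5)
  expect_true(sc$valid)
  expect_equal(sc$amplitude_uS, 0.5, tolerance = 0.005)
  expect_equal(sc$trough_t_s - 5, 1.5, tolerance = 0.1)

  # 0.015 uS deflection fails the amplitude rule
  small <- make_single_response_trace(amp = 0.015)
  expect_equal(score_scr_trial(small, 5)$zero_reason, "too_small")

  # response starting after the window fails the window rule
  late <- make_single_response_trace(amp = 0.5, latency_s = 5.5,
                                     total_s = 40)
  expect_equal(score_scr_trial(late, 5)$zero_reason, "outside_window")
  early <- make_single_response_trace(amp = 0.5, latency_s = 0.2)
  expect_equal(score_scr_trial(early, 5)$zero_reason, "outside_window")

  # a deflection rising for more than 5 s fails the duration rule
  slow <- make_single_response_trace(amp = 0.5, latency_s = 1,
                                     rise_tau = 3, decay_tau = 20,
                                     total_s = 60)
  expect_equal(score_scr_trial(slow, 5)$zero_reason, "too_long")

  # insufficient coverage is an error, not a zero score
  short <- make_single_response_trace(amp = 0.5, total_s = 10)
  expect_error(score_scr_trial(short, 5), "unscorable")
})

test_that("window bounds are inclusive at exactly 0.5 and 4.5 s", {
  for (lat in c(0.5, 4.5)) {
    tr <- make_single_response_trace(amp = 0.4, latency_s = lat,
                                     total_s = 40)
    sc <- score_scr_trial(tr, 5)
    expect_true(sc$valid,
                label = sprintf("latency %.1f scored valid", lat))
  }
  # one sample outside either bound is rejected
  tr <- make_single_response_trace(amp = 0.4, latency_s = 4.6, total_s = 40)
  expect_false(score_scr_trial(tr, 5)$valid)
})

test_that("amplitudes from 0.03 to 2 uS are recovered within 1%", {
  grid <- expand.grid(amp = c(0.03, 0.1, 0.5, 1.0, 2.0),
                      lat = c(0.6, 1.5, 3.0, 4.4))
  for (i in seq_len(nrow(grid))) {
    tr <- make_single_response_trace(amp = grid$amp[i],
                                     latency_s = grid$lat[i], total_s = 40)
    sc <- score_scr_trial(tr, 5)
    expect_true(sc$valid)
    expect_equal(sc$amplitude_uS, grid$amp[i],
                 tolerance = 0.01 * grid$amp[i])
  }
})

test_that("every score is zero with a reason or above the amplitude floor", {
  sched <- generate_pavlovian_schedule(9, 7, seed = 21)
  tr <- simulate_scr_trace(sched, scr_params(sample_rate = 200), seed = 22)
  sc <- score_scr_phase(tr, lowpass_10hz = TRUE)
  expect_true(all(xor(sc$amplitude_uS == 0, sc$amplitude_uS > 0.02)))
  expect_true(all(sc$valid == (sc$zero_reason == "none")))
  expect_true(all(sc$zero_reason %in%
                    c("none", "no_deflection", "outside_window",
                      "too_long", "too_small")))
  # valid scores respect the window on the reported onset
  lat <- sc$trough_t_s[sc$valid] -
    tr$events$cs_onset_s[match(sc$trial_index[sc$valid],
                               tr$events$trial_index)]
  expect_true(all(lat >= 0.5 - 1e-6 & lat <= 4.5 + 1e-6))
})

test_that("participant summaries include zero-scored trials as zeros", {
  sched <- generate_pavlovian_schedule(2, 1, seed = 30)
  scores <- data.frame(trial_index = sched$trial_index,
                       cs_type = sched$cs_type,
                       amplitude_uS = ifelse(sched$cs_type == "CS+", 0.6, 0.2),
                       valid = TRUE, zero_reason = "none",
                       stringsAsFactors = FALSE)
  s <- participant_scr_summary(scores, sched)
  expect_equal(s$differential_uS, 0.4)

  # all-zero scoring gives a zero differential, not NA
  scores0 <- scores
  scores0$amplitude_uS <- 0
  expect_equal(participant_scr_summary(scores0, sched)$differential_uS, 0)

  # zeros pull the condition mean down rather than dropping out
  scores_mix <- scores
  scores_mix$amplitude_uS[scores_mix$cs_type == "CS+"] <-
    c(0.6, 0, 0.6, 0, 0.6, 0)
  s_mix <- participant_scr_summary(scores_mix, sched)
  expect_equal(s_mix$cs_means$mean_amplitude_uS[
    s_mix$cs_means$cs_type == "CS+"], 0.3)
})
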