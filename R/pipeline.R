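#' Run configuration
#'
#' A run of the simulated experiment is a pure function of its
#' configuration. Layout 1 includes a baseline reaching phase before
#' conditioning; layout 2 starts at conditioning (the replication layout).
#' Per-participant random effects are driven by a latent "threat
#' reactivity" z-score that shifts both the CS+ vigor gain
#' (`subject_gain_sd`) and the CS+ phasic SCR amplitude (`scr_amp_link`),
#' planting a cross-participant coupling between sympathetic and kinematic
#' conditioned responses.
#'
#' @param seed Master seed; each stage (design, motion, SCR, per
#'   participant) derives its own child stream from it.
#' @param experiment 1 (with baseline) or 2 (without).
#' @param n_participants Cohort size.
#' @param reaching_trials_per_cell Trials per (CS type, position) cell in
#'   each reaching phase (default 20).
#' @param pav_trials_per_cell,reinforced_per_cell Pavlovian phase cell
#'   size and reinforced CS+ count per cell (defaults 9 and 7: a 77.8%
#'   reinforcement rate).
#' @param motion [motion_params()].
#' @param scr [scr_params()].
#' @param subject_mt_cv Between-participant movement-time lognormal CV.
#' @param subject_gain_sd Between-participant SD of the CS+ vigor gain.
#' @param subject_scr_cv Between-participant lognormal CV of overall
#'   electrodermal responsiveness (scales both CS amplitudes).
#' @param scr_amp_link Microsiemens of CS+ amplitude shift per unit of
#'   latent reactivity.
#' @param scoring Scoring thresholds: `threshold_frac`, `rt_reference`,
#'   `max_reversals`, `min_excursion`, `scr_target_rate`, `scr_lowpass`
#'   (`TRUE` for unfiltered signals such as the synthetic generator's),
#'   `scr_window`, `scr_max_rise`, `scr_min_amp`.
#' @param cs_plus_color Stimulus colour assigned to the CS+ role
#'   ("yellow" or "pink"); a between-participant counterbalancing label
#'   only - it relabels stimuli and affects no computation.
#' @param geometry [screen_geometry()].
#' @param out_dir Optional output directory; when set,
#'   [run_experiment()] writes all intermediate CSVs and the JSON bundle.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, experiment = 1, n_participants = 34,
                       reaching_trials_per_cell = 20,
                       pav_trials_per_cell = 9, reinforced_per_cell = 7,
                       motion = motion_params(), scr = scr_params(),
                       subject_mt_cv = 0.15, subject_gain_sd = 0.02,
                       subject_scr_cv = 0.5, scr_amp_link = 0.10,
                       scoring = list(threshold_frac = 0.02,
                                      rt_reference = "offset",
                                      max_reversals = 2L,
                                      min_excursion = 0.5,
                                      scr_target_rate = 200,
                                      scr_lowpass = TRUE,
                                      scr_window = c(0.5, 4.5),
                                      scr_max_rise = 5,
                                      scr_min_amp = 0.02),
                       cs_plus_color = c("yellow", "pink"),
                       geometry = screen_geometry(),
                       out_dir = NULL) {
  stopifnot(experiment %in% c(1, 2), n_participants >= 1)
  cs_plus_color <- match.arg(cs_plus_color)
  cfg <- list(seed = seed, experiment = experiment,
              n_participants = n_participants,
              reaching_trials_per_cell = reaching_trials_per_cell,
              pav_trials_per_cell = pav_trials_per_cell,
              reinforced_per_cell = reinforced_per_cell,
              motion = motion, scr = scr,
              subject_mt_cv = subject_mt_cv,
              subject_gain_sd = subject_gain_sd,
              subject_scr_cv = subject_scr_cv,
              scr_amp_link = scr_amp_link, cs_plus_color = cs_plus_color,
              scoring = scoring, geometry = geometry, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  plain <- strip_classes(config)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mp <- do.call(motion_params,
                c(list(base_movement_time = unlist(raw$motion$base_movement_time)),
                  raw$motion[setdiff(names(raw$motion), "base_movement_time")]))
  sp <- do.call(scr_params, raw$scr)
  geo <- screen_geometry(raw$geometry$diagonal_inches,
                         raw$geometry$resolution_x, raw$geometry$resolution_y)
  sc <- raw$scoring
  sc$scr_window <- unlist(sc$scr_window)
  run_config(seed = raw$seed, experiment = raw$experiment,
             n_participants = raw$n_participants,
             reaching_trials_per_cell = raw$reaching_trials_per_cell,
             pav_trials_per_cell = raw$pav_trials_per_cell,
             reinforced_per_cell = raw$reinforced_per_cell,
             motion = mp, scr = sp,
             subject_mt_cv = raw$subject_mt_cv,
             subject_gain_sd = raw$subject_gain_sd,
             subject_scr_cv = raw$subject_scr_cv,
             scr_amp_link = raw$scr_amp_link,
             cs_plus_color = raw$cs_plus_color,
             scoring = sc, geometry = geo, out_dir = raw$out_dir)
}

#' Simulate, score and analyze a full experiment
#'
#' Executes the stages in task order: schedule generation (per
#' participant), trajectory and skin-conductance simulation, kinematic and
#' SCR scoring, condition aggregation, and the statistical suite
#' (repeated-measures ANOVAs with sphericity handling, Helmert position
#' contrasts, paired CS tests with effect sizes, SCR-kinematics
#' differential correlations). With `config$out_dir` set, all intermediate
#' CSVs and a JSON results bundle are written.
#'
#' @param config A [run_config()].
#' @param keep_data Keep the simulated raw data (trajectory trials and SCR
#'   traces) in the returned bundle (default `FALSE`; they are large).
#' @return List of class `results_bundle`: `provenance` (config
#'   fingerprint, seed), `features`, `cell_means`, `exclusions`,
#'   `scr_scores`, `scr_cells`, `differentials`, `anova` (named list of
#'   `rm_anova` tables), `contrasts`, `paired` (CS+ vs CS- paired tests
#'   per measure), `correlations`, `stats_errors`.
#' @export
run_experiment <- function(config = run_config(), keep_data = FALSE) {
  stopifnot(inherits(config, "run_config"))
  px_to_cm <- config$geometry$px_to_cm
  n <- config$n_participants
  seed <- config$seed

  subj <- with_seed(child_seed(seed, 1), {
    z <- stats::rnorm(n)
    mt_mult <- stats::rlnorm(n, -config$subject_mt_cv^2 / 2,
                             config$subject_mt_cv)
    scr_scale <- stats::rlnorm(n, -config$subject_scr_cv^2 / 2,
                               config$subject_scr_cv)
    list(z = z, mt_mult = mt_mult, scr_scale = scr_scale,
         vigor_gain = config$motion$cs_plus_vigor_gain +
           config$subject_gain_sd * z,
         amp_plus = pmax(0.02, scr_scale * (config$scr$amp_cs_plus +
                                              config$scr_amp_link * z)),
         amp_minus = pmax(0.005, scr_scale * config$scr$amp_cs_minus))
  })

  reaching_phases <- c(if (config$experiment == 1) "baseline",
                       "test_safety", "test_threat")
  all_features <- vector("list", n)
  scr_cells <- vector("list", n)
  scr_scores <- vector("list", n)
  schedules_out <- vector("list", n)
  raw_trials <- if (keep_data) list() else NULL

  for (p in seq_len(n)) {
    scheds <- list()
    for (i in seq_along(reaching_phases))
      scheds[[reaching_phases[i]]] <- generate_reaching_schedule(
        config$reaching_trials_per_cell,
        seed = child_seed(seed, 100 + 10 * p + i),
        phase = reaching_phases[i])
    sched_pav <- generate_pavlovian_schedule(
      config$pav_trials_per_cell, config$reinforced_per_cell,
      seed = child_seed(seed, 100 + 10 * p))
    schedules_out[[p]] <- cbind(participant = p,
                                do.call(rbind, c(scheds, list(pavlovian = sched_pav))))

    mp <- config$motion
    mp$base_movement_time <- mp$base_movement_time * subj$mt_mult[p]
    trials <- with_seed(child_seed(seed, 200 + p), {
      unlist(lapply(scheds, function(s)
        lapply(seq_len(nrow(s)), function(i) {
          tr <- simulate_reach(s[i, ], mp, px_to_cm = px_to_cm,
                               vigor_gain = subj$vigor_gain[p])
          tr$participant_id <- p
          tr
        })), recursive = FALSE)
    })
    if (keep_data) raw_trials <- c(raw_trials, trials)
    all_features[[p]] <- score_kinematics(
      trials, px_to_cm = px_to_cm,
      threshold_frac = config$scoring$threshold_frac,
      rt_reference = config$scoring$rt_reference,
      max_reversals = config$scoring$max_reversals,
      min_excursion = config$scoring$min_excursion)

    sp <- config$scr
    trace <- simulate_scr_trace(sched_pav, sp,
                                seed = child_seed(seed, 300 + p),
                                amp_means = c("CS+" = subj$amp_plus[p],
                                              "CS-" = subj$amp_minus[p]))
    sc <- score_scr_phase(trace,
                          target_rate = config$scoring$scr_target_rate,
                          lowpass_10hz = isTRUE(config$scoring$scr_lowpass),
                          window = config$scoring$scr_window,
                          max_rise = config$scoring$scr_max_rise,
                          min_amp = config$scoring$scr_min_amp)
    scr_scores[[p]] <- cbind(participant = p, sc)
    summ <- participant_scr_summary(sc, sched_pav)
    scr_cells[[p]] <- cbind(participant = p, summ$cell_means)
  }

  features <- do.call(rbind, all_features)
  agg <- aggregate_conditions(features)
  scr_cells <- do.call(rbind, scr_cells)
  scr_scores <- do.call(rbind, scr_scores)

  bundle <- analyze_results(agg$cell_means, scr_cells, config)
  bundle$features <- features
  bundle$exclusions <- agg$exclusions
  bundle$scr_scores <- scr_scores
  bundle$schedules <- do.call(rbind, schedules_out)
  bundle$subject_effects <- data.frame(participant = seq_len(n),
                                       reactivity_z = subj$z,
                                       vigor_gain = subj$vigor_gain,
                                       amp_plus = subj$amp_plus,
                                       amp_minus = subj$amp_minus)
  if (keep_data) bundle$raw_trials <- raw_trials
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Statistical suite over kinematic and SCR condition means.
analyze_results <- function(cell_means, scr_cells, config) {
  errors <- list()
  note <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  test_phases <- c("test_safety", "test_threat")
  anova <- list(); contrasts <- list(); paired <- list()

  # SCR: 2 (CS type) x 3 (position)
  anova$scr <- note("anova_scr",
    rm_anova(stats::setNames(scr_cells[, c("participant", "cs_type",
                                           "position", "mean_amplitude_uS")],
                             c("participant", "cs_type", "position", "y")),
             dv = "y", within = c("cs_type", "position")))
  scr_wide <- note("scr_wide", {
    marg <- stats::aggregate(list(y = scr_cells$mean_amplitude_uS),
                             by = list(participant = scr_cells$participant,
                                       cs_type = scr_cells$cs_type),
                             FUN = mean)
    plus <- marg$y[marg$cs_type == "CS+"][order(marg$participant[marg$cs_type == "CS+"])]
    minus <- marg$y[marg$cs_type == "CS-"][order(marg$participant[marg$cs_type == "CS-"])]
    cbind(plus, minus)
  })
  if (!is.null(scr_wide))
    paired$scr <- note("paired_scr", paired_t(scr_wide[, 1], scr_wide[, 2]))

  for (m in KINEMATIC_MEASURES) {
    km <- cell_means[cell_means$measure == m, ]
    if (config$experiment == 1) {
      base <- km[km$phase == "baseline", ]
      anova[[paste0("baseline_", m)]] <- note(paste0("anova_baseline_", m),
        rm_anova(stats::setNames(base[, c("participant", "cs_type",
                                          "position", "mean")],
                                 c("participant", "cs_type", "position", "y")),
                 dv = "y", within = c("cs_type", "position")))
    }
    test <- km[km$phase %in% test_phases, ]
    anova[[paste0("test_", m)]] <- note(paste0("anova_test_", m),
      rm_anova(stats::setNames(test[, c("participant", "phase", "cs_type",
                                        "position", "mean")],
                               c("participant", "phase", "cs_type",
                                 "position", "y")),
               dv = "y", within = c("phase", "cs_type", "position")))
    contrasts[[paste0("test_", m, "_position")]] <-
      note(paste0("contrast_test_", m), {
        pm <- stats::aggregate(list(y = test$mean),
                               by = list(participant = test$participant,
                                         position = test$position),
                               FUN = mean)
        wide <- sapply(POSITIONS, function(pp)
          pm$y[pm$position == pp][order(pm$participant[pm$position == pp])])
        helmert_contrasts(wide)
      })
    paired[[paste0("test_", m, "_cs")]] <- note(paste0("paired_test_", m), {
      cm <- stats::aggregate(list(y = test$mean),
                             by = list(participant = test$participant,
                                       cs_type = test$cs_type), FUN = mean)
      plus <- cm$y[cm$cs_type == "CS+"][order(cm$participant[cm$cs_type == "CS+"])]
      minus <- cm$y[cm$cs_type == "CS-"][order(cm$participant[cm$cs_type == "CS-"])]
      paired_t(plus, minus)
    })
  }

  # differential correlations: SCR at learning vs kinematics at test
  correlations <- note("correlations", {
    test <- cell_means[cell_means$phase %in% test_phases, ]
    kd <- differential_scores(
      stats::setNames(test[, c("participant", "cs_type", "measure", "mean")],
                      c("participant", "cs_type", "measure", "mean")))
    sd_ <- differential_scores(
      data.frame(participant = scr_cells$participant,
                 cs_type = scr_cells$cs_type, measure = "scr",
                 mean = scr_cells$mean_amplitude_uS))
    dd <- merge(kd, sd_, by = "participant")
    out <- lapply(KINEMATIC_MEASURES, function(m)
      robust_pearson(dd$diff_scr, dd[[paste0("diff_", m)]]))
    names(out) <- KINEMATIC_MEASURES
    attr(out, "differentials") <- dd
    out
  })

  prov <- list(
    seed = config$seed,
    config_fingerprint = config_fingerprint(
      jsonlite::toJSON(strip_classes(config),
                       auto_unbox = TRUE, digits = NA)),
    package_version = as.character(utils::packageVersion("reachvigor")))

  structure(list(provenance = prov, cell_means = cell_means,
                 scr_cells = scr_cells, anova = anova,
                 contrasts = contrasts, paired = paired,
                 correlations = correlations,
                 differentials = if (!is.null(correlations))
                   attr(correlations, "differentials") else NULL,
                 stats_errors = errors),
            class = "results_bundle")
}

#' Re-analyze externally supplied data
#'
#' Skips simulation and runs scoring plus the statistical suite on data in
#' the package's documented long formats (as written by
#' [run_experiment()]): a long trajectory CSV, an SCR signal CSV
#' (optionally with a `participant` column), an SCR events CSV and a
#' schedule CSV. SCR inputs may be omitted for a kinematics-only
#' analysis. Stage errors that only affect the inferential layer (e.g. an
#' incomplete design with a single participant) are captured in
#' `stats_errors`; per-trial scores are still produced.
#'
#' @param trajectories_csv Path to the trajectory CSV.
#' @param scr_signal_csv,scr_events_csv Optional SCR paths.
#' @param schedule_csv Path to the schedule CSV (needed for SCR position
#'   bookkeeping; may include a `participant` column).
#' @param config A [run_config()] providing geometry and thresholds.
#' @return A `results_bundle` (see [run_experiment()]).
#' @export
run_on_external <- function(trajectories_csv, scr_signal_csv = NULL,
                            scr_events_csv = NULL, schedule_csv = NULL,
                            config = run_config()) {
  trials <- read_trajectories_csv(trajectories_csv)
  features <- score_kinematics(
    trials, px_to_cm = config$geometry$px_to_cm,
    threshold_frac = config$scoring$threshold_frac,
    rt_reference = config$scoring$rt_reference,
    max_reversals = config$scoring$max_reversals,
    min_excursion = config$scoring$min_excursion)
  agg <- aggregate_conditions(features)

  scr_cells <- NULL; scr_scores <- NULL
  if (!is.null(scr_signal_csv)) {
    if (is.null(scr_events_csv) || is.null(schedule_csv))
      stop("SCR analysis needs `scr_events_csv` and `schedule_csv`",
           call. = FALSE)
    sig <- utils::read.csv(scr_signal_csv)
    if (!all(c("t_s", "conductance_uS") %in% names(sig)))
      stop("signal file must have columns t_s, conductance_uS",
           call. = FALSE)
    ev <- utils::read.csv(scr_events_csv, stringsAsFactors = FALSE)
    sched <- utils::read.csv(schedule_csv, stringsAsFactors = FALSE)
    if (is.null(sig$participant)) sig$participant <- 1L
    if (is.null(ev$participant)) ev$participant <- 1L
    if (is.null(sched$participant)) sched$participant <- 1L
    parts <- sort(unique(sig$participant))
    res <- lapply(parts, function(p) {
      s <- sig[sig$participant == p, ]
      e <- ev[ev$participant == p, ]
      if (is.null(e$trial_index)) e$trial_index <- seq_len(nrow(e))
      fs <- (nrow(s) - 1) / (s$t_s[nrow(s)] - s$t_s[1])
      if (abs(fs - round(fs)) < 1e-3) fs <- round(fs)
      tr <- structure(list(t_s = s$t_s, conductance_uS = s$conductance_uS,
                           sample_rate = fs, events = e),
                      class = "scr_trace")
      sc <- score_scr_phase(tr,
                            target_rate = config$scoring$scr_target_rate,
                            lowpass_10hz = isTRUE(config$scoring$scr_lowpass),
                            window = config$scoring$scr_window,
                            max_rise = config$scoring$scr_max_rise,
                            min_amp = config$scoring$scr_min_amp)
      sp <- sched[sched$participant == p & sched$phase == "pavlovian", ]
      list(scores = cbind(participant = p, sc),
           cells = cbind(participant = p,
                         participant_scr_summary(sc, sp)$cell_means))
    })
    scr_scores <- do.call(rbind, lapply(res, `[[`, "scores"))
    scr_cells <- do.call(rbind, lapply(res, `[[`, "cells"))
  }

  cfg <- config
  if (!"baseline" %in% agg$cell_means$phase) cfg$experiment <- 2
  bundle <- if (is.null(scr_cells)) {
    b <- analyze_kinematics_only(agg$cell_means, cfg)
    b
  } else {
    analyze_results(agg$cell_means, scr_cells, cfg)
  }
  bundle$features <- features
  bundle$exclusions <- agg$exclusions
  bundle$scr_scores <- scr_scores
  bundle
}

analyze_kinematics_only <- function(cell_means, config) {
  empty_scr <- data.frame(participant = integer(), cs_type = character(),
                          position = character(),
                          mean_amplitude_uS = numeric())
  analyze_results(cell_means, empty_scr, config)
}

# Write the bundle's tabular members as CSVs plus a JSON summary.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name),
                                       row.names = FALSE)
  wr(bundle$features, "features.csv")
  wr(bundle$cell_means, "cell_means.csv")
  wr(bundle$exclusions, "exclusions.csv")
  wr(bundle$scr_scores, "scr_scores.csv")
  wr(bundle$scr_cells, "scr_cells.csv")
  wr(bundle$schedules, "schedules.csv")
  wr(bundle$differentials, "differentials.csv")
  for (nm in names(bundle$anova))
    wr(bundle$anova[[nm]], paste0("anova_", nm, ".csv"))
  jsonlite::write_json(bundle_to_json(bundle),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

bundle_to_json <- function(bundle) {
  list(provenance = bundle$provenance,
       anova = lapply(bundle$anova, function(a) if (!is.null(a)) as.data.frame(a)),
       contrasts = bundle$contrasts,
       paired = lapply(bundle$paired, function(p) if (!is.null(p)) as.data.frame(p)),
       correlations = lapply(bundle$correlations, function(r)
         if (!is.null(r)) list(r = r$r, p = r$p, n_used = r$n_used,
                               removed_points = r$removed_points)),
       stats_errors = bundle$stats_errors)
}
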