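#' @title Trial schedule generation
#' @name design
#' @description
#' Schedules for the three kinds of experimental phase:
#' * reaching phases (baseline and the two tests): a fully crossed
#'   2 (CS type) x 3 (position) design, `n_per_cell` trials per cell,
#'   uniformly shuffled;
#' * the Pavlovian threat-learning phase: same crossing, but the first six
#'   trials are three CS- and three reinforced CS+ covering each position
#'   once in random order, the remainder is pseudo-random with no more than
#'   two consecutive trials of the same CS type, and exactly
#'   `reinforced_per_cell` of the `n_per_cell` CS+ trials in each position
#'   cell co-terminate with the shock (7 of 9 by default, i.e. a 77.8%
#'   reinforcement rate). CS- trials are never reinforced.
#'
#' A schedule is a data frame with one row per trial and columns
#' `phase`, `trial_index`, `cs_type` ("CS+"/"CS-"), `position`
#' ("low"/"middle"/"high"), `target_x_px`, `target_y_px`, `reinforced`,
#' `pre_stim_s` (pre-stimulus jitter), `iti_s` (inter-trial interval) and
#' `stim_duration_s` (0.1 s for reaching phases, 6 s for the Pavlovian
#' phase). Generation is deterministic given `seed`.
NULL

PHASES <- c("baseline", "pavlovian", "test_safety", "test_threat")
CS_TYPES <- c("CS+", "CS-")
POSITIONS <- c("low", "middle", "high")

new_schedule <- function(phase, cs_type, position, reinforced,
                         pre_stim_s, iti_s, stim_duration_s, seed) {
  lay <- task_layout()
  tg <- lay$targets[position, , drop = FALSE]
  out <- data.frame(
    phase = phase,
    trial_index = seq_along(cs_type),
    cs_type = cs_type,
    position = position,
    target_x_px = unname(tg[, "x"]),
    target_y_px = unname(tg[, "y"]),
    reinforced = reinforced,
    pre_stim_s = pre_stim_s,
    iti_s = iti_s,
    stim_duration_s = stim_duration_s,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Generate a reaching-phase trial schedule
#'
#' Baseline and test phases: 2 CS types x 3 positions x `n_per_cell`
#' trials, presented in uniformly random order. Stimuli last 100 ms;
#' pre-stimulus jitter 1-1.5 s and inter-trial interval 2-4 s are drawn
#' uniformly and carried along (they do not affect scoring).
#'
#' @param n_per_cell Trials per (CS type, position) cell (>= 1); 20 gives
#'   the standard 120-trial phase.
#' @param seed Integer seed; the schedule is a pure function of it.
#' @param phase Phase label, one of "baseline", "test_safety", "test_threat".
#' @return A `trial_schedule` data frame (see [design]).
#' @export
generate_reaching_schedule <- function(n_per_cell = 20, seed = 1,
                                       phase = "baseline") {
  if (!is.numeric(n_per_cell) || n_per_cell < 1)
    stop("`n_per_cell` must be >= 1", call. = FALSE)
  phase <- match.arg(phase, PHASES[-2])
  n_per_cell <- as.integer(n_per_cell)
  n <- 6L * n_per_cell
  cells <- expand.grid(cs_type = CS_TYPES, position = POSITIONS,
                       rep = seq_len(n_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    ord <- sample.int(n)
    pre <- stats::runif(n, 1, 1.5)
    iti <- stats::runif(n, 2, 4)
  })
  cells <- cells[ord, ]
  new_schedule(phase, cells$cs_type, cells$position,
               reinforced = rep(FALSE, n),
               pre_stim_s = pre, iti_s = iti,
               stim_duration_s = 0.1, seed = seed)
}

#' Generate a Pavlovian threat-learning schedule
#'
#' Sequencing constraints: the first six trials are three CS- and three
#' reinforced CS+ trials, one per position each, in random order; from the
#' seventh trial onward, the order is pseudo-random with no run of more
#' than two consecutive trials of the same CS type. Exactly
#' `reinforced_per_cell` CS+ trials are reinforced within each position
#' cell (one of which falls in the first six); CS- trials are never
#' reinforced. Stimuli last 6 s, followed by a 12-14 s inter-trial
#' interval.
#'
#' The constrained order is drawn by sequential sampling: at each trial the
#' CS type is chosen uniformly among those with remaining trials that do
#' not create a run of three; dead ends trigger a restart, capped at
#' `max_attempts` before a schedule-infeasible error.
#'
#' @param n_per_cell CS presentations per (CS type, position) cell
#'   (default 9, the standard 54-trial phase).
#' @param reinforced_per_cell Reinforced CS+ trials per position cell
#'   (default 7, i.e. 7/9 = 77.8% reinforcement); must satisfy
#'   `1 <= reinforced_per_cell <= n_per_cell`.
#' @param seed Integer seed.
#' @param max_attempts Restart cap for the constrained sampler.
#' @return A `trial_schedule` data frame (see [design]).
#' @export
generate_pavlovian_schedule <- function(n_per_cell = 9,
                                        reinforced_per_cell = 7,
                                        seed = 1,
                                        max_attempts = 10000) {
  if (!is.numeric(n_per_cell) || n_per_cell < 1)
    stop("`n_per_cell` must be >= 1", call. = FALSE)
  if (reinforced_per_cell > n_per_cell || reinforced_per_cell < 1)
    stop("`reinforced_per_cell` must be in [1, n_per_cell]", call. = FALSE)
  n_per_cell <- as.integer(n_per_cell)
  reinforced_per_cell <- as.integer(reinforced_per_cell)
  n <- 6L * n_per_cell
  n_rest_per_type <- 3L * (n_per_cell - 1L)  # per CS type after first six

  res <- with_seed(seed, {
    # first six: one trial per position for each CS type, CS+ reinforced
    first6 <- data.frame(
      cs_type = rep(CS_TYPES, each = 3L),
      position = rep(POSITIONS, 2L),
      reinforced = rep(c(TRUE, FALSE), each = 3L),
      stringsAsFactors = FALSE
    )
    first6 <- first6[sample.int(6L), ]

    rest <- NULL
    if (n_rest_per_type > 0L) {
      types <- constrained_type_sequence(n_rest_per_type, n_rest_per_type,
                                         max_run = 2L,
                                         max_attempts = max_attempts)
      # positions balanced within each CS type, shuffled
      pos_plus <- sample(rep(POSITIONS, n_per_cell - 1L))
      pos_minus <- sample(rep(POSITIONS, n_per_cell - 1L))
      # remaining reinforcements: reinforced_per_cell - 1 per CS+ position
      reinf_plus <- unlist(lapply(POSITIONS, function(p) {
        idx <- which(pos_plus == p)
        r <- logical(length(idx))
        r[sample.int(length(idx), reinforced_per_cell - 1L)] <- TRUE
        stats::setNames(r, idx)
      }))
      reinf_vec <- logical(length(pos_plus))
      reinf_vec[as.integer(names(reinf_plus))] <- reinf_plus
      rest <- data.frame(cs_type = types, position = NA_character_,
                         reinforced = FALSE, stringsAsFactors = FALSE)
      rest$position[rest$cs_type == "CS+"] <- pos_plus
      rest$position[rest$cs_type == "CS-"] <- pos_minus
      rest$reinforced[rest$cs_type == "CS+"] <- reinf_vec
    }
    trials <- rbind(first6, rest)
    trials$pre_stim_s <- stats::runif(n, 1, 1.5)
    trials$iti_s <- stats::runif(n, 12, 14)
    trials
  })

  new_schedule("pavlovian", res$cs_type, res$position, res$reinforced,
               pre_stim_s = res$pre_stim_s, iti_s = res$iti_s,
               stim_duration_s = 6, seed = seed)
}

# Draw a binary sequence (n_plus "CS+", n_minus "CS-") with no run longer
# than max_run, by sequential uniform choice among feasible types; restarts
# on dead ends, errors out after max_attempts restarts.
constrained_type_sequence <- function(n_plus, n_minus, max_run = 2L,
                                      max_attempts = 10000) {
  for (attempt in seq_len(max_attempts)) {
    left <- c("CS+" = n_plus, "CS-" = n_minus)
    out <- character(n_plus + n_minus)
    run_type <- ""
    run_len <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      feasible <- names(left)[left > 0L]
      if (run_len >= max_run) feasible <- setdiff(feasible, run_type)
      if (length(feasible) == 0L) { ok <- FALSE; break }
      pick <- if (length(feasible) == 1L) feasible else
        feasible[sample.int(length(feasible), 1L)]
      out[i] <- pick
      left[pick] <- left[pick] - 1L
      if (pick == run_type) run_len <- run_len + 1L
      else { run_type <- pick; run_len <- 1L }
    }
    if (ok) return(out)
  }
  stop("schedule infeasible: no constraint-satisfying order found in ",
       max_attempts, " attempts", call. = FALSE)
}

#' Longest run of identical CS types in a schedule
#'
#' @param schedule A `trial_schedule`.
#' @param from First trial index to consider (the Pavlovian sequencing
#'   constraint applies from trial 7 onward).
#' @return Integer, the maximum run length.
#' @export
max_cs_run <- function(schedule, from = 1L) {
  x <- schedule$cs_type[schedule$trial_index >= from]
  if (length(x) == 0L) return(0L)
  max(rle(x)$lengths)
}

#' Read or write a schedule CSV
#'
#' Columns as documented in [design]. Round-trips exactly (up to numeric
#' printing precision of the jitter columns).
#'
#' @param schedule A `trial_schedule`.
#' @param path File path.
#' @return `read_schedule_csv` returns a `trial_schedule`;
#'   `write_schedule_csv` returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "trial_index", "cs_type", "position",
            "target_x_px", "target_y_px", "reinforced", "stim_duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schedule file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(df) <- c("trial_schedule", "data.frame")
  df
}
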