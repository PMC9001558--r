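# Synthetic rivalry datasets: alternating gamma renewal process with
# hazard modulation during tactile stimulation.

#' Duration of one tactile stimulus
#'
#' A tactile stimulus is a train of unidirectional sweeps separated by short
#' pauses, so its total duration is
#' `n_sweeps * sweep_duration_s + (n_sweeps - 1) * inter_sweep_pause_s`.
#' With 1-s sweeps and 100-ms pauses this gives 2.1 s for 2 sweeps and 3.2 s
#' for 3 sweeps.
#'
#' @param n_sweeps number of sweeps in the stimulus (2 or 3 in the standard
#'   design, but any positive count is accepted).
#' @param sweep_duration_s duration of a single sweep, seconds.
#' @param inter_sweep_pause_s pause between consecutive sweeps, seconds.
#' @return stimulus duration in seconds.
#' @export
tactile_duration <- function(n_sweeps, sweep_duration_s = 1, inter_sweep_pause_s = 0.1) {
  stopifnot(n_sweeps >= 1, sweep_duration_s > 0, inter_sweep_pause_s >= 0)
  n_sweeps * sweep_duration_s + (n_sweeps - 1) * inter_sweep_pause_s
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. Defaults
#' encode the standard study design: 14 participants (9 slow switchers with
#' mean dominance 3.53 s, 5 fast with 2.16 s), 48-s trials carrying 4 tactile
#' stimuli (first at 8 s, then every 10 s with a uniform 1-s onset jitter),
#' 1-s sweeps with 100-ms pauses, and a congruency-gated multiplicative
#' modulation of the switch hazard that is active only while a tactile
#' stimulus is on and only in the conditions where visual and tactile motion
#' share an axis and a location.
#'
#' Dominance durations follow a gamma distribution (shape `gamma_shape`,
#' mean set by the switcher profile); individual participants deviate from
#' their group mean by a lognormal factor with coefficient of variation
#' `participant_cv`. Transitions pass through a mixed-percept (`NONE`) gap
#' with probability `p_mixed`; gap durations are lognormal with the given
#' mean and log-scale dispersion.
#'
#' @param n_participants number of simulated participants.
#' @param switcher_profile character vector (`"slow"`/`"fast"`), one entry per
#'   participant.
#' @param gamma_shape shape of the gamma dominance-duration law.
#' @param mean_dominance_fast_s,mean_dominance_slow_s group mean dominance
#'   durations, seconds.
#' @param participant_cv coefficient of variation of participant-specific mean
#'   dominance durations around the group mean.
#' @param p_mixed probability that a transition passes through a mixed gap.
#' @param mixed_duration_s named numeric `c(mean = , sdlog = )` for the
#'   lognormal mixed-gap duration.
#' @param trial_length_s trial duration, seconds.
#' @param n_tactile_per_trial tactile stimuli per trial.
#' @param first_onset_s onset of the first tactile stimulus.
#' @param inter_onset_mean_s,onset_jitter_s mean and half-width of the uniform
#'   inter-onset interval.
#' @param sweep_duration_s,inter_sweep_pause_s sweep geometry, seconds.
#' @param hazard_mult_congruent hazard multiplier applied to the dominant
#'   percept while a direction-congruent stimulus is on (< 1 stabilises).
#' @param hazard_mult_incongruent multiplier for direction-incongruent
#'   stimulation (> 1 destabilises).
#' @param effect_conditions condition labels in which the multipliers apply.
#' @param conditions condition labels to simulate.
#' @param n_trials_per_condition trials per participant per condition.
#' @param seed integer seed; all randomness derives from it.
#' @return a validated list of class `rivalry_sim_config`.
#' @export
sim_config <- function(n_participants = 14,
                       switcher_profile = rep(c("slow", "fast"), c(9, 5)),
                       gamma_shape = 3.5,
                       mean_dominance_fast_s = 2.16,
                       mean_dominance_slow_s = 3.53,
                       participant_cv = 0.08,
                       p_mixed = 0.2,
                       mixed_duration_s = c(mean = 0.4, sdlog = 0.5),
                       trial_length_s = 48,
                       n_tactile_per_trial = 4,
                       first_onset_s = 8,
                       inter_onset_mean_s = 10,
                       onset_jitter_s = 1,
                       sweep_duration_s = 1,
                       inter_sweep_pause_s = 0.1,
                       hazard_mult_congruent = 0.4,
                       hazard_mult_incongruent = 3,
                       effect_conditions = c("parallel_aligned_visible",
                                             "parallel_aligned_invisible"),
                       conditions = c("parallel_aligned_visible",
                                      "parallel_aligned_invisible",
                                      "orthogonal_aligned",
                                      "parallel_misaligned"),
                       n_trials_per_condition = 16,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    switcher_profile = as.character(switcher_profile),
    gamma_shape = gamma_shape,
    mean_dominance_fast_s = mean_dominance_fast_s,
    mean_dominance_slow_s = mean_dominance_slow_s,
    participant_cv = participant_cv,
    p_mixed = p_mixed,
    mixed_duration_s = mixed_duration_s,
    trial_length_s = trial_length_s,
    n_tactile_per_trial = as.integer(n_tactile_per_trial),
    first_onset_s = first_onset_s,
    inter_onset_mean_s = inter_onset_mean_s,
    onset_jitter_s = onset_jitter_s,
    sweep_duration_s = sweep_duration_s,
    inter_sweep_pause_s = inter_sweep_pause_s,
    hazard_mult_congruent = hazard_mult_congruent,
    hazard_mult_incongruent = hazard_mult_incongruent,
    effect_conditions = as.character(effect_conditions),
    conditions = as.character(conditions),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    seed = as.integer(seed)
  )
  class(cfg) <- "rivalry_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1,
            length(cfg$switcher_profile) == cfg$n_participants,
            all(cfg$switcher_profile %in% c("fast", "slow")))
  pos <- c("gamma_shape", "mean_dominance_fast_s", "mean_dominance_slow_s",
           "trial_length_s", "first_onset_s", "inter_onset_mean_s",
           "sweep_duration_s", "hazard_mult_congruent",
           "hazard_mult_incongruent")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a positive number", f))
  }
  if (cfg$p_mixed < 0 || cfg$p_mixed > 1) stop("p_mixed must lie in [0, 1]")
  if (cfg$participant_cv < 0) stop("participant_cv must be non-negative")
  if (cfg$onset_jitter_s < 0 || cfg$inter_sweep_pause_s < 0)
    stop("jitter and pause durations must be non-negative")
  if (!all(c("mean", "sdlog") %in% names(cfg$mixed_duration_s)) ||
      cfg$mixed_duration_s[["mean"]] <= 0)
    stop("mixed_duration_s must be c(mean = , sdlog = ) with positive mean")
  if (cfg$onset_jitter_s >= cfg$inter_onset_mean_s)
    stop("onset jitter must be smaller than the mean inter-onset interval")
  max_dur <- tactile_duration(3L, cfg$sweep_duration_s, cfg$inter_sweep_pause_s)
  latest <- cfg$first_onset_s +
    (cfg$n_tactile_per_trial - 1) * (cfg$inter_onset_mean_s + cfg$onset_jitter_s) +
    max_dur
  if (latest > cfg$trial_length_s)
    stop("tactile schedule can exceed the trial length; adjust onsets or trial_length_s")
  if (cfg$n_trials_per_condition < 1 || length(cfg$conditions) < 1)
    stop("need at least one condition and one trial per condition")
  invisible(cfg)
}

#' Build one trial's tactile schedule
#'
#' Draws the tactile events of a single trial from the current RNG state:
#' first onset fixed at `first_onset_s`, subsequent inter-onset gaps uniform
#' on `inter_onset_mean_s` +/- `onset_jitter_s`, and sweep directions
#' counterbalanced (half `LEFT`, half `RIGHT`) in random order.
#'
#' @param cfg a [sim_config()] object.
#' @param n_sweeps sweeps per stimulus for this participant (2 fast / 3 slow).
#' @return data.frame with one row per tactile event: `index_in_trial`,
#'   `onset_s`, `direction`, `n_sweeps`, `duration_s`.
#' @export
build_schedule <- function(cfg, n_sweeps = 3L) {
  n <- cfg$n_tactile_per_trial
  gaps <- if (n > 1)
    stats::runif(n - 1, cfg$inter_onset_mean_s - cfg$onset_jitter_s,
                 cfg$inter_onset_mean_s + cfg$onset_jitter_s)
  else numeric(0)
  onsets <- cfg$first_onset_s + c(0, cumsum(gaps))
  dur <- tactile_duration(n_sweeps, cfg$sweep_duration_s, cfg$inter_sweep_pause_s)
  if (n > 1 && any(diff(onsets) <= dur))
    stop("tactile events overlap: inter-onset gap shorter than stimulus duration")
  if (onsets[n] + dur > cfg$trial_length_s)
    stop("tactile schedule exceeds trial length")
  dirs <- sample(rep(c("LEFT", "RIGHT"), length.out = n))
  data.frame(index_in_trial = seq_len(n), onset_s = onsets, direction = dirs,
             n_sweeps = as.integer(n_sweeps), duration_s = dur)
}

# Cumulative hazard of the gamma dominance law and its inverse, on log scale
# for numerical stability far in the tail.
.H0 <- function(a, shape, rate) {
  -stats::pgamma(a, shape = shape, rate = rate, lower.tail = FALSE, log.p = TRUE)
}
.H0inv <- function(h, shape, rate) {
  stats::qgamma(-h, shape = shape, rate = rate, lower.tail = FALSE, log.p = TRUE)
}

# Draw the end time of the current dominance period under a piecewise-constant
# hazard multiplier. `wins` is a data.frame(start, end, mult) of modulation
# windows; outside them the multiplier is 1. Returns `horizon` if the percept
# survives to the horizon (censoring at trial end).
sample_dominance_end <- function(t0, horizon, wins, shape, rate) {
  E <- stats::rexp(1)
  bp <- c(t0, horizon)
  if (nrow(wins)) bp <- c(bp, wins$start, wins$end)
  bp <- sort(unique(pmin(pmax(bp, t0), horizon)))
  mult <- rep(1, length(bp) - 1)
  if (nrow(wins)) {
    lo <- bp[-length(bp)]
    mid <- lo + pmin(bp[-1] - lo, 1) / 2  # robust to an infinite horizon
    for (k in seq_len(nrow(wins))) {
      inside <- mid >= wins$start[k] & mid < wins$end[k]
      mult[inside] <- wins$mult[k]
    }
  }
  a <- bp - t0
  H <- .H0(a, shape, rate)
  acc <- 0
  for (i in seq_along(mult)) {
    step <- mult[i] * (H[i + 1] - H[i])
    if (acc + step >= E) {
      target <- H[i] + (E - acc) / mult[i]
      return(t0 + .H0inv(target, shape, rate))
    }
    acc <- acc + step
  }
  horizon
}

#' Simulate one trial's perceptual trace
#'
#' Generates the piecewise-constant percept path of a single rivalry trial as
#' an alternating renewal process. Dominance durations are gamma distributed
#' with mean `mean_dominance_s`; while a tactile event is active and
#' `condition` belongs to `cfg$effect_conditions`, the instantaneous switch
#' hazard of the current percept is multiplied by `hazard_mult_congruent`
#' when the percept's direction matches the stimulus direction and by
#' `hazard_mult_incongruent` otherwise. Transitions pass through a `NONE`
#' (mixed percept) gap with probability `p_mixed`.
#'
#' @param cfg a [sim_config()] object.
#' @param events tactile schedule as returned by [build_schedule()].
#' @param condition condition label of the trial.
#' @param mean_dominance_s participant mean dominance duration, seconds.
#' @param axis `"horizontal"` (states `LEFT`/`RIGHT`) or `"vertical"`
#'   (states `UP`/`DOWN`; `UP` plays the role of `LEFT`).
#' @return list with `intervals` (data.frame `start_s`, `end_s`, `state`
#'   tiling `[0, trial_length_s]`) and `switches` (data.frame `time_s`,
#'   `from`, `to` of true perceptual switches).
#' @export
simulate_trace <- function(cfg, events, condition, mean_dominance_s,
                           axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stopifnot(condition %in% cfg$conditions || is.character(condition))
  shape <- cfg$gamma_shape
  rate <- shape / mean_dominance_s
  T_end <- cfg$trial_length_s
  gated <- condition %in% cfg$effect_conditions &&
    !(cfg$hazard_mult_congruent == 1 && cfg$hazard_mult_incongruent == 1)
  sdlog <- cfg$mixed_duration_s[["sdlog"]]
  mulog <- log(cfg$mixed_duration_s[["mean"]]) - sdlog^2 / 2
  labels <- if (axis == "horizontal") c("LEFT", "RIGHT") else c("UP", "DOWN")
  ev_dir <- ifelse(events$direction == "LEFT", -1, 1)

  dir <- sample(c(-1L, 1L), 1)
  t <- 0
  st_start <- numeric(0); st_end <- numeric(0); st_state <- character(0)
  sw_time <- numeric(0); sw_from <- character(0); sw_to <- character(0)
  lab <- function(d) labels[(d + 3) / 2]  # -1 -> first label, 1 -> second

  while (t < T_end) {
    if (gated) {
      mult <- ifelse(ev_dir == dir, cfg$hazard_mult_congruent,
                     cfg$hazard_mult_incongruent)
      wins <- data.frame(start = events$onset_s,
                         end = events$onset_s + events$duration_s,
                         mult = mult)
      wins <- wins[wins$end > t & wins$start < T_end, , drop = FALSE]
      s_end <- sample_dominance_end(t, T_end, wins, shape, rate)
    } else {
      s_end <- min(t + stats::rgamma(1, shape = shape, rate = rate), T_end)
    }
    st_start <- c(st_start, t); st_end <- c(st_end, s_end)
    st_state <- c(st_state, lab(dir))
    if (s_end >= T_end) break
    sw_time <- c(sw_time, s_end)
    sw_from <- c(sw_from, lab(dir)); sw_to <- c(sw_to, lab(-dir))
    t2 <- s_end
    if (stats::runif(1) < cfg$p_mixed) {
      gap_end <- min(t2 + stats::rlnorm(1, mulog, sdlog), T_end)
      st_start <- c(st_start, t2); st_end <- c(st_end, gap_end)
      st_state <- c(st_state, "NONE")
      t2 <- gap_end
    }
    t <- t2
    dir <- -dir
  }
  list(intervals = data.frame(start_s = st_start, end_s = st_end,
                              state = st_state),
       switches = data.frame(time_s = sw_time, from = sw_from, to = sw_to))
}

condition_axis <- function(condition) {
  ifelse(grepl("^orthogonal", condition), "vertical", "horizontal")
}

#' Simulate a complete multi-participant rivalry dataset
#'
#' Runs [build_schedule()] and [simulate_trace()] for every participant,
#' condition and trial in the configuration. Randomness is organised as one
#' L'Ecuyer-CMRG stream per trial, advanced in enumeration order from
#' `cfg$seed`, so identical configurations yield bitwise-identical datasets.
#'
#' @param cfg a [sim_config()] object.
#' @return object of class `rivalry_dataset`: list with `traces` (long
#'   interval table), `events` (tactile event table), `participants`
#'   (per-participant group, sweeps and true mean dominance), `truth`
#'   (ground-truth switch log) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "rivalry_sim_config"))
  validate_sim_config(cfg)
  # make sure a seed exists so the caller's RNG kind and state are restored
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))

  suppressWarnings(set.seed(cfg$seed, kind = "L'Ecuyer-CMRG"))
  n <- cfg$n_participants
  pid <- sprintf("P%02d", seq_len(n))
  group <- cfg$switcher_profile
  gmean <- ifelse(group == "fast", cfg$mean_dominance_fast_s,
                  cfg$mean_dominance_slow_s)
  if (cfg$participant_cv > 0) {
    sl <- sqrt(log(1 + cfg$participant_cv^2))
    pmean <- gmean * stats::rlnorm(n, -sl^2 / 2, sl)
  } else pmean <- gmean
  nsw <- ifelse(group == "fast", 2L, 3L)

  stream <- get(".Random.seed", envir = globalenv())
  tr_list <- list(); ev_list <- list(); sw_list <- list()
  k <- 0L
  for (p in seq_len(n)) {
    for (cond in cfg$conditions) {
      ax <- condition_axis(cond)
      for (tt in seq_len(cfg$n_trials_per_condition)) {
        k <- k + 1L
        stream <- parallel::nextRNGStream(stream)
        assign(".Random.seed", stream, envir = globalenv())
        trial_id <- sprintf("%s_%s_%02d", pid[p], cond, tt)
        ev <- build_schedule(cfg, nsw[p])
        tr <- simulate_trace(cfg, ev, cond, pmean[p], ax)
        ni <- nrow(tr$intervals)
        tr_list[[k]] <- cbind(participant_id = pid[p], trial_id = trial_id,
                              condition = cond, axis = ax, tr$intervals)
        ev_list[[k]] <- cbind(participant_id = pid[p], trial_id = trial_id,
                              condition = cond, ev)
        if (nrow(tr$switches))
          sw_list[[k]] <- cbind(participant_id = pid[p], trial_id = trial_id,
                                tr$switches)
      }
    }
  }
  traces <- do.call(rbind, tr_list); rownames(traces) <- NULL
  events <- do.call(rbind, ev_list); rownames(events) <- NULL
  truth <- if (length(sw_list)) do.call(rbind, sw_list) else
    data.frame(participant_id = character(0), trial_id = character(0),
               time_s = numeric(0), from = character(0), to = character(0))
  rownames(truth) <- NULL
  participants <- data.frame(participant_id = pid, group = group,
                             n_sweeps = nsw, mean_dominance_s = pmean)
  structure(list(traces = traces, events = events, participants = participants,
                 truth = truth, config = cfg),
            class = "rivalry_dataset")
}

#' @method print rivalry_dataset
#' @export
print.rivalry_dataset <- function(x, ...) {
  cat(sprintf("rivalry_dataset: %d participants, %d trials, %d intervals, %d tactile events\n",
              nrow(x$participants), length(unique(x$traces$trial_id)),
              nrow(x$traces), nrow(x$events)))
  cat(sprintf("conditions: %s (seed %d)\n",
              paste(x$config$conditions, collapse = ", "), x$config$seed))
  invisible(x)
}

fmt_num_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write / read a simulated dataset as plain text
#'
#' `write_rivalry_dataset()` writes `traces.csv`, `events.csv`,
#' `participants.csv`, `truth.csv` and a `config.json` sidecar carrying the
#' full configuration and seed. Doubles are serialised with 17 significant
#' digits so that `read_rivalry_dataset()` round-trips losslessly.
#'
#' @param x a `rivalry_dataset`.
#' @param path directory to write to (created if absent).
#' @return `write_rivalry_dataset()` returns `path` invisibly;
#'   `read_rivalry_dataset()` returns a `rivalry_dataset`.
#' @export
write_rivalry_dataset <- function(x, path) {
  stopifnot(inherits(x, "rivalry_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fmt_num_cols(x$traces), file.path(path, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt_num_cols(x$events), file.path(path, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt_num_cols(x$participants),
                   file.path(path, "participants.csv"), row.names = FALSE)
  utils::write.csv(fmt_num_cols(x$truth), file.path(path, "truth.csv"),
                   row.names = FALSE)
  cfg <- unclass(x$config)
  cfg$mixed_duration_s <- as.list(cfg$mixed_duration_s)
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_table_checked <- function(file, cols, numeric_cols) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", basename(file),
                 paste(missing, collapse = ", ")))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(df[[cc]]))
    if (length(bad))
      stop(sprintf("%s: row %d, column '%s' is not numeric", basename(file),
                   bad[1], cc))
    df[[cc]] <- v
  }
  df
}

#' @rdname write_rivalry_dataset
#' @export
read_rivalry_dataset <- function(path) {
  traces <- read_table_checked(file.path(path, "traces.csv"),
                               c("participant_id", "trial_id", "condition",
                                 "axis", "start_s", "end_s", "state"),
                               c("start_s", "end_s"))
  events <- read_table_checked(file.path(path, "events.csv"),
                               c("participant_id", "trial_id", "condition",
                                 "index_in_trial", "onset_s", "direction",
                                 "n_sweeps", "duration_s"),
                               c("onset_s", "duration_s"))
  events$index_in_trial <- as.integer(events$index_in_trial)
  events$n_sweeps <- as.integer(events$n_sweeps)
  participants <- read_table_checked(file.path(path, "participants.csv"),
                                     c("participant_id", "group", "n_sweeps",
                                       "mean_dominance_s"),
                                     c("mean_dominance_s"))
  participants$n_sweeps <- as.integer(participants$n_sweeps)
  truth <- read_table_checked(file.path(path, "truth.csv"),
                              c("participant_id", "trial_id", "time_s",
                                "from", "to"), c("time_s"))
  cj <- jsonlite::read_json(file.path(path, "config.json"),
                            simplifyVector = TRUE)
  cfg <- sim_config(
    n_participants = cj$n_participants,
    switcher_profile = cj$switcher_profile,
    gamma_shape = cj$gamma_shape,
    mean_dominance_fast_s = cj$mean_dominance_fast_s,
    mean_dominance_slow_s = cj$mean_dominance_slow_s,
    participant_cv = cj$participant_cv,
    p_mixed = cj$p_mixed,
    mixed_duration_s = unlist(cj$mixed_duration_s),
    trial_length_s = cj$trial_length_s,
    n_tactile_per_trial = cj$n_tactile_per_trial,
    first_onset_s = cj$first_onset_s,
    inter_onset_mean_s = cj$inter_onset_mean_s,
    onset_jitter_s = cj$onset_jitter_s,
    sweep_duration_s = cj$sweep_duration_s,
    inter_sweep_pause_s = cj$inter_sweep_pause_s,
    hazard_mult_congruent = cj$hazard_mult_congruent,
    hazard_mult_incongruent = cj$hazard_mult_incongruent,
    effect_conditions = cj$effect_conditions,
    conditions = cj$conditions,
    n_trials_per_condition = cj$n_trials_per_condition,
    seed = cj$seed)
  structure(list(traces = traces, events = events, participants = participants,
                 truth = truth, config = cfg),
            class = "rivalry_dataset")
}
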