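# Fixture builders shared across test files. All synthetic, generated in code.

# Build a one-trial interval table from durations and states.
make_trace <- function(durs, states, trial_id = "T1", participant_id = "P01",
                       condition = "parallel_aligned_invisible",
                       axis = "horizontal") {
  ends <- cumsum(durs)
  data.frame(participant_id = participant_id, trial_id = trial_id,
             condition = condition, axis = axis,
             start_s = c(0, ends[-length(ends)]), end_s = ends,
             state = states)
}

# Random contiguous trace on a 50-ms lattice: alternating LEFT/RIGHT with
# occasional NONE gaps. Used with oracle grid scans (no boundary ties).
random_lattice_trace <- function(len_s = 14, lattice = 0.05,
                                 trial_id = "T1") {
  t <- 0; durs <- c(); states <- c()
  cur <- sample(c("LEFT", "RIGHT"), 1)
  while (t < len_s) {
    d <- sample(2:60, 1) * lattice
    durs <- c(durs, d); states <- c(states, cur)
    t <- t + d
    if (t < len_s && runif(1) < 0.3) {
      g <- sample(1:10, 1) * lattice
      durs <- c(durs, g); states <- c(states, "NONE")
      t <- t + g
    }
    cur <- if (cur == "LEFT") "RIGHT" else "LEFT"
  }
  over <- sum(durs) - len_s
  durs[length(durs)] <- durs[length(durs)] - over
  keep <- durs > 1e-9
  make_trace(durs[keep], states[keep], trial_id = trial_id)
}

# Small simulation configs.
tiny_cfg <- function(seed = 1, ...) {
  args <- list(
    n_participants = 5,
    switcher_profile = c("slow", "slow", "slow", "fast", "fast"),
    conditions = c("parallel_aligned_invisible", "orthogonal_aligned"),
    effect_conditions = "parallel_aligned_invisible",
    n_trials_per_condition = 6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

null_cfg <- function(seed = 1, ...) {
  tiny_cfg(seed = seed, hazard_mult_congruent = 1,
           hazard_mult_incongruent = 1, ...)
}

# Wrap a participants x bins matrix as a binned_timecourse for one condition.
make_tc <- function(mat, condition = "A") {
  nb <- ncol(mat)
  pids <- rownames(mat)
  if (is.null(pids)) pids <- sprintf("P%02d", seq_len(nrow(mat)))
  out <- data.frame(participant_id = rep(pids, each = nb),
                    condition = condition,
                    bin = rep(seq_len(nb), times = nrow(mat)),
                    prob = as.vector(t(mat)))
  attr(out, "n_bins") <- nb
  class(out) <- c("binned_timecourse", "data.frame")
  out
}
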