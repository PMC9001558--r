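# Cleaning of raw button-press traces: artefact removal, axis remapping,
# dominance statistics.

DOMINANCE_STATES <- c("LEFT", "RIGHT", "UP", "DOWN")

# Merge adjacent same-state intervals within each trial, preserving the
# contiguous tiling. Assumes intervals are contiguous within trials.
merge_adjacent <- function(tr) {
  if (nrow(tr) == 0) return(tr)
  o <- order(tr$trial_id, tr$start_s)
  tr <- tr[o, , drop = FALSE]
  nr <- nrow(tr)
  new_run <- c(TRUE, tr$trial_id[-1] != tr$trial_id[-nr] |
                 tr$state[-1] != tr$state[-nr])
  last <- c(new_run[-1], TRUE)
  out <- tr[new_run, , drop = FALSE]
  out$end_s <- tr$end_s[last]
  rownames(out) <- NULL
  out
}

#' Remove artefactual dominance reports
#'
#' Dominance intervals lasting `threshold_s` or less are treated as response
#' artefacts and relabelled `NONE` (excluded time) rather than merged into a
#' neighbour, which would fabricate dominance the participant never reported.
#' Existing `NONE` periods (mixed percepts) are untouched. The returned table
#' keeps the contiguous tiling of each trial; an attribute `removed_time_s`
#' summarises excluded time per trial (relabelled artefact time plus
#' pre-existing mixed time).
#'
#' @param traces long interval table with columns `trial_id`, `start_s`,
#'   `end_s`, `state` (plus any others, preserved).
#' @param threshold_s artefact threshold in seconds; intervals with duration
#'   `<= threshold_s` are discarded. Default 0.18.
#' @return cleaned trace table of the same shape, with attribute
#'   `removed_time_s`.
#' @export
remove_artifacts <- function(traces, threshold_s = 0.18) {
  stopifnot(all(c("trial_id", "start_s", "end_s", "state") %in% names(traces)),
            threshold_s >= 0)
  if (nrow(traces) == 0) {
    attr(traces, "removed_time_s") <-
      data.frame(trial_id = character(0), artefact_s = numeric(0),
                 mixed_s = numeric(0), removed_time_s = numeric(0))
    return(traces)
  }
  dur <- traces$end_s - traces$start_s
  dom <- traces$state %in% DOMINANCE_STATES
  art <- dom & dur <= threshold_s
  mixed_time <- dur * (traces$state == "NONE")
  out <- traces
  out$state[art] <- "NONE"
  out <- merge_adjacent(out)

  tid <- factor(traces$trial_id, levels = unique(traces$trial_id))
  summ <- data.frame(
    trial_id = levels(tid),
    artefact_s = as.vector(rowsum(dur * art, tid)),
    mixed_s = as.vector(rowsum(mixed_time, tid)))
  summ$removed_time_s <- summ$artefact_s + summ$mixed_s
  rownames(summ) <- NULL
  attr(out, "removed_time_s") <- summ
  out
}

#' Remap vertical-axis responses onto the horizontal direction labels
#'
#' For trials where the visual grating drifted vertically (orthogonal to the
#' lateral tactile sweeps), upward responses are mapped to `LEFT` and
#' downward responses to `RIGHT`, mirroring the button assignment used for
#' responding. This arbitrary but fixed mapping gives every trial a common
#' direction alphabet so that congruency is defined in all conditions.
#' Horizontal trials pass through unchanged; a `mapped_axis` column records
#' which rows were remapped.
#'
#' @param traces long interval table with an `axis` column
#'   (`"horizontal"`/`"vertical"`).
#' @return the table with states remapped and a logical `mapped_axis` column.
#' @export
remap_vertical <- function(traces) {
  stopifnot("axis" %in% names(traces), "state" %in% names(traces))
  v <- traces$axis == "vertical"
  traces$mapped_axis <- v
  if (!any(v)) {
    if (nrow(traces)) message("remap_vertical: no vertical-axis trials; nothing to remap")
    return(traces)
  }
  st <- traces$state
  st[v & traces$state == "UP"] <- "LEFT"
  st[v & traces$state == "DOWN"] <- "RIGHT"
  traces$state <- st
  traces
}

#' Per-participant dominance statistics and switcher class
#'
#' Mean and SD of dominance durations (`LEFT`/`RIGHT`/`UP`/`DOWN` intervals
#' only; `NONE` time never contributes), with the switcher classification
#' used to calibrate tactile stimulus length: `fast` if the mean dominance
#' duration is strictly below 3 s, `slow` otherwise.
#'
#' @param traces cleaned interval table with `participant_id`, `start_s`,
#'   `end_s`, `state`.
#' @param fast_threshold_s class boundary in seconds (default 3).
#' @return data.frame with one row per participant: `participant_id`,
#'   `mean_s`, `sd_s`, `n_intervals`, `class`. Participants with no dominance
#'   intervals are dropped with a warning.
#' @export
dominance_stats <- function(traces, fast_threshold_s = 3) {
  stopifnot(all(c("participant_id", "start_s", "end_s", "state") %in% names(traces)))
  all_p <- unique(traces$participant_id)
  dom <- traces[traces$state %in% DOMINANCE_STATES, , drop = FALSE]
  if (nrow(dom) == 0) {
    warning("no dominance intervals for participant(s): ",
            paste(all_p, collapse = ", "))
    return(data.frame(participant_id = character(0), mean_s = numeric(0),
                      sd_s = numeric(0), n_intervals = integer(0),
                      class = character(0)))
  }
  dur <- dom$end_s - dom$start_s
  pid <- factor(dom$participant_id, levels = unique(dom$participant_id))
  out <- data.frame(
    participant_id = levels(pid),
    mean_s = as.vector(tapply(dur, pid, mean)),
    sd_s = as.vector(tapply(dur, pid, stats::sd)),
    n_intervals = as.vector(tapply(dur, pid, length)))
  out$class <- ifelse(out$mean_s < fast_threshold_s, "fast", "slow")
  missing <- setdiff(all_p, out$participant_id)
  if (length(missing))
    warning("participant(s) with no dominance intervals excluded: ",
            paste(missing, collapse = ", "))
  rownames(out) <- NULL
  out
}
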