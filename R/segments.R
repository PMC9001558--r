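# Tactile-onset-locked segment extraction and congruency/outcome
# classification.

# State at time `t` for a contiguous, sorted interval table. Intervals are
# half-open [start, end): at a boundary the new interval's state applies
# (right-continuous convention).
state_at <- function(tr, t) {
  i <- findInterval(t, tr$start_s)
  if (i < 1 || t >= tr$end_s[nrow(tr)]) return(NA_character_)
  tr$state[i]
}

# Dominance direction sequence and mixed time within [w0, w1). Switches are
# LEFT<->RIGHT transitions, possibly through NONE: a LEFT-NONE-LEFT excursion
# is no switch, LEFT-NONE-RIGHT is one.
window_summary <- function(tr, w0, w1) {
  sel <- tr$start_s < w1 & tr$end_s > w0
  sub <- tr[sel, , drop = FALSE]
  ov <- pmin(sub$end_s, w1) - pmax(sub$start_s, w0)
  dom <- sub$state %in% c("LEFT", "RIGHT")
  dirs <- sub$state[dom]
  n_sw <- if (length(dirs) > 1) sum(dirs[-1] != dirs[-length(dirs)]) else 0L
  list(n_switches = as.integer(n_sw),
       mixed_s = sum(ov[sub$state == "NONE"]),
       dirs = dirs)
}

#' Extract tactile-onset-locked segments
#'
#' Cuts each trial into one segment per tactile event, locked to stimulus
#' onset, and classifies it by (a) visuo-tactile congruency of the dominant
#' percept at onset and (b) perceptual outcome during stimulation. The state
#' at the exact onset instant follows the half-open `[start, end)`
#' convention. Outcomes:
#' \describe{
#'   \item{`maintained`}{no direction switch during the touch window and no
#'     mixed time}
#'   \item{`switched`}{exactly one direction switch, no mixed time}
#'   \item{`multi_switch`}{two or more direction switches, no mixed time}
#'   \item{`excluded_mixed`}{any mixed (`NONE`) time inside the touch window}
#'   \item{`excluded_no_dominance`}{no dominant percept at onset; congruency
#'     is `undefined`}
#' }
#' `n_switches_in_touch` is reported for every segment regardless of
#' exclusion. Direction switches are `LEFT`/`RIGHT` reversals, counted
#' through `NONE` gaps (a return to the same percept is not a switch).
#'
#' @param traces cleaned interval table (after [remap_vertical()]).
#' @param events tactile event table with `trial_id`, `onset_s`,
#'   `duration_s`, `direction` (plus ids, preserved).
#' @param window_s analysis window length from onset; default `NULL` uses
#'   each event's own stimulus duration.
#' @return data.frame with one row per tactile event.
#' @export
extract_segments <- function(traces, events, window_s = NULL) {
  stopifnot(all(c("trial_id", "start_s", "end_s", "state") %in% names(traces)),
            all(c("trial_id", "onset_s", "duration_s", "direction") %in%
                  names(events)))
  if (!is.null(window_s)) stopifnot(window_s > 0)
  byt <- split(traces[c("start_s", "end_s", "state")], traces$trial_id)
  ne <- nrow(events)
  init <- character(ne); congr <- character(ne)
  nsw <- integer(ne); outc <- character(ne); win <- numeric(ne)
  for (i in seq_len(ne)) {
    tid <- events$trial_id[i]
    tr <- byt[[tid]]
    if (is.null(tr)) stop(sprintf("no trace for trial %s", tid))
    w0 <- events$onset_s[i]
    w <- if (is.null(window_s)) events$duration_s[i] else window_s
    w1 <- w0 + w
    trial_end <- max(tr$end_s)
    if (w1 > trial_end + 1e-9)
      stop(sprintf("tactile event %d of trial %s extends beyond the trace end",
                   events$index_in_trial[i], tid))
    s0 <- state_at(tr, w0)
    ws <- window_summary(tr, w0, w1)
    win[i] <- w
    init[i] <- s0
    nsw[i] <- ws$n_switches
    if (s0 == "NONE") {
      congr[i] <- "undefined"
      outc[i] <- "excluded_no_dominance"
    } else {
      congr[i] <- if (s0 == events$direction[i]) "congruent" else "incongruent"
      outc[i] <- if (ws$mixed_s > 1e-12) "excluded_mixed"
      else if (ws$n_switches == 0) "maintained"
      else if (ws$n_switches == 1) "switched"
      else "multi_switch"
    }
  }
  out <- events
  out$window_s <- win
  out$initial_state <- init
  out$congruency <- congr
  out$n_switches_in_touch <- nsw
  out$outcome <- outc
  rownames(out) <- NULL
  out
}

#' Tabulate segment outcomes per participant, condition and congruency
#'
#' Counts maintained / switched-once / switched-multiple segments within each
#' participant x condition x congruency cell (exclusions dropped first) and
#' converts them to probabilities that sum to 1 within a cell. Cells with no
#' usable segments are flagged and carry `NA` probabilities.
#'
#' @param segments output of [extract_segments()].
#' @return data.frame with counts, probabilities and an `empty_cell` flag.
#' @export
tabulate_outcomes <- function(segments) {
  keep <- segments$outcome %in% c("maintained", "switched", "multi_switch")
  s <- segments[keep, , drop = FALSE]
  pid <- factor(segments$participant_id)
  cond <- factor(segments$condition)
  cells <- expand.grid(participant_id = levels(pid), condition = levels(cond),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  key <- function(p, cd, cg) paste(p, cd, cg, sep = "\r")
  cnt <- function(outcome) {
    tab <- table(key(s$participant_id, s$condition, s$congruency)[
      s$outcome == outcome])
    v <- as.integer(tab[key(cells$participant_id, cells$condition,
                            cells$congruency)])
    ifelse(is.na(v), 0L, v)
  }
  cells$n_maintained <- cnt("maintained")
  cells$n_switched_once <- cnt("switched")
  cells$n_switched_multiple <- cnt("multi_switch")
  cells$n_total <- cells$n_maintained + cells$n_switched_once +
    cells$n_switched_multiple
  cells$empty_cell <- cells$n_total == 0L
  tot <- ifelse(cells$empty_cell, NA_integer_, cells$n_total)
  cells$p_maintained <- cells$n_maintained / tot
  cells$p_switched_once <- cells$n_switched_once / tot
  cells$p_switched_multiple <- cells$n_switched_multiple / tot
  cells
}
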