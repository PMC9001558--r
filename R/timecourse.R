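# Normalised tactile-onset-locked congruent-probability timecourses,
# FDR-corrected bin tests, and the cluster-mass permutation test.

#' Timecourse segmentation specification
#'
#' Fixes the geometry of the normalised timecourse analysis: segments run
#' from tactile onset to a group-specific cutoff chosen so that the tactile
#' stimulus occupies the same fraction of the segment in both switch groups
#' (3.2/9 s for slow switchers, 2.1/5.91 s for fast; both round to 0.36),
#' and are divided into `n_bins` equal bins on the normalised [0, 1] axis.
#'
#' @param slow_cutoff_s,fast_cutoff_s segment cutoffs from tactile onset,
#'   seconds.
#' @param touch_slow_s,touch_fast_s tactile stimulus durations per group.
#' @param n_bins number of bins on the normalised axis.
#' @param alpha_bin two-sided alpha for the per-bin tests.
#' @param chance chance level of the congruent probability.
#' @return list of class `tc_spec`, including the common `touch_fraction`.
#' @export
tc_spec <- function(slow_cutoff_s = 9, fast_cutoff_s = 5.91,
                    touch_slow_s = 3.2, touch_fast_s = 2.1,
                    n_bins = 36, alpha_bin = 0.025, chance = 0.5) {
  fr_slow <- round(touch_slow_s / slow_cutoff_s, 2)
  fr_fast <- round(touch_fast_s / fast_cutoff_s, 2)
  if (fr_slow != fr_fast)
    stop(sprintf("touch fraction differs between groups (%.2f vs %.2f)",
                 fr_slow, fr_fast))
  structure(list(slow_cutoff_s = slow_cutoff_s, fast_cutoff_s = fast_cutoff_s,
                 touch_slow_s = touch_slow_s, touch_fast_s = touch_fast_s,
                 n_bins = as.integer(n_bins), alpha_bin = alpha_bin,
                 chance = chance, touch_fraction = fr_slow),
            class = "tc_spec")
}

#' Fast-switcher cutoff by touch-proportion matching
#'
#' The fast-group segment cutoff is chosen so that the 2.1-s fast stimulus
#' occupies the same proportion of the segment as the 3.2-s slow stimulus
#' does of the 9-s slow segment: `2.1 * 9 / 3.2 = 5.91` (2 dp).
#'
#' @param slow_cutoff_s slow-group cutoff, seconds.
#' @param touch_slow_s,touch_fast_s stimulus durations, seconds.
#' @return matched fast-group cutoff, seconds (rounded to 2 dp).
#' @export
matched_fast_cutoff <- function(slow_cutoff_s = 9, touch_slow_s = 3.2,
                                touch_fast_s = 2.1) {
  round(touch_fast_s * slow_cutoff_s / touch_slow_s, 2)
}

#' Binned congruent-probability trace of one segment
#'
#' For a single tactile event, computes per bin the fraction of dominance
#' time (`LEFT`/`RIGHT` only; `NONE` time is excluded by time-weighting)
#' spent congruent with the stimulus direction, over the window
#' `[onset, onset + cutoff_s]` divided into `n_bins` equal bins. Bins with
#' zero dominance time are `NA`.
#'
#' @param intervals one trial's interval table (`start_s`, `end_s`, `state`).
#' @param onset_s tactile onset, seconds.
#' @param direction tactile direction, `"LEFT"` or `"RIGHT"`.
#' @param cutoff_s segment length from onset, seconds.
#' @param n_bins number of bins.
#' @return numeric vector of length `n_bins` in `[0, 1]`, `NA` where no
#'   dominance time falls in the bin.
#' @export
congruency_trace <- function(intervals, onset_s, direction, cutoff_s,
                             n_bins = 36) {
  edges <- onset_s + cutoff_s * seq(0, 1, length.out = n_bins + 1)
  lo <- edges[-(n_bins + 1)]; hi <- edges[-1]
  a <- outer(intervals$start_s, lo, pmax)
  b <- outer(intervals$end_s, hi, pmin)
  ov <- pmax(b - a, 0)
  dom <- intervals$state %in% c("LEFT", "RIGHT")
  cong <- dom & intervals$state == direction
  dom_t <- colSums(ov[dom, , drop = FALSE])
  cong_t <- colSums(ov[cong, , drop = FALSE])
  ifelse(dom_t > 1e-12, cong_t / dom_t, NA_real_)
}

#' Per-participant binned congruent-probability timecourses
#'
#' Builds one timecourse per tactile event (segment length by switch group;
#' segments truncated by the trial end are dropped and counted), then
#' averages segment traces within each participant x condition cell --
#' segment-level averaging always precedes any across-participant statistic.
#' All segments enter regardless of their congruency at onset.
#'
#' @param traces cleaned interval table (after [remap_vertical()]).
#' @param events tactile event table.
#' @param groups named character vector mapping `participant_id` to
#'   `"slow"`/`"fast"`.
#' @param spec a [tc_spec()].
#' @return object of class `binned_timecourse`: long data.frame
#'   (`participant_id`, `condition`, `bin`, `prob`) with attributes
#'   `n_bins`, `n_segments` (per cell) and `n_dropped` (truncated segments).
#' @export
participant_timecourses <- function(traces, events, groups, spec = tc_spec()) {
  stopifnot(all(unique(events$participant_id) %in% names(groups)))
  byt <- split(traces[c("start_s", "end_s", "state")], traces$trial_id)
  nb <- spec$n_bins
  cell_id <- paste(events$participant_id, events$condition, sep = "\r")
  cells <- unique(cell_id)
  acc <- matrix(0, length(cells), nb, dimnames = list(cells, NULL))
  cnt <- matrix(0L, length(cells), nb, dimnames = list(cells, NULL))
  nseg <- stats::setNames(integer(length(cells)), cells)
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    tr <- byt[[events$trial_id[i]]]
    if (is.null(tr)) stop(sprintf("no trace for trial %s", events$trial_id[i]))
    cutoff <- if (groups[[events$participant_id[i]]] == "fast")
      spec$fast_cutoff_s else spec$slow_cutoff_s
    if (events$onset_s[i] + cutoff > max(tr$end_s) + 1e-9) {
      dropped <- dropped + 1L
      next
    }
    v <- congruency_trace(tr, events$onset_s[i], events$direction[i],
                          cutoff, nb)
    ok <- !is.na(v)
    ci <- cell_id[i]
    acc[ci, ok] <- acc[ci, ok] + v[ok]
    cnt[ci, ok] <- cnt[ci, ok] + 1L
    nseg[ci] <- nseg[ci] + 1L
  }
  mean_mat <- ifelse(cnt > 0, acc / cnt, NA_real_)
  parts <- do.call(rbind, strsplit(cells, "\r", fixed = TRUE))
  out <- data.frame(
    participant_id = rep(parts[, 1], each = nb),
    condition = rep(parts[, 2], each = nb),
    bin = rep(seq_len(nb), times = length(cells)),
    prob = as.vector(t(mean_mat)))
  attr(out, "n_bins") <- nb
  attr(out, "n_segments") <- data.frame(participant_id = parts[, 1],
                                        condition = parts[, 2],
                                        n_segments = as.integer(nseg))
  attr(out, "n_dropped") <- dropped
  class(out) <- c("binned_timecourse", "data.frame")
  out
}

#' Participants-by-bins matrix for one condition
#'
#' @param tc a `binned_timecourse`.
#' @param condition condition label to extract.
#' @return numeric matrix, one row per participant (rownames set), one
#'   column per bin.
#' @export
tc_matrix <- function(tc, condition) {
  s <- tc[tc$condition == condition, , drop = FALSE]
  if (nrow(s) == 0) stop("no timecourses for condition ", condition)
  nb <- attr(tc, "n_bins")
  pids <- unique(s$participant_id)
  m <- matrix(NA_real_, length(pids), nb, dimnames = list(pids, NULL))
  m[cbind(match(s$participant_id, pids), s$bin)] <- s$prob
  m
}

# Column-wise one-sample t statistics of a participants-by-bins matrix.
# Bins with fewer than 2 non-missing participants or zero variance are
# masked (NA) rather than reported as infinite.
one_sample_t <- function(M, mu = 0) {
  n <- colSums(!is.na(M))
  m <- colMeans(M, na.rm = TRUE)
  s <- apply(M, 2, stats::sd, na.rm = TRUE)
  t <- (m - mu) / (s / sqrt(n))
  masked <- n < 2 | !is.finite(t)
  t[masked] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df = pmax(n - 1, 1))
  list(n = n, mean = m, sd = s, t = t, p = p, masked = masked)
}

#' Per-bin tests of a condition's timecourse against chance
#'
#' One-sample two-tailed t-tests of each bin's across-participant values
#' against the chance level, Benjamini-Hochberg corrected over the bins of
#' the timecourse; significance at `alpha_bin` on the adjusted p-values.
#' The significant duration per switch group is the number of significant
#' bins times that group's bin width (`cutoff / n_bins`).
#'
#' @param tc a `binned_timecourse`.
#' @param condition condition label to test.
#' @param spec a [tc_spec()].
#' @return list of class `bin_tests`: `t`, `p`, `p_fdr`, `sig_mask`,
#'   `masked`, `n_sig` and `significant_duration_s` (named `slow`/`fast`).
#' @export
bin_tests <- function(tc, condition, spec = tc_spec()) {
  M <- tc_matrix(tc, condition)
  r <- one_sample_t(M, mu = spec$chance)
  ok <- !r$masked
  if (sum(ok) == 0) stop("all bins are masked; cannot test")
  p_fdr <- rep(NA_real_, length(r$p))
  p_fdr[ok] <- stats::p.adjust(r$p[ok], method = "BH")
  sig <- !is.na(p_fdr) & p_fdr < spec$alpha_bin
  nsig <- sum(sig)
  structure(list(condition = condition, t = r$t, p = r$p, p_fdr = p_fdr,
                 sig_mask = sig, masked = r$masked, n_sig = nsig,
                 significant_duration_s = c(
                   slow = nsig * spec$slow_cutoff_s / spec$n_bins,
                   fast = nsig * spec$fast_cutoff_s / spec$n_bins)),
            class = "bin_tests")
}

#' Per-participant condition-difference waveforms
#'
#' Elementwise `cond_a - cond_b` per participant; missing bins propagate.
#' Participants present in only one condition are dropped with a warning.
#'
#' @param tc a `binned_timecourse`.
#' @param cond_a,cond_b condition labels.
#' @return participants-by-bins matrix of differences.
#' @export
difference_waveform <- function(tc, cond_a, cond_b) {
  A <- tc_matrix(tc, cond_a)
  B <- tc_matrix(tc, cond_b)
  common <- intersect(rownames(A), rownames(B))
  if (length(common) < length(union(rownames(A), rownames(B))))
    warning("dropping participants not present in both conditions")
  if (length(common) == 0) stop("no participants shared across conditions")
  A[common, , drop = FALSE] - B[common, , drop = FALSE]
}

#' Maximal supra-threshold clusters of a t-vector
#'
#' Clusters are maximal runs of temporally adjacent bins whose t-values
#' exceed the threshold with a common sign; the cluster mass is the sum of
#' t-values in the run. Masked (`NA`) bins break adjacency.
#'
#' @param t numeric vector of per-bin t-values (`NA` allowed).
#' @param threshold positive threshold, scalar or per-bin vector.
#' @return data.frame with `start_bin`, `end_bin`, `sign`, `mass`.
#' @export
find_clusters <- function(t, threshold) {
  code <- integer(length(t))
  ok <- !is.na(t)
  thr <- rep_len(threshold, length(t))
  code[ok & t > thr] <- 1L
  code[ok & t < -thr] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(start_bin = integer(0), end_bin = integer(0),
                      sign = integer(0), mass = numeric(0)))
  data.frame(
    start_bin = starts[keep], end_bin = ends[keep], sign = r$values[keep],
    mass = mapply(function(s, e) sum(t[s:e]), starts[keep], ends[keep]))
}

# t statistics for a batch of sign-flip assignments. S: permutations x
# participants matrix of +/-1; D: participants x bins with NA allowed.
flip_t_matrix <- function(S, D) {
  D0 <- D; D0[is.na(D)] <- 0
  nb <- colSums(!is.na(D))
  ss <- colSums(D0^2)
  Mn <- sweep(S %*% D0, 2, nb, "/")
  V <- sweep(-sweep(Mn^2, 2, nb, "*"), 2, ss, "+") / pmax(nb - 1, 1)
  Tm <- Mn / sqrt(sweep(V, 2, nb, "/"))
  Tm[, nb < 2] <- NA_real_
  Tm[!is.finite(Tm)] <- NA_real_
  Tm
}

#' Cluster-mass permutation test for paired difference waveforms
#'
#' Observed stage: per-bin one-sample t-tests of the difference traces
#' against zero, thresholded at the 97.5th quantile of the t-distribution
#' (two-sided `alpha = .025`); supra-threshold bins are clustered by
#' temporal adjacency separately per sign and scored by their summed
#' t-values. Permutation stage: under the paired-design exchangeability
#' null, each participant's difference trace has its sign flipped at random;
#' per permutation the maximum absolute cluster mass is recorded. A cluster
#' is significant when its absolute mass exceeds the 95th percentile of the
#' permutation maxima; per-cluster Monte-Carlo p-values are also reported.
#' With `exact = TRUE` all `2^n` sign assignments are enumerated instead of
#' sampled (n <= 20).
#'
#' The literal scheme of shuffling each participant's responses across bins
#' and conditions is available as `method = "shuffle"` (requires the two
#' condition matrices `cond_a`, `cond_b`); the sign-flip default is the
#' standard paired-design cluster permutation.
#'
#' @param diff participants-by-bins matrix of condition differences
#'   (see [difference_waveform()]).
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param alpha one-tail alpha of the bin threshold (default .025).
#' @param exact enumerate all sign assignments.
#' @param method `"sign_flip"` (default) or `"shuffle"`.
#' @param cond_a,cond_b condition matrices, only for `method = "shuffle"`.
#' @return object of class `cluster_test`: `clusters` (with `p` and
#'   `significant`), `perm_max` (distribution of maximum absolute masses),
#'   `threshold_t`, `significance_limit`, `n_perm`, `exact`.
#' @export
cluster_permutation_test <- function(diff, n_perm = 1000, alpha = 0.025,
                                     exact = FALSE,
                                     method = c("sign_flip", "shuffle"),
                                     cond_a = NULL, cond_b = NULL) {
  method <- match.arg(method)
  D <- as.matrix(diff)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 participants")
  if (all(is.na(D))) stop("all bins are missing")
  if (!exact && n_perm < 100) warning("fewer than 100 permutations")
  obs <- one_sample_t(D, 0)
  thr <- stats::qt(1 - alpha, df = pmax(obs$n - 1, 1))
  # observed t through the same arithmetic path as the permutations, so the
  # identity assignment ties the observed mass exactly (no FP asymmetry in
  # the >= comparisons below)
  tvec <- as.vector(flip_t_matrix(matrix(1, 1, n), D))
  clusters <- find_clusters(tvec, thr)

  max_mass <- function(tv) {
    cl <- find_clusters(tv, thr)
    if (nrow(cl) == 0) 0 else max(abs(cl$mass))
  }
  if (method == "sign_flip") {
    if (exact) {
      if (n > 20) stop("exact enumeration limited to 20 participants")
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      dimnames(S) <- NULL
    } else {
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    }
    Tm <- flip_t_matrix(S, D)
    perm_max <- apply(Tm, 1, max_mass)
  } else {
    if (is.null(cond_a) || is.null(cond_b))
      stop("method = 'shuffle' needs cond_a and cond_b matrices")
    A <- as.matrix(cond_a); B <- as.matrix(cond_b)
    stopifnot(all(dim(A) == dim(B)), nrow(A) == n)
    nb <- ncol(A)
    perm_max <- vapply(seq_len(n_perm), function(i) {
      pooled <- cbind(A, B)
      for (r in seq_len(n)) pooled[r, ] <- sample(pooled[r, ])
      Dp <- pooled[, seq_len(nb), drop = FALSE] -
        pooled[, nb + seq_len(nb), drop = FALSE]
      max_mass(one_sample_t(Dp, 0)$t)
    }, numeric(1))
  }
  limit <- stats::quantile(perm_max, 0.95, names = FALSE)
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$mass,
                         function(m) mean(perm_max >= abs(m)), numeric(1))
    clusters$significant <- abs(clusters$mass) > limit
  } else {
    clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, perm_max = perm_max,
                 threshold_t = thr, significance_limit = limit,
                 n_perm = length(perm_max), exact = exact, alpha = alpha,
                 n_participants = n),
            class = "cluster_test")
}

#' @method print cluster_test
#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster-mass permutation test: %d participants, %d permutations%s\n",
              x$n_participants, x$n_perm, if (x$exact) " (exact)" else ""))
  cat(sprintf("significance limit (95th pct of max |mass|): %.3f\n",
              x$significance_limit))
  if (nrow(x$clusters)) print(x$clusters) else cat("no supra-threshold clusters\n")
  invisible(x)
}
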