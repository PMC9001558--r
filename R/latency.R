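# First-switch latency segments and the two-way within-subject ANOVA with
# Mauchly test, Greenhouse-Geisser correction and generalized eta squared.

#' First-switch latency segments
#'
#' For every tactile event, builds a unimodal (visual-only) segment
#' `[onset - L, onset)` and a bimodal segment `[onset, onset + L)` of equal
#' group-specific length `L` (4.25 s slow / 2.95 s fast by default), so that
#' unimodal and bimodal segment counts are equal per participant before any
#' filtering. Bimodal segments are typed by visuo-tactile congruency at
#' onset (a switch inside a `bimodal_congruent` segment is a switch to
#' incongruence and vice versa); segments with no dominant percept at onset
#' get an `NA` kind. Pairs whose unimodal window would precede the trial
#' start or whose bimodal window would overrun the trial end are dropped and
#' counted in the `n_dropped_pairs` attribute.
#'
#' A perceptual switch is the moment a new dominance direction begins
#' (`LEFT`/`RIGHT` reversals, counted through `NONE` gaps). The first-switch
#' latency is expressed as a proportion of segment length; only segments
#' with exactly one switch carry usable latencies.
#'
#' @param traces cleaned interval table (after [remap_vertical()]).
#' @param events tactile event table.
#' @param groups named character vector mapping participant to
#'   `"slow"`/`"fast"`.
#' @param lengths named segment lengths in seconds, `c(slow = , fast = )`.
#' @return data.frame with two rows per kept event (`kind` in `unimodal`,
#'   `bimodal_congruent`, `bimodal_incongruent` or `NA`), `start_s`,
#'   `length_s`, `n_switches`, `first_switch_latency_prop`.
#' @export
build_latency_segments <- function(traces, events, groups,
                                   lengths = c(slow = 4.25, fast = 2.95)) {
  stopifnot(all(c("slow", "fast") %in% names(lengths)))
  byt <- split(traces[c("start_s", "end_s", "state")], traces$trial_id)
  rows <- list(); k <- 0L; dropped <- 0L
  for (i in seq_len(nrow(events))) {
    tid <- events$trial_id[i]
    tr <- byt[[tid]]
    if (is.null(tr)) stop(sprintf("no trace for trial %s", tid))
    L <- lengths[[groups[[events$participant_id[i]]]]]
    onset <- events$onset_s[i]
    trial_end <- max(tr$end_s)
    if (onset - L < -1e-9 || onset + L > trial_end + 1e-9) {
      dropped <- dropped + 1L
      next
    }
    # switch times: starts of dominance intervals whose direction differs
    # from the previous dominance direction in the trial
    dom <- tr[tr$state %in% c("LEFT", "RIGHT"), , drop = FALSE]
    if (nrow(dom) > 1) {
      chg <- dom$state[-1] != dom$state[-nrow(dom)]
      sw_times <- dom$start_s[-1][chg]
    } else sw_times <- numeric(0)
    seg_row <- function(w0, kind) {
      inw <- sw_times >= w0 & sw_times < w0 + L
      nsw <- sum(inw)
      lat <- if (nsw == 1) (sw_times[inw][1] - w0) / L else NA_real_
      data.frame(participant_id = events$participant_id[i], trial_id = tid,
                 condition = events$condition[i],
                 index_in_trial = events$index_in_trial[i], kind = kind,
                 start_s = w0, length_s = L, n_switches = nsw,
                 first_switch_latency_prop = lat)
    }
    s0 <- state_at(tr, onset)
    bikind <- if (is.na(s0) || s0 == "NONE") NA_character_
    else if (s0 == events$direction[i]) "bimodal_congruent"
    else "bimodal_incongruent"
    rows[[k <- k + 1L]] <- seg_row(onset - L, "unimodal")
    rows[[k <- k + 1L]] <- seg_row(onset, bikind)
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(participant_id = character(0), trial_id = character(0),
               condition = character(0), index_in_trial = integer(0),
               kind = character(0), start_s = numeric(0),
               length_s = numeric(0), n_switches = integer(0),
               first_switch_latency_prop = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_dropped_pairs") <- dropped
  out
}

#' Participant mean first-switch latencies
#'
#' Keeps only segments with exactly one switch and a defined kind (the
#' single-switch rule), and averages latency proportions per participant x
#' condition x kind.
#'
#' @param segments output of [build_latency_segments()].
#' @return data.frame `participant_id`, `condition`, `kind`, `latency`, `n`.
#' @export
participant_latency_means <- function(segments) {
  s <- segments[segments$n_switches == 1 & !is.na(segments$kind), ,
                drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(participant_id = character(0), condition = character(0),
                      kind = character(0), latency = numeric(0),
                      n = integer(0)))
  key <- interaction(s$participant_id, s$condition, s$kind, drop = TRUE,
                     sep = "\r")
  agg <- data.frame(do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(agg) <- c("participant_id", "condition", "kind")
  agg$latency <- as.vector(tapply(s$first_switch_latency_prop, key, mean))
  agg$n <- as.vector(tapply(s$first_switch_latency_prop, key, length))
  rownames(agg) <- NULL
  agg
}

# Orthonormal contrast matrix for a k-level within factor: (k-1) x k rows,
# orthonormal, each orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

#' Greenhouse-Geisser epsilon of a set of within-subject scores
#'
#' Given the participants-by-levels matrix of one within-subject effect,
#' projects onto orthonormal contrasts and computes
#' `eps = tr(M)^2 / (d * tr(M^2))` where `M` is the covariance of the
#' contrast scores and `d` its dimension.
#'
#' @param Y numeric matrix, participants x levels (k >= 2).
#' @param C optional contrast matrix ((k-1) x k, orthonormal rows); defaults
#'   to normalised Helmert contrasts.
#' @return epsilon in `(1/(k-1), 1]`.
#' @export
gg_epsilon <- function(Y, C = NULL) {
  k <- ncol(Y)
  if (k < 2) stop("need at least 2 levels")
  if (is.null(C)) C <- orthonormal_contrasts(k)
  M <- stats::cov(Y %*% t(C))
  d <- nrow(C)
  sum(diag(M))^2 / (d * sum(M * M))
}

#' Mauchly's test of sphericity for within-subject scores
#'
#' @param Y participants-by-levels matrix of one within-subject effect.
#' @param C optional orthonormal contrast matrix as in [gg_epsilon()].
#' @return list with `W`, `chi2`, `df`, `p` (`p = NA` when the effect has a
#'   single contrast dimension, where sphericity holds trivially).
#' @export
mauchly_test <- function(Y, C = NULL) {
  k <- ncol(Y); n <- nrow(Y)
  if (is.null(C)) C <- orthonormal_contrasts(k)
  d <- nrow(C)
  if (d < 2) return(list(W = 1, chi2 = 0, df = 0L, p = NA_real_))
  M <- stats::cov(Y %*% t(C))
  W <- det(M) / (sum(diag(M)) / d)^d
  if (!is.finite(W) || W <= 0)
    return(list(W = W, chi2 = Inf, df = as.integer(d * (d + 1) / 2 - 1), p = 0))
  f <- (n - 1) - (2 * d^2 + d + 2) / (6 * d)
  chi2 <- -f * log(W)
  df <- as.integer(d * (d + 1) / 2 - 1)
  list(W = W, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-way within-subject ANOVA with sphericity handling
#'
#' Classical repeated-measures decomposition for a complete two-factor
#' within-subject design (one observation per participant x cell; cell
#' replicates are averaged first, participants with missing cells are
#' dropped listwise with a message). For every effect with three or more
#' levels of contrast, Mauchly's sphericity test is run; whenever it is
#' significant at `sphericity_alpha`, the reported p-value uses
#' Greenhouse-Geisser corrected degrees of freedom. Generalized eta squared
#' uses the all-within form: effect SS over effect SS plus all
#' subject-related SS.
#'
#' @param df long data.frame.
#' @param value,participant,factor_a,factor_b column names.
#' @param sphericity_alpha threshold on the Mauchly p-value (default .05).
#' @return data.frame of class `rm_anova`, one row per effect (`A`, `B`,
#'   `A:B`): `F`, `df_num`, `df_den`, `p`, `gg_epsilon`, `df_num_gg`,
#'   `df_den_gg`, `p_gg`, `p_reported`, `mauchly_p`, `eta_g_sq`. The sums of
#'   squares table is attached as attribute `ss`.
#' @export
rm_anova_within <- function(df, value = "latency",
                            participant = "participant_id",
                            factor_a = "condition", factor_b = "kind",
                            sphericity_alpha = 0.05) {
  d <- df[!is.na(df[[value]]), c(participant, factor_a, factor_b, value)]
  names(d) <- c("id", "A", "B", "y")
  d$id <- factor(d$id); d$A <- factor(d$A); d$B <- factor(d$B)
  cells <- tapply(d$y, list(d$id, d$A, d$B), mean)
  complete <- apply(!is.na(cells), 1, all)
  if (!all(complete))
    message(sprintf("rm_anova_within: dropping %d participant(s) with missing cells",
                    sum(!complete)))
  Y <- cells[complete, , , drop = FALSE]
  n <- dim(Y)[1]; A <- dim(Y)[2]; B <- dim(Y)[3]
  if (n < 3) stop("need at least 3 participants with complete cells")

  gm <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_ab <- apply(Y, c(2, 3), mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)

  SS_T <- sum((Y - gm)^2)
  SS_S <- A * B * sum((m_s - gm)^2)
  SS_A <- n * B * sum((m_a - gm)^2)
  SS_B <- n * A * sum((m_b - gm)^2)
  SS_AB <- n * sum((m_ab - outer(m_a, rep(1, B)) -
                      outer(rep(1, A), m_b) + gm)^2)
  SS_AS <- B * sum((m_sa - outer(m_s, rep(1, A)) -
                      outer(rep(1, n), m_a) + gm)^2)
  SS_BS <- A * sum((m_sb - outer(m_s, rep(1, B)) -
                      outer(rep(1, n), m_b) + gm)^2)
  SS_ABS <- SS_T - SS_S - SS_A - SS_B - SS_AB - SS_AS - SS_BS

  ss <- data.frame(
    term = c("S", "A", "AxS", "B", "BxS", "AxB", "AxBxS", "total"),
    SS = c(SS_S, SS_A, SS_AS, SS_B, SS_BS, SS_AB, SS_ABS, SS_T),
    df = c(n - 1, A - 1, (A - 1) * (n - 1), B - 1, (B - 1) * (n - 1),
           (A - 1) * (B - 1), (A - 1) * (B - 1) * (n - 1),
           n * A * B - 1))

  Ca <- orthonormal_contrasts(A); Cb <- orthonormal_contrasts(B)
  # cell matrix with column index a + (b-1)*A, matching kronecker(Cb, Ca)
  Ycells <- matrix(Y, n)
  scores <- list(A = m_sa %*% t(Ca), B = m_sb %*% t(Cb),
                 `A:B` = Ycells %*% t(kronecker(Cb, Ca)))
  denom_eta <- SS_S + SS_AS + SS_BS + SS_ABS

  one_effect <- function(name, SS_eff, df1, SS_err, df2, sc) {
    F <- (SS_eff / df1) / (SS_err / df2)
    eps <- if (ncol(sc) < 2) 1 else {
      M <- stats::cov(sc)
      max(sum(diag(M))^2 / (ncol(sc) * sum(M * M)), 1 / ncol(sc))
    }
    mau <- if (ncol(sc) < 2) NA_real_ else {
      W <- det(stats::cov(sc)) / (sum(diag(stats::cov(sc))) / ncol(sc))^ncol(sc)
      mauchly_from_W(W, n, ncol(sc))
    }
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE)
    correct <- !is.na(mau) && mau < sphericity_alpha
    data.frame(effect = name, F = F, df_num = df1, df_den = df2, p = p,
               gg_epsilon = eps, df_num_gg = eps * df1, df_den_gg = eps * df2,
               p_gg = p_gg, p_reported = if (correct) p_gg else p,
               mauchly_p = mau,
               eta_g_sq = SS_eff / (SS_eff + denom_eta))
  }
  out <- rbind(
    one_effect("A", SS_A, A - 1, SS_AS, (A - 1) * (n - 1), scores$A),
    one_effect("B", SS_B, B - 1, SS_BS, (B - 1) * (n - 1), scores$B),
    one_effect("A:B", SS_AB, (A - 1) * (B - 1), SS_ABS,
               (A - 1) * (B - 1) * (n - 1), scores$`A:B`))
  rownames(out) <- NULL
  attr(out, "ss") <- ss
  attr(out, "n") <- n
  attr(out, "factors") <- c(A = factor_a, B = factor_b)
  class(out) <- c("rm_anova", "data.frame")
  out
}

mauchly_from_W <- function(W, n, d) {
  if (!is.finite(W) || W <= 0) return(0)
  f <- (n - 1) - (2 * d^2 + d + 2) / (6 * d)
  stats::pchisq(-f * log(W), d * (d + 1) / 2 - 1, lower.tail = FALSE)
}

#' Bonferroni-corrected paired contrasts between segment kinds
#'
#' Two-sided paired t-tests between each pair of segment kinds within one
#' condition, with p-values multiplied by the number of comparisons (capped
#' at 1). Identical paired vectors give `t = 0`, `p = 1` by convention.
#'
#' @param means output of [participant_latency_means()].
#' @param condition condition level to test within.
#' @param value,kind,participant column names.
#' @param n_comparisons Bonferroni multiplier (default: number of pairs).
#' @return data.frame with `pair`, `t`, `df`, `mean_diff`, `p_raw`, `p_adj`.
#' @export
paired_contrasts <- function(means, condition, value = "latency",
                             kind = "kind", participant = "participant_id",
                             n_comparisons = NULL) {
  s <- means[means$condition == condition, , drop = FALSE]
  kinds <- sort(unique(s[[kind]]))
  prs <- utils::combn(kinds, 2, simplify = FALSE)
  if (is.null(n_comparisons)) n_comparisons <- length(prs)
  rows <- lapply(prs, function(pr) {
    a <- s[s[[kind]] == pr[1], c(participant, value)]
    b <- s[s[[kind]] == pr[2], c(participant, value)]
    m <- merge(a, b, by = participant)
    dd <- m[[paste0(value, ".x")]] - m[[paste0(value, ".y")]]
    n <- length(dd)
    if (n < 2) stop("need at least 2 paired participants for ",
                    paste(pr, collapse = " vs "))
    if (stats::sd(dd) == 0) {
      t <- if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
      p <- if (mean(dd) == 0) 1 else 0
    } else {
      tt <- stats::t.test(dd)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(pair = paste(pr, collapse = " - "), t = t, df = n - 1,
               mean_diff = mean(dd), p_raw = p,
               p_adj = min(1, n_comparisons * p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
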