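# Independent brute-force oracles. Each reimplements a statistic from its
# definition, by a different mechanism than the package code, and is used to
# pin the implementation on random instances.

# Benjamini-Hochberg rejection set, straight from the step-up definition.
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# BH adjusted p-values: running minimum of m * p_(i) / i from the largest p.
bh_adjust_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Supra-threshold cluster scan by explicit loop.
cluster_oracle <- function(t, thr) {
  thr <- rep_len(thr, length(t))
  res <- list()
  cur_sign <- 0L; cur_start <- NA_integer_
  flush <- function(i) {
    if (cur_sign != 0L)
      res[[length(res) + 1L]] <<- data.frame(
        start_bin = cur_start, end_bin = i - 1L, sign = cur_sign,
        mass = sum(t[cur_start:(i - 1L)]))
    cur_sign <<- 0L
  }
  for (i in seq_along(t)) {
    s <- if (is.na(t[i])) 0L else if (t[i] > thr[i]) 1L
    else if (t[i] < -thr[i]) -1L else 0L
    if (s != cur_sign) {
      flush(i)
      if (s != 0L) { cur_sign <- s; cur_start <- i }
    }
  }
  flush(length(t) + 1L)
  if (!length(res))
    return(data.frame(start_bin = integer(0), end_bin = integer(0),
                      sign = integer(0), mass = numeric(0)))
  do.call(rbind, res)
}

# Segment classification by dense grid sampling of the state path. Traces
# must live on a time lattice and the window must be offset from it so no
# grid point falls on an interval boundary.
classify_oracle <- function(tr, onset, win, direction, dt = 0.005) {
  times <- seq(onset + dt / 2, onset + win - dt / 2, by = dt)
  inmat <- outer(tr$start_s, times, "<=") & outer(tr$end_s, times, ">")
  states <- tr$state[max.col(t(inmat), ties.method = "first")]
  init <- states[1]
  doms <- states[states %in% c("LEFT", "RIGHT")]
  r <- rle(doms)
  n_sw <- max(length(r$values) - 1L, 0L)
  mixed <- any(states == "NONE")
  congr <- if (init == "NONE") "undefined"
  else if (init == direction) "congruent" else "incongruent"
  outcome <- if (init == "NONE") "excluded_no_dominance"
  else if (mixed) "excluded_mixed"
  else if (n_sw == 0) "maintained"
  else if (n_sw == 1) "switched" else "multi_switch"
  list(initial_state = init, congruency = congr,
       n_switches = as.integer(n_sw), outcome = outcome)
}

# Greenhouse-Geisser epsilon from the double-centred covariance definition.
gg_eps_oracle <- function(Y) {
  k <- ncol(Y)
  S <- cov(Y)
  Tm <- diag(k) - 1 / k
  Sd <- Tm %*% S %*% Tm
  sum(diag(Sd))^2 / ((k - 1) * sum(Sd * Sd))
}

# Exhaustive sign-flip permutation distribution of the max absolute cluster
# mass, computed with plain loops.
exact_signflip_oracle <- function(D, alpha = 0.025) {
  n <- nrow(D); nb <- ncol(D)
  thr <- qt(1 - alpha, df = n - 1)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  apply(signs, 1, function(s) {
    X <- D * s
    tv <- numeric(nb)
    for (j in seq_len(nb)) {
      x <- X[, j]
      tv[j] <- mean(x) / (sd(x) / sqrt(n))
    }
    cl <- cluster_oracle(tv, thr)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  })
}

# Congruent-probability bins by dense numerical time integration.
trace_bins_oracle <- function(tr, onset, direction, cutoff, n_bins,
                              dt = 2e-4) {
  edges <- onset + cutoff * seq(0, 1, length.out = n_bins + 1)
  vapply(seq_len(n_bins), function(j) {
    times <- seq(edges[j] + dt / 2, edges[j + 1] - dt / 2, by = dt)
    inmat <- outer(tr$start_s, times, "<=") & outer(tr$end_s, times, ">")
    states <- tr$state[max.col(t(inmat), ties.method = "first")]
    dom <- states %in% c("LEFT", "RIGHT")
    if (!any(dom)) return(NA_real_)
    mean(states[dom] == direction)
  }, numeric(1))
}
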