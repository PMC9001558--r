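test_that("segment geometry: matched cutoffs and touch fractions", {
  expect_equal(matched_fast_cutoff(), 5.91)
  sp <- tc_spec()
  expect_equal(sp$touch_fraction, 0.36)
  expect_equal(round(3.2 / 9, 2), 0.36)
  expect_equal(round(2.1 / 5.91, 2), 0.36)
  expect_error(tc_spec(fast_cutoff_s = 8), "differs")
})

test_that("congruency traces time-weight dominance within bins", {
  # fully congruent segment: all bins 1
  tr <- make_trace(c(20), c("RIGHT"))
  v <- congruency_trace(tr, 2, "RIGHT", 9)
  expect_equal(v, rep(1, 36))

  # switch from incongruent to congruent exactly at segment midpoint
  tr2 <- make_trace(c(6.5, 20), c("LEFT", "RIGHT"))
  v2 <- congruency_trace(tr2, 2, "RIGHT", 9)
  expect_equal(v2[1:18], rep(0, 18))
  expect_equal(v2[19:36], rep(1, 18))

  # switch inside a bin: boundary bin is time-weighted; NONE time excluded
  set.seed(77)
  for (i in 1:25) {
    tr3 <- random_lattice_trace(len_s = 13)
    onset <- sample(20:70, 1) * 0.05 + 0.013
    v3 <- congruency_trace(tr3, onset, "RIGHT", 5.91)
    want <- trace_bins_oracle(tr3, onset, "RIGHT", 5.91, 36)
    expect_equal(is.na(v3), is.na(want))
    # oracle is a midpoint rule at dt = 2e-4; bins holding several interval
    # boundaries, or only a sliver of dominance, amplify its grid error
    expect_lt(max(abs(v3 - want), na.rm = TRUE), 0.02)
    expect_true(all(v3 >= 0 & v3 <= 1, na.rm = TRUE))
  }
})

test_that("participant averaging is segments-first, never time-pooled", {
  # segment 1: fully congruent with full dominance (bin prob 1, heavy time);
  # segment 2: only a 10-ms incongruent sliver per bin (bin prob 0, light
  # time). The segment-first mean is 0.5 everywhere; pooling dominance time
  # across segments would give ~0.96.
  tr1 <- make_trace(c(20), c("RIGHT"), trial_id = "T1")
  tr2 <- make_trace(c(rep(c(0.01, 0.24), 36), 11),
                    c(rep(c("LEFT", "NONE"), 36), "RIGHT"), trial_id = "T2")
  traces <- rbind(tr1, tr2)
  events <- data.frame(participant_id = "P01", trial_id = c("T1", "T2"),
                       condition = "A", index_in_trial = 1L,
                       onset_s = c(0, 0), direction = "RIGHT",
                       n_sweeps = 3L, duration_s = 3.2)
  tc <- participant_timecourses(traces, events, c(P01 = "slow"))
  m <- tc_matrix(tc, "A")
  expect_equal(as.vector(m), rep(0.5, 36))
})

test_that("truncated segments are dropped and counted", {
  tr <- make_trace(c(20), c("RIGHT"))
  events <- data.frame(participant_id = "P01", trial_id = "T1",
                       condition = "A", index_in_trial = 1:2,
                       onset_s = c(2, 15), direction = "RIGHT",
                       n_sweeps = 3L, duration_s = 3.2)
  tc <- participant_timecourses(tr, events, c(P01 = "slow"))
  expect_equal(attr(tc, "n_dropped"), 1L)
  expect_equal(attr(tc, "n_segments")$n_segments, 1L)
})

test_that("bin tests mask degenerate bins and convert counts to durations", {
  set.seed(5)
  n_part <- 8
  M <- matrix(0.5, n_part, 36, dimnames = list(sprintf("P%02d", 1:n_part), NULL))
  M[, 5:12] <- 0.9 + rnorm(n_part * 8, 0, 0.01)  # 8 strong bins
  bt <- bin_tests(make_tc(M, "A"), "A", tc_spec())
  expect_true(all(bt$masked[-(5:12)]))  # constant 0.5 bins are masked
  expect_equal(which(bt$sig_mask), 5:12)
  expect_equal(bt$n_sig, 8)
  expect_equal(unname(bt$significant_duration_s["slow"]), 8 * 9 / 36)
  expect_equal(unname(bt$significant_duration_s["fast"]), 8 * 5.91 / 36,
               tolerance = 1e-12)
})

test_that("BH adjustment matches the definitional oracle", {
  set.seed(31)
  for (i in 1:200) {
    m <- sample(5:40, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_adjust_oracle(p))
    q <- runif(1, 0.01, 0.2)
    expect_equal(p.adjust(p, "BH") <= q, bh_reject_oracle(p, q))
  }
  # worked example: (.001, .02, .04, rest large)
  p <- c(0.001, 0.02, 0.04, rep(0.8, 33))
  expect_equal(p.adjust(p, "BH") < 0.05, bh_reject_oracle(p, 0.05))
})

test_that("difference waveforms are participant-wise, antisymmetric, NA-propagating", {
  set.seed(8)
  A <- matrix(runif(5 * 36), 5, dimnames = list(sprintf("P%d", 1:5), NULL))
  B <- matrix(runif(5 * 36), 5, dimnames = list(sprintf("P%d", 1:5), NULL))
  B[2, 7] <- NA
  tc <- rbind(make_tc(A, "a"), make_tc(B, "b"))
  attr(tc, "n_bins") <- 36
  class(tc) <- c("binned_timecourse", "data.frame")
  d1 <- difference_waveform(tc, "a", "b")
  d2 <- difference_waveform(tc, "b", "a")
  expect_equal(d1, -d2)
  expect_true(is.na(d1[2, 7]))
  expect_equal(d1[1, ], A[1, ] - B[1, ])
  # identical conditions: all-zero
  tc2 <- rbind(make_tc(A, "a"), make_tc(A, "b"))
  attr(tc2, "n_bins") <- 36
  class(tc2) <- c("binned_timecourse", "data.frame")
  expect_equal(unname(difference_waveform(tc2, "a", "b")),
               matrix(0, 5, 36))
})

test_that("cluster formation equals a brute-force run scan", {
  set.seed(41)
  for (i in 1:300) {
    t <- rnorm(36, sd = 2)
    t[sample(36, sample(0:6, 1))] <- NA
    thr <- runif(1, 0.5, 2.5)
    expect_equal(find_clusters(t, thr), cluster_oracle(t, thr))
  }
})

test_that("all-zero differences yield no clusters and a zero limit", {
  D <- matrix(0, 6, 36)
  r <- cluster_permutation_test(D, n_perm = 200)
  expect_equal(nrow(r$clusters), 0)
  expect_equal(r$significance_limit, 0)
  expect_true(all(r$perm_max == 0))
})

test_that("exact sign-flip enumeration matches the exhaustive oracle at n = 5", {
  set.seed(55)
  D <- matrix(rnorm(5 * 36, 0, 0.1), 5, 36)
  D[, 8:14] <- D[, 8:14] + 0.25  # genuine positive cluster
  r <- cluster_permutation_test(D, exact = TRUE)
  expect_equal(r$n_perm, 32L)
  want <- exact_signflip_oracle(D)
  expect_equal(sort(r$perm_max), sort(want), tolerance = 1e-12)
  expect_gt(nrow(r$clusters), 0)
  for (k in seq_len(nrow(r$clusters))) {
    expect_equal(r$clusters$p[k],
                 mean(want >= abs(r$clusters$mass[k]) - 1e-8))
  }
  # Monte-Carlo p approaches the exhaustive p
  set.seed(56)
  rmc <- cluster_permutation_test(D, n_perm = 2000)
  expect_equal(rmc$clusters$p, r$clusters$p, tolerance = 0.05)
})

test_that("an injected effect confined to the touch window is detected there", {
  set.seed(60)
  D <- matrix(rnorm(10 * 36, 0, 0.08), 10, 36)
  D[, 2:13] <- D[, 2:13] + 0.2
  r <- cluster_permutation_test(D, n_perm = 500)
  sig <- r$clusters[r$clusters$significant & r$clusters$sign > 0, ]
  expect_gt(nrow(sig), 0)
  expect_lte(sig$start_bin[1], 13)  # overlaps the touch window (bins 1-13)
})

test_that("the literal bins-and-conditions shuffle scheme runs and is calibrated-ish", {
  set.seed(61)
  A <- matrix(runif(6 * 36, 0.4, 0.6), 6, dimnames = list(sprintf("P%d", 1:6), NULL))
  B <- matrix(runif(6 * 36, 0.4, 0.6), 6, dimnames = list(sprintf("P%d", 1:6), NULL))
  r <- cluster_permutation_test(A - B, n_perm = 300, method = "shuffle",
                                cond_a = A, cond_b = B)
  expect_equal(r$n_perm, 300L)
  expect_true(is.finite(r$significance_limit))
})
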