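lat_events <- function(trial_id = "T1", onset = 10, direction = "RIGHT",
                       participant_id = "P01", condition = "A") {
  data.frame(participant_id = participant_id, trial_id = trial_id,
             condition = condition, index_in_trial = 1L, onset_s = onset,
             direction = direction, n_sweeps = 3L, duration_s = 3.2)
}

test_that("latency segments pair unimodal/bimodal windows and scale latencies", {
  # RIGHT until onset + L/2, then LEFT: bimodal latency exactly 0.5
  L <- 4.25
  tr <- make_trace(c(10 + L / 2, 10), c("RIGHT", "LEFT"))
  segs <- build_latency_segments(tr, lat_events(onset = 10), c(P01 = "slow"))
  expect_equal(nrow(segs), 2)
  uni <- segs[segs$kind == "unimodal", ]
  bi <- segs[segs$kind != "unimodal", ]
  expect_equal(uni$start_s, 10 - L)
  expect_equal(bi$start_s, 10)
  expect_equal(bi$length_s, L)
  expect_equal(bi$kind, "bimodal_congruent")  # RIGHT percept, RIGHT touch
  expect_equal(bi$n_switches, 1L)
  expect_equal(bi$first_switch_latency_prop, 0.5)
  expect_equal(uni$n_switches, 0L)
  expect_true(is.na(uni$first_switch_latency_prop))

  # fast group uses the 2.95-s window
  segf <- build_latency_segments(tr, lat_events(onset = 10), c(P01 = "fast"))
  expect_equal(unique(segf$length_s), 2.95)
})

test_that("only single-switch segments contribute latencies", {
  tr <- make_trace(c(10.5, 1, 1, 10), c("RIGHT", "LEFT", "RIGHT", "LEFT"))
  segs <- build_latency_segments(tr, lat_events(onset = 10), c(P01 = "slow"))
  bi <- segs[segs$kind != "unimodal", ]
  expect_equal(bi$n_switches, 3L)
  m <- participant_latency_means(segs)
  expect_equal(nrow(m), 0)  # 0-switch unimodal and 3-switch bimodal excluded
})

test_that("window-edge pairs are dropped and counts stay equal per participant", {
  tr <- make_trace(c(48), c("RIGHT"))
  ev <- rbind(lat_events(onset = 3), lat_events(onset = 10),
              lat_events(onset = 46))
  ev$index_in_trial <- 1:3
  segs <- build_latency_segments(tr, ev, c(P01 = "slow"))
  expect_equal(attr(segs, "n_dropped_pairs"), 2L)  # 3 - 4.25 < 0; 46 + 4.25 > 48
  expect_equal(sum(segs$kind == "unimodal"),
               sum(segs$kind != "unimodal" | is.na(segs$kind)))

  # NONE at onset: bimodal kind undefined but the pair is kept
  trn <- make_trace(c(9, 2, 37), c("RIGHT", "NONE", "LEFT"))
  segn <- build_latency_segments(trn, lat_events(onset = 10), c(P01 = "slow"))
  expect_true(is.na(segn$kind[2]))
})

test_that("the within-subject ANOVA matches the car oracle on random designs", {
  set.seed(91)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    d <- expand.grid(participant_id = sprintf("S%d", 1:n),
                     condition = c("c1", "c2"), kind = c("k1", "k2", "k3"),
                     stringsAsFactors = FALSE)
    d$latency <- rnorm(nrow(d), 0.5, 0.1) +
      rep(rnorm(n, 0, 0.05), times = 6) +
      ifelse(d$kind == "k2" & runif(1) < 0.5, 0.08, 0)
    a <- rm_anova_within(d)
    Y <- matrix(tapply(d$latency, list(d$participant_id, d$condition, d$kind),
                       mean), nrow = n)
    idata <- expand.grid(condition = c("c1", "c2"), kind = c("k1", "k2", "k3"))
    av <- suppressWarnings(summary(car::Anova(lm(Y ~ 1), idata = idata,
                                              idesign = ~ condition * kind,
                                              type = 3),
                                   multivariate = FALSE))
    ut <- av$univariate.tests
    expect_equal(a$F, unname(ut[2:4, "F value"]), tolerance = 1e-8)
    expect_equal(a$p, unname(ut[2:4, "Pr(>F)"]), tolerance = 1e-8)
    expect_equal(a$gg_epsilon[2:3], unname(av$pval.adjustments[, "GG eps"]),
                 tolerance = 1e-8)
    expect_equal(a$p_gg[2:3], unname(av$pval.adjustments[, "Pr(>F[GG])"]),
                 tolerance = 1e-8)
    expect_equal(a$mauchly_p[2:3],
                 unname(av$sphericity.tests[, "p-value"]), tolerance = 1e-8)
  }
})

test_that("epsilon via orthonormal contrasts equals the double-centring oracle", {
  set.seed(17)
  for (i in 1:300) {
    k <- sample(3:5, 1)
    n <- sample((k + 1):12, 1)
    Y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k, sd = 0.7), k)
    expect_equal(gg_epsilon(Y), gg_eps_oracle(Y), tolerance = 1e-10)
    eps <- gg_epsilon(Y)
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }
})

test_that("ANOVA degenerate cases behave: zero effects, 2-level epsilon, SS partition", {
  set.seed(23)
  n <- 6
  d <- expand.grid(participant_id = sprintf("S%d", 1:n),
                   condition = c("c1", "c2"), kind = c("k1", "k2", "k3"),
                   stringsAsFactors = FALSE)
  d$latency <- rnorm(nrow(d))
  # centre every cell so all cell means are equal: every F is exactly 0
  cellmean <- ave(d$latency, d$condition, d$kind)
  d0 <- d; d0$latency <- d$latency - cellmean
  a0 <- rm_anova_within(d0)
  expect_equal(a0$F, rep(0, 3), tolerance = 1e-12)

  a <- rm_anova_within(d)
  expect_equal(a$gg_epsilon[a$effect == "A"], 1)  # 2-level factor
  expect_true(is.na(a$mauchly_p[a$effect == "A"]))
  ss <- attr(a, "ss")
  expect_equal(sum(ss$SS[ss$term != "total"]), ss$SS[ss$term == "total"])
  expect_true(all(a$eta_g_sq >= 0 & a$eta_g_sq <= 1))
  expect_error(rm_anova_within(d[d$participant_id %in% c("S1", "S2"), ]),
               "at least 3")
})

test_that("paired contrasts use Bonferroni capping and zero-variance conventions", {
  m <- expand.grid(participant_id = sprintf("S%d", 1:8), condition = "A",
                   kind = c("k1", "k2", "k3"), stringsAsFactors = FALSE)
  set.seed(3)
  m$latency <- runif(nrow(m), 0.3, 0.7)
  # identical vectors for k1 and k2
  m$latency[m$kind == "k2"] <- m$latency[m$kind == "k1"]
  ct <- paired_contrasts(m, condition = "A")
  r12 <- ct[ct$pair == "k1 - k2", ]
  expect_equal(r12$t, 0)
  expect_equal(r12$p_adj, 1)
  expect_equal(ct$p_adj, pmin(1, 3 * ct$p_raw))
  expect_equal(nrow(ct), 3)
})

test_that("an injected stabilising/destabilising effect orders the latencies", {
  cfg <- tiny_cfg(n_participants = 6,
                  switcher_profile = rep(c("slow", "fast"), 3),
                  n_trials_per_condition = 10, seed = 44)
  ds <- simulate_dataset(cfg)
  clean <- remove_artifacts(remap_vertical(ds$traces))
  groups <- setNames(ds$participants$group, ds$participants$participant_id)
  segs <- build_latency_segments(clean, ds$events, groups)
  mm <- participant_latency_means(
    segs[segs$condition == "parallel_aligned_invisible", ])
  km <- tapply(mm$latency, mm$kind, mean)
  # congruent-at-onset percepts are stabilised (late switches), incongruent
  # destabilised (early switches), the visual-only baseline in between
  expect_gt(km[["bimodal_congruent"]], km[["unimodal"]])
  expect_gt(km[["unimodal"]], km[["bimodal_incongruent"]])
})
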