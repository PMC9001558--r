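# rivaltact

Event-locked analysis of tactile influences on binocular rivalry.

When two incompatible gratings are shown one to each eye, perception
alternates between them (binocular rivalry). A collocated tactile motion
stimulus delivered to the fingerpad can bias these alternations — but only
when the visual and tactile motions share an axis and a spatial location.
`rivaltact` packages the full analysis chain for experiments of this kind,
where participants track the dominant percept with button presses while
brief tactile sweep trains are delivered at known onsets, together with a
stochastic simulator of such recordings for power analysis, calibration and
parameter-recovery studies.

## What the package computes

For button-press traces `x(t) ∈ {LEFT, RIGHT, NONE}` and tactile events with
onset `t_k`, direction `d_k` and duration `τ` (2.1 s or 3.2 s, calibrated to
each participant's switch rate):

* **Segment classification.** Each tactile event defines a segment starting
  at `t_k`. Its congruency is `1{x(t_k) = d_k}`; its outcome is *maintained*
  (no direction switch during the touch), *switched* (exactly one), or an
  exclusion (multiple switches, mixed percepts, no dominance at onset).
* **Switch-probability GLMM.** For single-switch-or-maintained segments,
  `switch ~ condition × congruency + (1 | participant)` with a logit link
  (binomial, Laplace ML). The interaction is tested by a likelihood-ratio
  test, `χ² = 2(ℓ_full − ℓ_reduced)` on 1 df, and followed up by pairwise
  contrasts of estimated marginal means on the probability scale.
* **Congruent-probability timecourses.** The instantaneous probability that
  the dominant percept is congruent with the tactile direction, on a
  normalised time axis (segments cut at 9 s for slow switchers, 5.91 s for
  fast, so the touch occupies 0.36 of every segment), binned into 36 bins,
  averaged segments → participant → group. Bins are tested against chance
  (0.5) with two-tailed one-sample t-tests, Benjamini–Hochberg corrected
  (α = .025). Condition differences are tested with a cluster-mass
  permutation test: bins with `|t| > t_{.975, n−1}` form sign-consistent
  adjacent clusters scored by `Σt`; 1,000 participant-wise sign flips give
  the null distribution of the maximum absolute mass, whose 95th percentile
  is the significance limit.
* **First-switch latencies.** Equal-length unimodal `[t_k − L, t_k)` and
  bimodal `[t_k, t_k + L)` segments (`L` = 4.25 s slow / 2.95 s fast); the
  latency of the single switch, as a proportion of `L`, enters a 2 × 3
  within-subject ANOVA (condition × segment kind) with Mauchly's sphericity
  test, Greenhouse–Geisser correction and generalized η², plus
  Bonferroni-corrected paired contrasts.

The simulator generates the same trial structure (48-s trials, 4 tactile
stimuli, first at 8 s then every 10 ± 1 s) as an alternating gamma renewal
process whose switch hazard is multiplied by a configurable factor while a
tactile stimulus is on — below 1 for direction-congruent stimulation
(stabilising), above 1 for incongruent (destabilising) — gated to the
conditions where the effect should exist.

## Worked example

```r
library(rivaltact)

cfg <- sim_config(conditions = c("parallel_aligned_invisible", "orthogonal_aligned"),
                  effect_conditions = "parallel_aligned_invisible", seed = 11)
rep <- run_pipeline(cfg, n_perm = 1000)
print(rep)
```

```
rivalry pipeline report (seed 11 )
conditions contrasted: parallel_aligned_invisible vs orthogonal_aligned

GLMM interaction LRT: chi2(1) = 213.40, p = 2.484e-48
response-scale congruency contrasts:
               level_pair                  condition estimate_prob_scale       z         p
1 congruent - incongruent parallel_aligned_invisible             -0.6850 -25.003 5.69e-138
2 congruent - incongruent         orthogonal_aligned              0.0284   0.744  4.57e-01

cluster test: 2 cluster(s), significance limit 23.30
  start_bin end_bin sign  mass     p significant
1         2      18    1 195.0 0.000        TRUE
2        23      28   -1 -15.2 0.101       FALSE

latency ANOVA (A = condition, B = segment kind):
  effect      F df_num_gg df_den_gg p_reported gg_epsilon eta_g_sq
1      A   1.37      1.00      13.0   2.63e-01      1.000   0.0287
2      B 131.59      1.71      22.3   2.51e-14      0.857   0.6837
3    A:B  83.08      1.99      25.9   5.09e-12      0.997   0.6965
```

Reading the report: the simulated congruency effect is active only in the
parallel-aligned condition, and every analysis localises it there. The
congruency × condition interaction is decisively flagged (χ²(1) = 213.4);
the response-scale contrast shows switching is ~69 percentage points more
likely from incongruent than congruent onsets in the parallel condition and
flat in the orthogonal one. The cluster test finds one significant positive
cluster (bins 2–18) overlapping the touch window (bins 1–13 of 36), i.e.
the dominant percept is drawn toward the tactile direction during and just
after stimulation. The latency ANOVA shows a large segment-kind effect:
congruent-at-onset percepts are stabilised (late first switches),
incongruent-at-onset percepts are destabilised (early switches), with the
visual-only baseline in between.

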