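---
title: "Methods: event-locked analysis of tactile influences on binocular rivalry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked analysis of tactile influences on binocular rivalry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rivaltact` implements a complete analysis chain for binocular-rivalry
experiments with event-locked tactile perturbations, together with a
generative simulator of such recordings. This vignette documents the
models, the conventions the implementation commits to where the design was
genuinely open, the numerical choices, and what the simulation-based tests
do and do not establish.

## The experimental structure being modelled

Participants view two gratings drifting in opposite directions, one per
eye, and hold a button for the currently dominant direction (releasing both
during mixed percepts). Trials last 48 s and carry four tactile sweep
trains delivered to the fingerpad: the first at 8 s, the rest every
10 ± 1 s (uniform jitter), directions counterbalanced two-left/two-right
per trial. Stimulus length is calibrated per participant: 2 sweeps (2.1 s
including 100-ms inter-sweep pauses) for *fast* switchers (mean dominance
below 3 s), 3 sweeps (3.2 s) for *slow* switchers. Conditions vary whether
the visual motion axis is parallel or orthogonal to the tactile sweeps,
whether the stimuli are spatially aligned, and whether the hand is visible;
a congruency effect is expected only with parallel axes and spatial
alignment.

## The simulator

### Dominance model

Dominance durations are drawn from a gamma distribution — the standard
empirical description of rivalry phase durations, which are unimodally
right-skewed with a coefficient of variation near 0.5. The shape parameter
defaults to 3.5 (CV ≈ 0.53) and is a configuration knob (`gamma_shape`);
the means default to the two cohort values the analysis is calibrated
around, 3.53 s (slow) and 2.16 s (fast). Because every analysis with a
random intercept needs genuine between-participant heterogeneity,
participant-specific means deviate from their cohort mean by a lognormal
factor with coefficient of variation `participant_cv = 0.08`, chosen once
to be of the order of the cohort-level dispersion of mean dominance
durations (a few percent to ~10 % of the mean) and not revisited.

### Tactile modulation

The tactile effect is a multiplicative, memoryless modulation of the
instantaneous switch hazard of the currently dominant percept, active
exactly while a tactile stimulus is on and only in conditions listed in
`effect_conditions`: the hazard is multiplied by `hazard_mult_congruent`
(default 0.4, stabilising) when the dominant direction matches the sweep
direction, and by `hazard_mult_incongruent` (default 3, destabilising)
otherwise. This mechanism was chosen because it simultaneously produces the
two signatures the analyses look for — extended dominance of congruent
percepts and curtailed suppression (earlier switches) of incongruent ones —
time-locked to stimulus on- and offset.

Sampling is exact, not discretised: with baseline cumulative hazard
`H0(a) = −log(1 − F_gamma(a))` and a piecewise-constant multiplier `m(t)`,
the percept age at switch solves `Σ m_i [H0(a_{i+1}) − H0(a_i)] = E`,
`E ~ Exp(1)`, inverted piece by piece through the gamma quantile function.
Percepts surviving to the trial end are right-censored.

### Mixed percepts, axes, RNG

Transitions pass through a `NONE` (mixed) gap with probability
`p_mixed = 0.2`; gap durations are lognormal with mean 0.4 s
(`sdlog = 0.5`). Real recordings contain such gaps and the preprocessing
rules must be exercised by them; the rate itself is a plausible round
figure, not an estimate. Orthogonal-axis trials are generated with
`UP`/`DOWN` states, which the preprocessing remaps. All randomness derives
from one seed through per-trial L'Ecuyer-CMRG substreams in enumeration
order, so a fixed configuration reproduces bitwise-identical datasets.
Datasets serialise to CSV plus a JSON sidecar carrying the configuration
and seed; doubles are written with 17 significant digits so the round trip
is lossless.

The simulator is deliberately not a neural model: there is no adaptation,
no mutual inhibition, no serial correlation between successive durations,
and no response-latency smearing of button presses. Tests that pass on this
generator therefore certify the *analysis chain* (correct segmentation,
calibrated error rates, recovery of hazard-level effects), not the
biological fidelity of any particular dataset.

## Preprocessing

Dominance reports of 180 ms or less (`≤`, boundary included) are artefacts
and are relabelled `NONE` rather than merged into a neighbour — merging
would fabricate dominance time the participant never reported. Mixed time
and relabelled time are accounted per trial. Vertical responses are mapped
`UP → LEFT`, `DOWN → RIGHT`, mirroring the button assignment, so congruency
is defined in every condition. Switcher classification uses the strict rule
*fast iff mean dominance < 3 s*; in the pipeline the configured profile
(the simulated analogue of a practice-block calibration) is used for
stimulus length and segment geometry, with `dominance_stats()` as the
empirical check.

## Segmentation conventions

Where the segment definitions admitted more than one reading, the package
fixes these conventions:

* Intervals are half-open `[start, end)`; the state *at* tactile onset is
  right-continuous (the interval starting at the onset instant wins).
* Switches are direction reversals, counted through `NONE`:
  `LEFT→NONE→LEFT` is zero switches, `LEFT→NONE→RIGHT` is one. A switch
  happens at the instant the new direction becomes dominant.
* Segments with mixed time during the touch are excluded from the
  switch-probability model only; the timecourse analysis keeps them and
  handles `NONE` by time-weighted exclusion within bins (a bin's value is
  congruent dominance time over total dominance time; all-`NONE` bins are
  missing).
* Single tactile stimuli never mix sweep directions; the congruency
  analyses presuppose one direction per stimulus.

## Switch-probability GLMM

The model is binomial with logit link, fixed factors condition (2 levels)
and onset congruency (2 levels), optionally their interaction, and a random
intercept per participant, fitted by Laplace-approximated maximum
likelihood via `lme4::glmer` (bobyqa). The interaction is assessed by the
likelihood-ratio statistic `2(ℓ_full − ℓ_reduced)` against χ²(1), clipped
at zero. Follow-up contrasts are differences of estimated marginal means on
the probability scale (inverse link applied first, delta-method standard
errors, two-sided z-tests), computed at the population level (random
intercept at its zero mean) via `emmeans`; no multiplicity correction is
applied across the two per-model contrasts. Zero-variance (singular) random
effects are reported with a boundary flag rather than suppressed; in that
regime the fit provably collapses onto pooled logistic regression, which
the tests pin to 10⁻³.

## Timecourse and cluster-mass permutation test

Segment cutoffs are 9 s (slow) and 5.91 s (fast); 5.91 is the
proportion-matched value `2.1 × 9 / 3.2` rounded to two decimals, making
the touch fraction 0.36 in both groups. The normalised axis is divided into
36 half-open bins (last bin closed). Averaging order is fixed and
test-pinned: segments → participant × condition mean → group statistics.
Per-bin tests against chance are two-tailed one-sample t-tests with
Benjamini–Hochberg correction over the timecourse's bins at α = .025; bins
with fewer than two contributing participants or zero variance are masked,
never reported as infinite t.

For condition contrasts the package forms per-participant difference
waveforms and runs a cluster-mass permutation test. The permutation scheme
is participant-wise sign flipping of the difference traces — the standard
exchangeability argument for paired designs. A literal scheme that shuffles
each participant's responses across bins and conditions is also available
(`method = "shuffle"`) for comparison, but it breaks the temporal structure
within traces and is not the default. Clustering is two-sided: positive and
negative supra-threshold runs (`|t| > t_{.975, n−1}`) form separate
clusters; missing bins break adjacency (conservative); the significance
limit is the 95th percentile of the permuted maximum absolute cluster mass,
and per-cluster Monte-Carlo p-values are reported alongside. The observed
t-vector is computed through the same vectorised arithmetic as the
permuted ones, so the identity sign assignment ties the observed mass
exactly and the `>=` comparisons are free of floating-point asymmetry. With
`exact = TRUE` all `2^n` sign assignments are enumerated, which the tests
compare against an independent exhaustive oracle at n = 5.

## First-switch latencies

Unimodal segments are marked backwards from each onset, bimodal segments
forwards, both of length 4.25 s (slow) or 2.95 s (fast). 4.25 s is taken as
printed in the design rather than recomputed as half of 9 s; the pairing
guarantees equal unimodal/bimodal counts per participant before the
single-switch filter. Bimodal kinds are labelled by congruency *at onset*;
note the inversion relative to switch-destination language: a switch inside
a congruent-at-onset segment is a switch *to incongruence*, so a
stabilising congruent effect shows up as `bimodal_congruent` having the
longest latencies and `bimodal_incongruent` the shortest, with the
unimodal baseline between.

The 2 × 3 ANOVA uses the classical within-subject decomposition with each
effect tested against its own participant-interaction error term. Mauchly's
test (conventional .05 threshold; the design leaves it unstated) decides
whether Greenhouse–Geisser corrected degrees of freedom are reported;
ε is computed from the covariance of orthonormal contrast scores as
`tr(M)²/(d·tr(M²))` and floored at `1/d`. Effect sizes are generalized η²
in the all-within form (effect SS over effect SS plus all subject-related
SS). The implementation is validated against `car::Anova` (F, ε, GG p,
Mauchly p) and against a double-centring ε oracle on random designs.
Paired contrasts are two-sided paired t-tests with p-values multiplied by
the number of comparisons (capped at 1); identical vectors conventionally
give t = 0, p = 1 instead of a zero-variance error.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to make their statistical
assertions sharp while keeping the suite fast to iterate on, and are stated
here as the package's own choices. Parameter recovery uses 20 seeded
replicates of the standard design (14 participants, 9 slow / 5 fast, 16
trials per condition, two conditions, multipliers 3 / 0.4 gated to the
parallel-aligned condition), asserting ≥ 80 % detection of the GLMM
interaction and of a significant positive cluster overlapping the touch
window, and the latency ordering on replicate-averaged means. Null
calibration uses 200 replicates of a reduced design (10 participants, 8
trials per condition, multipliers 1), asserting the pre-FDR bin rejection
rate lies in (0.010, 0.045) around the nominal .025 and that cluster and
GLMM false-positive rates lie in (0.005, 0.105) around the nominal .05 —
roughly 99 % binomial bands fixed before running. Oracle-equivalence checks
use 1,000 random instances each for BH, cluster formation, segment
classification and Greenhouse–Geisser ε, plus exact 2⁵ enumeration of the
sign-flip distribution at n = 5.

## Known limitations

* The simulator's renewal process has independent successive durations;
  real rivalry shows weak serial correlations and adaptation, so absolute
  power figures from simulation transfer to real data only approximately.
* Response latency and motor noise in button presses are not modelled; in
  real data the onset-state classification inherits the participant's
  report lag.
* The GLMM uses random intercepts only (no random slopes), matching the
  target analysis; heterogeneous tactile susceptibility across participants
  would call for slopes.
* Latency proportions are analysed with a Gaussian ANOVA although they live
  in (0, 1]; with strong effects pushing means toward the boundaries the
  normality approximation coarsens.
* The literal bins-and-conditions shuffle permutation is provided for
  comparison but has no exchangeability guarantee for temporally structured
  waveforms; conclusions should rest on the sign-flip scheme.
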