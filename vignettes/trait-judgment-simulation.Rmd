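---
title: "Staircase-controlled trait judgments: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staircase-controlled trait judgments: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitjudge)
```

## The problem and the model

Two-alternative judgments about subjective material — here, whether a
group of trait adjectives better describes oneself or a well-known other
person — have no external ground truth. The package adopts the
standard-rating solution: each adjective carries a pair of 0–100
visual-analog ratings (self, other) elicited separately, and the
evidence of a word is `e = self − other`. "Correct" means choosing the
response the trial's stimuli were constructed to favor. Everything else
in the package is the machinery that (a) constructs such trials at a
controlled difficulty and (b) analyzes the resulting choices and
confidence reports the way psychophysics analyzes perceptual decisions.

### Difficulty control

A weighted up-down staircase per condition moves along the major
diagonal of the rating square (the locus `self + other = 100`, which
traverses every evidence value). One step down after a correct
response, 2-2-3 steps up (cycling; the cycle advances only on errors)
after an error. Expected movement is zero when
`p = ū/(ū + d) = (7/3)/(7/3 + 1) = 0.7`, so the staircase holds accuracy
near 70% regardless of the observer's sensitivity — the session merely
converges at a different diagonal position. Each staircase starts at
the median evidence of the words favoring its condition. The step is
the evidence range divided by 20; by default the theoretical range
(200, giving step 10) rather than the participant's empirical range,
because the theoretical scale is what the caps at ±100 refer to (an
`empirical` mode is available). The 2-2-3 cursor is kept per staircase,
matching the per-staircase phrasing of the update rule.

### Stimulus sampling

Words for a trial are drawn from an isotropic bivariate Gaussian at the
staircase's diagonal point. Because adjective ratings occupy the space
non-uniformly, raw Gaussian weighting would over-represent dense
evidence regions; each word's weight is therefore divided by a kernel
density estimate of the lexicon's evidence values, evaluated at the
word's own evidence. Density is estimated in 1D over `e` (the quantity
the staircase controls), not in 2D: the correction's purpose is to keep
the *evidence* marginal of sampled words faithful to the Gaussian.
Draws are sequential without replacement with renormalization, then the
four words are shuffled so every word–position pairing is equally
likely.

Numerical choices:

* **Bandwidth.** `"auto"` uses Silverman's rule (`bw.nrd0`), adequate
  for the roughly unimodal evidence spreads that correlated bivariate
  ratings produce. For strongly clustered evidence Silverman
  over-smooths, the estimated density under-tracks the peaks, and the
  corrected marginal stays measurably distorted; `"sj"`
  (Sheather–Jones) is provided and recommended there.
* **Expected ratings.** Reverse correlation needs each trial's expected
  stimulus. The package logs the mean rating under the trial's actual
  selection distribution (`sum(p_w * rating_w)`), alongside the raw
  diagonal center. On a finite lexicon the selection mean is the
  correct zero point: the sampler is mildly attracted toward the
  lexicon's dense regions (KDE smoothing is imperfect; this is also why
  accuracy control degrades slightly toward the edges of the stimulus
  space), and defining fluctuations against the raw center would leak
  that attraction into every weight as a per-participant offset.
* **Sigma and calibration.** The Gaussian SD starts at `sigma_scale`
  (default 0.25) times the distance between the two staircase start
  positions on the evidence scale. Because word density differs between
  the two conditions' regions, equal sigmas can produce unequal spreads
  of sampled ratings; `calibrate_sigma()` equalizes the empirical
  variance of sampled ratings across conditions by a secant iteration
  on log-variance against log-sigma (the response slope is ≈2 while the
  Gaussian dominates and flattens when the local word supply
  saturates), to a relative tolerance of 0.1 by default.
* **Degenerate inputs.** All-equal evidence yields a uniform density
  with a warning; a selection Gaussian so remote that every weight
  underflows falls back to the nearest word with a warning; sampling
  ties at probability zero are resolved uniformly.

### Simulated observers

The rating generator draws (self, other) pairs from a bivariate
Gaussian, mean 50, SD 20, correlation 0.3 — a similar-but-different
other; clamped to the scale. An `e_clusters` mode generates deliberately
multimodal evidence for sampler stress-tests. A `rating_bias` parameter
exists for studying systematically inflated self ratings but defaults to
0, since no generative form for such bias is established.

Choices follow `d = mean(self − other) + ε`, `ε ~ N(0, 15)`: the sign of
`d` is the response. With this noise level the probability of a correct
response rises smoothly through 0.7 well inside the staircase range and
exceeds 0.9 at the caps, which is what difficulty control requires.

Confidence comes in two generative flavors:

* **balanced** — `offset + gain·|d| + η`, with `d` the *same* noisy
  internal variable that produced the choice. Sharing the internal noise
  is the standard assumption behind metacognitive effects: it is what
  makes high-confidence trials genuinely more stimulus-driven, and hence
  produces steeper choice functions for confident trials. (Confidence
  computed from the noiseless stimulus alone splits trials by a function
  of the regressor and leaves the true choice curve untouched — the
  slope contrast then all but disappears, which is diagnostic, not
  desirable, for a generative stand-in.)
* **positive_evidence** — `offset + gain·(mean rating on the chosen
  dimension − its expected value) + η`: confidence reads only the
  evidence congruent with the decision just made.

The confidence constants (gain 0.7, offset 38, report noise SD 13) are
calibrated so a default balanced observer reports confidence with mean
≈ 49, SD ≈ 15 and a correct-minus-error gap ≈ 6 on the 0–100 scale —
the coarse metacognitive resolution typical of human observers in
uncertain trait judgments. Simulated confidence weights and
median-split contrasts therefore carry human-scale statistical power,
not an idealized one.

### Analyses

**Stimulus strength** is the mean rating favoring the trial's target
minus the mean rating favoring the non-target, standardized per
participant by dividing by its SD (n−1). The per-participant mean is
*not* subtracted by default: zero strength must remain "a stimulus
carrying no net evidence", the point where an unbiased observer is at
chance and where the choice-function intercept measures response bias.
The staircase deliberately keeps the *average* stimulus informative, so
mean-centering would relocate zero to roughly the staircase equilibrium
(intercepts near `logit(0.7)` for every observer, bias or none).
`center = TRUE` gives conventional z-scores when wanted.

**Choice functions** are maximum-likelihood logistic regressions of
correctness on strength (via `glm`), fitted per participant × condition
× confidence level. Confidence levels come from a per-participant
median split with ties going to "low" — deterministic, and conservative
for the high-confidence contrast. Complete separation is detected
beforehand and flagged with its direction; non-converged fits are
excluded from aggregation and counted rather than clamped.

**Reverse correlation** divides raw fluctuations by their SD over all of
a participant's trials, pooled over word positions, separately per
rating dimension — the most literal reading of "their standard deviation
over all trials" (a per-position variant is selectable). Per trial the
two dimensions are relabelled chosen/non-chosen by the response, and
weights are choice-conditioned means per congruence × position — the
classification-image estimator, whose sign convention (positive chosen,
negative non-chosen) matches how such weights are usually displayed.
Confidence weights are high-minus-low decision weights, with the
normalizing SD computed before splitting so both levels share one scale.

**Inference.** The two-way repeated-measures ANOVA decomposes a complete
subject × congruence × position table with each effect tested against
its own subject-interaction stratum; effect sizes are generalized eta
squared with all error strata plus the subject SS in the denominator
(the Olejnik–Algina form for fully within designs). Sphericity
corrections are not applied: the critical congruence factor has two
levels and needs none. Zero-error strata are reported as exact fits
rather than errors. The symmetry test runs the ANOVA twice — raw, and
with the non-chosen row negated — and calls the weights mirror-symmetric
when the raw congruence effect is present but the post-inversion effect
size falls below a smallness threshold (default η²g < .01). Bayes
factors are out of scope; the η²g smallness criterion stands in their
place. t tests delegate to `t.test`, with an explicit error on
zero-variance input (and the convention that an all-zero difference
vector is t = 0, not an error).

## What the simulations establish — and what they do not

The generator emulates: continuous standard ratings with a plausible
self–other correlation, staircase-controlled difficulty, density-
corrected sampling, balance-of-evidence choices, and two confidence
rules bracketing the metacognitive hypotheses of interest. Passing
tests show the *pipeline* is correct and that the qualitative
signatures (symmetric decision weights; steeper high-confidence choice
functions; discounted non-chosen evidence under decision-congruent
confidence) are recoverable at realistic sample sizes.

They do not show that human raters behave like the generator: real
standard ratings carry measurement error and possibly systematic bias
the generator omits (`rating_bias` exists but defaults to 0); real
confidence may mix the two rules; word meanings correlate in ways
synthetic lexica do not; and effect magnitudes in human data depend on
internal noise the package makes no claim about. Reported human effect
sizes are therefore treated as qualitative patterns, not numeric
targets.

## Problem sizes

The test suite and acceptance script run, by choice, at the scale a
simulation study of this design would use: single sessions of 306
(the experiment's length) to 20,000 trials for equilibrium checks, and
batches of 20 observers × 2,000 trials for weight-recovery and
choice-function contrasts — enough for the congruence effect to be
estimated with subject-level noise well below its size, while a desk
machine completes the whole suite in a few minutes.

## Known limitations

* The sampler's residual attraction toward dense lexicon regions means
  difficulty control is slightly asymmetric near the edges of the
  stimulus space; narrowing selection toward the edges would mitigate
  this but is not implemented.
* `calibrate_sigma` equalizes total sampled-rating variance, one
  plausible reading of "comparable variance"; other criteria (per-
  dimension, per-trial) would differ in detail.
* The CLI covers simulation and analysis of logs; it does not present
  stimuli to human participants.
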