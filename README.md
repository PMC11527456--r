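# traitjudge

Simulation and analysis of **staircase-controlled two-alternative
personality-trait judgments**.

Subjective choices — "do these adjectives describe *me*, or my friend
David?" — lack the ground truth that makes perceptual decisions so
tractable in the laboratory. A workable substitute is a separately
assessed **standard rating**: before the choice task, the participant
rates every adjective once for how well it describes themself and once
for how well it describes the other person, on a 0–100 visual-analog
scale. The evidence a word carries is then

```
e = self rating − other rating        e ∈ [−100, 100]
```

and the standard toolbox of psychophysics applies: adaptive difficulty
control, psychometric functions, reverse correlation, confidence
analysis. `traitjudge` implements that toolbox end to end for simulated
observers, so the stimulus-control machinery and the analyses can be
validated — and their statistical behavior studied — before any human is
tested.

It is aimed at researchers in decision making and metacognition who want
to run, extend or power-analyze this class of experiments.

## What the package implements

**Stimulus control.** Two weighted up-down staircases (one per target
condition) move along the major diagonal of the (self, other) rating
square. A correct response moves the staircase one step toward harder
trials; an error moves it 2, 2 or 3 steps (cycling in that order) toward
easier ones, with step size = evidence range / 20 and positions capped at
±100. The equilibrium accuracy solves `p·d = (1−p)·ū`:

```
p = ū / (ū + d) = (7/3) / (7/3 + 1) = 0.7
```

Per trial, four distinct adjectives are drawn from an isotropic Gaussian
centered at the staircase's diagonal position, with each word's
probability divided by the kernel-density estimate of words on the
evidence scale (so overpopulated evidence regions are not
overrepresented), then shuffled in place across screen positions.
Per-condition Gaussian widths are calibrated so the sampled-rating
variance is comparable across conditions.

**Simulated observers.** Choices follow a balance-of-evidence rule,
`d = mean(self − other) + ε`, `ε ~ N(0, σ_choice)`. Confidence follows
either a **balanced** rule (`offset + gain·|d| + η`, reusing the same
noisy internal evidence) or a **positive-evidence** rule (`offset +
gain·(mean rating on the chosen dimension − its expected value) + η`),
the generative form of decision-congruent confidence.

**Analysis.** Logistic choice functions of standardized stimulus
strength per participant × condition × confidence median-split; reverse
correlation of choices and confidence against the sampling fluctuations
(rating − expected rating), normalized by their SD and relabelled
chosen/non-chosen, giving 2 × 4 decision- and confidence-weight
matrices; two-way repeated-measures ANOVA with generalized eta squared
(η²g), the weight-inversion symmetry test, and per-position t tests for
the positive evidence bias.

## Worked example

Eight balanced-evidence observers, 800 trials each:

```r
library(traitjudge)

logs <- do.call(rbind, lapply(1:8, function(i) {
  lex <- generate_fixture_lexicon(104, seed = 10 + i)
  obs <- observer_params()                       # balanced observer
  rat <- generate_standard_ratings(lex, obs, seed = 40 + i)
  run_session(lex, rat, obs, session_config(n_trials = 800, seed = 70 + i),
              participant_id = sprintf("p%02d", i))
}))

symmetry_test(decision_weights(logs))
```

```
Repeated-measures ANOVA (within-subject: congruence x position )
  congruence           F(1,7) = 24.427, p = 0.001671, ges = 0.4762
  ...
Repeated-measures ANOVA (within-subject: congruence x position )   # non-chosen row inverted
  congruence           F(1,7) = 0.185, p = 0.6798, ges = 0.0024
symmetric: TRUE
```

The congruence effect is large before inversion (η²g = .48: chosen-word
fluctuations push choices one way, non-chosen fluctuations the other)
and vanishes after mirroring the non-chosen row (η²g = .002): decision
weights are symmetric, the signature of a balance-of-evidence rule.

```r
agg <- aggregate_fits(fit_choice_functions(logs))
agg$cells[agg$cells$condition == "all", c("confidence_level", "mean_intercept", "mean_slope")]
#>  confidence_level mean_intercept mean_slope
#>               all         -0.008       1.70
#>               low          0.049       1.27
#>              high         -0.129       2.41
```

Intercepts sit at 0 — an unbiased observer is at chance for a neutral
stimulus — and high-confidence trials show the steeper choice function.
A `positive_evidence` observer run through the same pipeline yields
confidence weights near zero for the non-chosen dimension but positive
for the chosen one (`confidence_weights()`, `confidence_bias_test()`),
the positive evidence bias.

A command-line interface wraps the same pipeline:

```sh
inst/cli/traitjudge simulate --out log.csv --seed 7
inst/cli/traitjudge analyze report log.csv
inst/cli/traitjudge analyze weights log.csv --kind confidence --out w.csv
```

## Documentation

The methods vignette (`vignettes/trait-judgment-simulation.Rmd`) details
the model assumptions, parameter choices and their calibration, the
numerical decisions, and what the simulations do and do not establish
about real data.
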