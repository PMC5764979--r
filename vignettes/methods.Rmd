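---
title: "Divisively normalized value coding: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisively normalized value coding: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuenorm)
```

## The scientific problem

Single neurons in medial orbitofrontal cortex fire at rates that track not the
absolute value of a reward option but its value *relative to the alternative
on offer*. The canonical computational account of such relative coding is
divisive normalization: the response to option 1 is its value divided by the
summed value context,

$$R = R_{\max}\,\frac{\beta + \mathrm{EV}_1}{\sigma + \mathrm{EV}_1 + \mathrm{EV}_2},$$

with $R_{\max}$ the response ceiling (spikes/s), $\beta$ (µl) setting the
theoretical output $R_{\max}\beta/\sigma$ when both values are zero, and
$\sigma$ (µl) setting value sensitivity (larger $\sigma$, flatter tuning).
`valuenorm` provides a complete, tested pipeline for asking whether firing
rates recorded — or simulated — in a risky/safe cued-lottery task are better
described by this computation than by a field of alternatives: a simple
fractional form, a value-difference (gain) model, range normalization, linear
value codes, a choice code, a null model, a block-wise linear model, and
state-augmented normalization variants. Because the original recordings are
not publicly deposited, the package is organized around a synthetic-data
generator that reproduces the task's statistical structure, so every analysis
stage can be exercised and validated end to end.

## The task

A session consists of the four payoff blocks in random order, 86 trials each:
36 forced-choice trials (6 repeats of 6 instruction conditions — each of the
five risky-instructed pairs plus one safe-instructed condition — shuffled)
followed by 50 free-choice trials (10 repeats of 5 lottery pairs, shuffled).
Safe options pay 60/120/180/240 µl with certainty in blocks 1–4; each block
pairs its safe option with five risky options (p = 0.5) on a 60 µl grid
centered on twice the safe magnitude, so the middle pair (LP3) always has
exactly equal expected values and the block value ranges are 240/360/480/600
µl. Two details the task description leaves open were fixed once:

* The risky magnitude grid is $2\times\text{safe} + \{-120,-60,0,60,120\}$ µl,
  the only 60 µl grid consistent with the printed block maxima, the equal-EV
  middle pair, and cues ranging from empty to full. The 0 µl entry of block 1
  is the blank pie chart, which pays 5 µl; its expected value is 2.5 µl, but
  the block's value *range* still starts at 0 because the risky option can pay
  nothing.
* Safe-instructed forced trials still display a lottery pair; the pair index
  is drawn uniformly per repeat.

The risky target's side is drawn once per block and fixed; block order is a
uniform random permutation. Aborts are modeled as a per-trial flag (aborted
forced trials register a saccade to the non-matched target); aborted trials
are excluded from every analysis rather than re-queued, since re-presentation
affects only trial bookkeeping, not any fitted quantity.

## The synthetic-data generator

The generator defines the study conditions and is not an analysis dial.

* **Choice behavior.** Free-trial choices follow a softmax on the
  expected-value difference, $P(\text{risky}) =
  \text{logistic}(\tau\,(\mathrm{EV}_r + b_{\text{risk}} - \mathrm{EV}_s))$,
  with inverse temperature $\tau = 0.05$ /µl (giving ~95% risky choice at the
  widest pair of block 1 and indifference at LP3) and a risky bonus
  $b_{\text{risk}}$ (µl, default 0) encoding risk attitude additively rather
  than through utility curvature — one parameter suffices to shift LP3
  behavior, which is all the risk-attitude analysis needs. Reaction times are
  log-normal (median 200 ms, log-sd 0.2); aborts are Bernoulli (default 2%).
* **Spiking.** Per trial, the generating model's predicted rate (floored at
  0.01 spikes/s) is the mean of an independent Poisson count in each 1.0-s
  epoch (cue, saccade, feedback) — the simplest spike-count model consistent
  with non-negative rates; the feedback-epoch mean can add a configurable
  reward term. The pre-cue baseline is a Poisson draw over 0.6 s around the
  model's zero-value output. Epochs are conditionally independent because all
  analyses treat them separately.
* **Forced-trial attenuation.** A ground-truth factor ≥ 1 multiplies $\beta$
  and $\sigma$ on forced trials in the fractional models, weakening value
  modulation; for gain-style truths the gain is divided by the same factor so
  that "attenuation" generalizes across model families.

What the generator does not emulate: trial-history/adaptation dynamics,
sub-epoch spike timing, correlated noise across epochs or neurons, and
utility curvature in behavior. Passing recovery tests therefore show that the
analysis machinery is correct and unbiased under these idealized conditions —
not that real cortical data satisfy them.

## Screening for relative-value coding

Each neuron-epoch activity (non-aborted free trials) is screened by
exhaustive variable selection: ordinary least squares is fitted for *every*
subset of {b0, EVr, EVs} (plus Fb in the feedback epoch; plus Cho in the
choice screen), including the empty and intercept-only subsets, and the
subset with minimal AIC wins. The AIC of a least-squares fit uses the
Gaussian convention $n\ln(\mathrm{SSE}/n) + 2k$ with $k$ counting model
coefficients and additive constants dropped; because every comparison is
between fits of the same activity, the dropped constants cancel and the
convention cannot affect any selection. Ties are broken toward the smaller
subset, then lexicographically in the fixed candidate order — determinism
over elegance. An activity is labeled `EVr+EVs-` when the selected subset
contains both values with a positive risky and negative safe coefficient,
`EVr-EVs+` for the mirror image, `choice_only` when only the spatial choice
indicator survives, and `other` otherwise.

## Fitting the model zoo

All thirteen models sit behind one prediction interface keyed by model id.
EV1/EV2 assignment follows the coding type: option 1 is the option the
neuron's firing increases with. Two forced-trial value assumptions are
supported: assumption 1 encodes both cued values exactly as on free trials;
assumption 2 zeroes the non-selectable option.

Numerical choices, applied identically everywhere:

* Models nonlinear in their parameters (M1 and the M11–M13 variants) are
  minimized by Levenberg–Marquardt from 100 random restarts by default
  ($R_{\max}$ uniform on 0.5–2× the observed maximum rate; $\beta,\sigma$
  uniform on 1–600 µl, spanning the plausible estimate range), keeping the
  lowest-SSE converged solution; tolerance 1e-8 on the relative SSE change,
  at most 500 iterations per restart; one master seed expands into
  per-restart seeds so the best SSE is non-increasing in the number of
  restarts. Parameters are unbounded — negative fitted $\beta$ and $\sigma$
  are legitimate outcomes.
* Models linear in their parameters (M2–M10; M2 and M4 become linear after a
  fixed covariate transform) are solved exactly by OLS, which *is* the global
  least-squares minimum, so restarts would be redundant.
* The fractional form has an unbounded ridge — $R_{\max},\sigma \to \infty$
  at fixed ratio, where it degenerates into a line in EV1 — on which the SSE
  infimum is never attained. A restart stopping there — whether by the
  tolerance test at absurd magnitudes or by the iteration cap while still
  climbing — reports parameters that reflect only the stopping rule.
  Solutions with any |parameter| beyond 1e6 (orders of magnitude outside any
  reachable rate or value scale), or terminated by the iteration cap, are
  therefore classed as *diverged*; the best interior solution is preferred,
  and only when every restart diverged is the ridge solution returned,
  flagged `diverged`, with a warning. This arises for weakly modulated
  neurons (small dynamic range relative to Poisson noise), where the
  likelihood genuinely prefers the linear limit. Parameter-*distribution*
  analyses and recovery correlations exclude flagged fits (with a message),
  since their magnitudes are not estimates.
* The block-wise model M10 is read as $a_i\,\mathrm{EVr} + b_i$ applying in
  payoff block $i$ — the only reading under which its eight parameters are
  identifiable.
* The reaction-time covariate of M13 is z-scored per session for numerical
  conditioning; this affine change leaves AIC comparisons untouched. The
  percent-correct covariate of M12 is the non-aborted percentage per lottery
  pair over the session.

Model performance is summarized as percent variance explained on single
trials or on the 20 condition means, and by stratified two-fold
cross-validation: each pair's trials are split in half at random (larger half
to training), the model is refitted on the training fold, and mean-basis VE
is reported for both folds under the training parameters.

## Population inference

Population model selection compares per-activity AIC differences against zero
with two-tailed one-sample t-tests; a reference model is "best" only when
every mean difference is negative and significant. Epoch proportions use a
2×3 chi-squared homogeneity test (Fisher's exact test replaces it when an
expected cell is zero, flagged). Free-vs-forced attenuation compares
|coefficients| of the full value regression with paired t-tests; time courses
use 12-trial bins pooled across blocks by within-block index (3 forced bins,
4 free bins, the last 2 free trials dropped), a one-way ANOVA across bins
within context, and a paired t-test at the forced/free boundary. Parameter
dispersion across phases (forced, first and second halves of the free trials,
split at within-block trial 61) uses the Brown–Forsythe test; epoch-wise
parameter location uses Kruskal–Wallis. Parameter sanity correlates fitted
$R_{\max}$ with the observed maximum rate and $R_{\max}\beta/\sigma$ with the
observed baseline, excluding negative $\beta/\sigma$ rows from the latter.
All tests are two-tailed.

The risk-attitude analysis needs a deviation score at the equal-EV pair. The
construction here — declared as this package's operationalization — fits a
straight line through each block's five condition-mean rates against
$\mathrm{EV}_r-\mathrm{EV}_s$, takes the observed LP3 mean minus the line's
value at zero difference, and averages over blocks; the correlation with the
session's risky-choice percentage is computed separately per coding type.
Note the reference line includes LP3 itself, so a pure LP3 bump is partially
absorbed (the tests account for this exactly).

## Study wrappers and problem sizes

Three wrappers freeze the package's population experiments at sizes chosen to
mirror the study's scale while remaining desk-computable; the same code path
serves the test suite and the acceptance script.

* `recovery_study()`: 50 neurons, truths drawn with $R_{\max}\sim U(10,60)$,
  $\beta\sim U(10,100)$, $\sigma\sim U(20,200)$, 200 free trials each, 40
  restarts per fit; reports Pearson correlations between true and fitted
  parameters. Correlation is outlier-sensitive, so these values wobble a few
  hundredths across seeds.
* `model_selection_study()`: 30 cue-epoch activities generated from M1
  ($R_{\max}=40,\beta=20,\sigma=60$) or from M3 ($G=0.08$, $b=15$ — matched
  dynamic range), fitted with M1–M4; checks that the generating model is
  selected, i.e. the pipeline is not biased toward the normalization form.
* `attenuation_study()`: 27 neurons × 3 epochs = 81 activities (the analysis
  unit is the neuron-epoch), base truths $R_{\max}\sim U(20,50)$,
  $\beta\sim U(10,40)$, $\sigma\sim U(40,120)$, forced-phase inflation ×5.
  Runs the paired coefficient comparison, the three-phase Brown–Forsythe
  dispersion (243 fits), and forced-trial model selection. The $\sigma$
  dispersion test is the least powerful of the three findings at this scale:
  its P value is usually but not always below 0.05 across seeds, an honest
  property of a spread statistic computed on heavy-tailed nonlinear estimates.

## Known limitations

* Poisson spiking and independent epochs understate the trial-to-trial
  correlation structure of real recordings; trial-based VE values here are
  optimistic relative to cortical data.
* Near-linear operating regimes (large $\sigma$ relative to the value range)
  leave $\sigma$ weakly identified; fitted values are then heavy-tailed even
  with the divergence guard, and correlations involving $\sigma$ are the
  noisiest quantities the package reports.
* The risk-attitude deviation metric and the blank-chart convention are
  declared design choices; alternative constructions would change numerical
  values, though not the machinery.
* Trial-history adaptation and subjective-value (utility curvature) models
  are out of scope by design.
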