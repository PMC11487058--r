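---
title: "Measuring crossover interference with the interference length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crossover interference with the interference length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xolint)
```

## The problem

Meiotic crossovers (COs) rarely form close together on the same
chromosome: interference spreads them out.  Data come in two flavours —
cytological foci positioned in µm along the synaptonemal complex (SC),
and genetic CO calls positioned in Mb along the chromosome — and the two
differ systematically: a designated CO is inherited by only half the
gametes, so genetic data are a randomly sub-sampled version of the
cytological picture.  A useful interference statistic therefore has to
use chromosomes with zero or one CO, survive random CO loss, and avoid
binning choices.  The interference length `L_int` fitted by
`interference_length()` is built for exactly that.

## The model

The unit of analysis is a `chromosome_dataset`: all samples (cells,
bivalents, or gamete chromatids) for one chromosome, with its length `L`
and a coordinate-space tag.  The estimator compares the observed
distances between all same-sample CO pairs to a null in which COs are
placed independently:

* the null CO count is Poisson with the observed mean `<N>`, so the
  expected number of pairs per sample is `<N>^2 / 2`;
* null positions are drawn from the *pooled* observed positions, so any
  non-uniform CO landscape (telomeric bias, centromeric suppression) is
  part of the null and does not masquerade as interference.  Concretely,
  `d_noInt` is the exact mean distance over all `choose(M, 2)` pairs of
  distinct pooled CO instances (same-sample pairs included; drawing
  without replacement differs from with-replacement only at `O(1/M)`).

Interference manifests twice: observed pairs are further apart than
pooled pairs (`d_obs > d_noInt`), and pairs are *missing* — the observed
count distribution is narrower than Poisson, so
`mean(N(N-1)/2) < <N>^2/2`.  Missing pairs are assigned the largest
distance that could ever be observed, `d_mis = L`.  Writing
`phi = 2 mean(N(N-1)/2) / <N>^2` for the fraction of expected pairs that
are actually observed,

```
L_int = phi * (d_obs - d_noInt) + (1 - phi) * (L - d_noInt).
```

Both deficits push `L_int` up; without interference `phi = 1`,
`d_obs = d_noInt`, and `L_int = 0`.  Useful landmarks, all reproduced by
the test suite on simulations: one uniformly placed obligate CO per
sample gives `2/3 L` (also when a fraction of samples has no CO); every
sample carrying one CO at the identical position gives exactly `L`
(`phi = 0`, `d_noInt = 0`); `N` COs at regular spacing `L/N` with a
uniform phase give `L [1/N - 1/(3 N^2)]`.  The normalized variant
`L_int^norm = L_int <N> / L` removes the `L/<N>` scaling that dominates
comparisons across chromosomes and species and measures placement
regularity.

### Parameters that matter

* `L` (`length_L`, Mb or µm) — a genuine parameter, not a plug-in: it is
  the weight of missing pairs.  It comes from a `length_table`, never
  from the maximum observed position, which would bias `L_int` downward.
* `bivalent_correction` (default `FALSE`) — genetic (gamete) counts are
  about half the bivalent counts; the flag doubles `<N>` inside
  `L_int^norm` only.  `L_int` itself is invariant to random sub-sampling
  (thinning scales `mean(N(N-1))` and `<N>^2` by the same `p^2`, leaving
  `phi`, `d_obs` and `d_noInt` unchanged in expectation), so no
  correction is applied to it.  The package cannot know the detection
  modality, so the caller sets the flag.
* `bin_count` for `coc_curve()` (default 15) — the CoC curve is the one
  measure here that needs binning; 15 equal-width bins is a workable
  default for a few thousand samples, documented rather than privileged.

## Companion measures

`coc_curve()` uses presence/absence per bin and aggregates bin pairs at
equal centre separation by a ratio of sums, which stays stable when
individual expected frequencies are tiny.  `interference_distance()`
finds the first upward 0.5-crossing by linear interpolation; a curve that
starts at or above 0.5 yields 0 by convention, one that never reaches 0.5
yields `NA` with a warning.  `gamma_shape()` fits a two-parameter gamma
to the pooled adjacent CO distances by exact maximum likelihood: the
shape solves `log(a) - digamma(a) = log(mean(x)) - mean(log(x))` (a
single monotone root), the scale is `mean(x)/shape`.  Exact zeros
(coincident foci) are replaced by `L * 1e-9` to keep the likelihood
finite.  Distances are *not* corrected for censoring at chromosome ends;
the resulting bias scales with (typical gap)/L, which is why the
shape-recovery checks in the tests simulate several COs per chromosome.

## Inference

The exchangeable unit is the sample, so all resampling moves whole
samples.  `bootstrap_sem()` is a nonparametric bootstrap over samples;
degenerate replicates (no CO pairs for the gamma fit, a CoC curve that
never crosses 0.5) are redrawn within a 10-fold budget.
`test_two_sample()` is a permutation test on the absolute difference of
estimates; `test_vs_null()` draws parametric-bootstrap replicates from
the fitted Poisson null (the same null `L_int` is defined against) and is
one-sided, since interference pushes the estimators up.  Both use add-one
p-values `(k+1)/(B+1)`.  No multiple-testing correction is applied;
callers comparing many chromosomes should correct downstream.  The test
suite calibrates both tests (type-I error at the nominal 5% over 400 null
replications) and checks the `1/sqrt(n)` scaling of the bootstrap SEM.

At CO densities typical of real chromosomes (`<N>` around 2–3) the
bootstrap SEM of `L_int` is clearly smaller than that of `d_CoC` or of
the gamma-shape-derived length scale — the statistical-power advantage
that motivates the statistic.  This is a sparse-CO-regime statement: in
dense simulations (`<N> = 5` and above) `d_CoC` is well resolved and its
SEM can edge below `L_int`'s.  The package tests the directional claim at
`<N> = 2`.

## Simulators

`simulate_crossovers()` generates the canonical scenarios (Poisson null
with uniform, bimodal, or user-supplied position densities; obligate CO;
regular placement; fixed position) plus a stationary gamma renewal
process whose shape tunes interference continuously.  Stationarity uses
the equilibrium first-arrival construction — a uniform fraction of a
length-biased inter-arrival, `U * Gamma(shape + 1, rate)` — so shape 1
reproduces the Poisson process exactly and the expected CO count equals
`mean_count` on any window.  The renewal model is a statistical test rig,
not a mechanistic model of interference.  `subsample_crossovers()`
implements binomial thinning.

What the simulations do *not* emulate: per-cell SC-length variation,
non-uniform DNA-to-SC compaction, CO-calling errors, and mechanistic
interference dynamics (HEI10 coarsening, beam-film).  Passing tests
therefore show that the estimators are correct and calibrated under the
stated placement models, not that any biological mechanism holds.

## Numerical choices

Mean pairwise distances use the sorted prefix-sum identity
`sum_{i<j}(x_j - x_i) = sum_k (2k - 1 - M) x_k`, `O(M log M)`, verified
against the brute-force double loop to `1e-12` relative tolerance.
Values are shifted by the per-group minimum before accumulation — the
weights sum to zero, so this is exact, keeps the degenerate
identical-positions case at exactly 0, and conditions the sum well.
Pooled pair counts are computed in double precision (integer products
overflow past ~46k positions).  Positions serialize with `%.17g`, so
file round trips are bit-exact.  Zero-CO samples must appear as manifest
rows (empty position field) in the interchange TSV: a pure call table
cannot represent them, and dropping them silently would bias `<N>`
upward.  Duplicate positions within a sample are legal (distance-0
pairs).  When a dataset shows *more* pairs than the Poisson null
(`phi > 1`, clustering), the formula is evaluated as written, may return
a negative `L_int`, and warns — clamping would hide real signal.

Problem sizes in the test suite were chosen to keep Monte-Carlo error
well below the asserted tolerances: 2e5 samples for the 0.01-tolerance
limit checks, 5e4 per regular-placement count, 400 outer replications for
test calibration, 100–200 bootstrap replicates elsewhere.

## Known limitations

* For the configuration "exactly two COs, one at each chromosome end",
  direct evaluation of the formula gives `L/2` (`phi = 1/2`, `d_obs = L`,
  `d_noInt = L/2`), although this scenario is sometimes quoted alongside
  the `2/3 L` complete-interference value.  The package reports what the
  formula yields and does not special-case the configuration.
* The maximal-interference reference curve `4/3 L / N` (capped at `L`) is
  exposed by `theoretical_lint()` for annotation only; no generator for
  the configurations achieving it at `N >= 2` is provided.
* No correction of `L_int` for an unobserved class II CO fraction is
  implemented; the mixed-class estimator
  (`mixed_interference_length()`) quantifies cross-class interference
  when both classes are labelled, with `phi_mix = <N_a N_b> /
  (<N_a><N_b>)` and cross-class distance pools — a design-decided
  definition.  COs labelled `unknown` take part in the single-class
  estimator but are excluded from mixed-class estimation.
* Space conversion assumes uniform compaction (a single length ratio per
  chromosome) and uses average SC lengths, ignoring per-cell variation.
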