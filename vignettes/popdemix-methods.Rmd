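---
title: "Demixing population activity under factorial task designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixing population activity under factorial task designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdemix)
```

## The data model

The package analyses trial-binned firing rates of a neuron population
recorded under a factorial task design: a task parameter with $S$ levels
(reach targets, wrist orientations, grip types), a visual condition with
$V = 2$ levels (light, dark), and time in 40 ms bins over a fixed window
around movement onset (by default $-4500$ to $+2500$ ms, i.e. $T = 175$
bins). Neurons are typically recorded in separate sessions, so the
population is a *pseudo-population*: trials are aligned only through their
condition labels. Each neuron contributes 7–15 trials per condition cell.

Averaging trials within each condition and centering each neuron at its
grand mean (with equal condition weighting, so unbalanced trial counts do
not bias the mean) yields the PSTH tensor $X \in \mathbb{R}^{N \times S
\times V \times T}$, the substrate of everything downstream. Time bins are
half-open, $[t_0 + t\,\Delta,\ t_0 + (t+1)\Delta)$, 0-based internally and
labelled by their start time in ms in outputs. Grip-type sessions use two
alignment events (object illumination, movement onset); the two epochs are
binned against their own event and concatenated along time, with the
boundary bin stored in the design so that no reported interval ever spans
the concatenation point.

## Marginalization

The centered tensor decomposes additively into four parts, one per
task-variable combination (an ANOVA-style decomposition over the condition
factors):

$$
X = X_{\mathrm{ci}} + X_{\mathrm{par}} + X_{\mathrm{vis}} + X_{\mathrm{int}},
$$

where the condition-independent part is the mean over $(s, v)$, the
parameter part is the mean over $v$ minus the condition-independent part
(zero mean over $s$), the visual part symmetrically (zero mean over $v$),
and the interaction part is the remainder (zero mean over both factors at
every $(n, t)$). The reconstruction is exact to machine precision and each
part is itself a fixed linear projection of $X$ — `marginalize()` is
idempotent. Inputs whose per-neuron means exceed $10^{-6}$ are rejected
rather than silently re-centered, since a non-centered tensor usually
signals an upstream bookkeeping error.

## Demixed PCA

With $X$ also denoting its $N \times SVT$ unfolding, ordinary PCA minimizes
$\|X - FDX\|^2$ over rank-$q$ encoder/decoder pairs with $D = F^\top$.
Demixed PCA instead minimizes one reduced-rank regression loss per
marginalization,

$$
L_\phi = \|X_\phi - F_\phi D_\phi X\|^2 + \lambda \|F_\phi D_\phi\|^2 ,
$$

whose full-rank ridge solution is $A_\phi = X_\phi X^\top (X X^\top +
\lambda I)^{-1}$. Rank reduction truncates the SVD of $A_\phi X$: the
encoder $F_\phi$ is the leading left-singular block (unit-norm columns) and
the decoder is $D_\phi = F_\phi^\top A_\phi$. Decoding axes are *not*
constrained to be mutually orthogonal — that freedom is what lets each
component carry a single marginalization. The printed two-term
stimulus/time form of this loss is the didactic special case; the solver
uses one term per marginalization because the analysis itself reports four
parts.

Numerical and reporting choices:

* **Ridge strength.** $\lambda$ defaults to $10^{-6}\,\|X\|^2 /
  (N\,SVT)$ — a pure numerical stabilizer that also handles the common
  rank-deficient case $N > \mathrm{rank}(X)$. $\lambda = 0$ is allowed when
  $X X^\top$ is invertible and then reproduces the unregularized solution;
  a singular system with $\lambda = 0$ raises an error instructing the user
  to set $\lambda > 0$. A cross-validated $\lambda$ search is deliberately
  not run by default.
* **Components kept.** `q = 10` per marginalization (40 total), of which
  reports typically use the leading one or two per marginalization.
* **Ordering and signs.** Components are ordered globally by explained
  variance $\|D_i X\|^2$. Signs of an SVD are arbitrary, so each component
  is flipped to make the time-averaged projection of the first condition
  non-negative; this makes fits reproducible across platforms.
* **Cumulative variance.** Reported as $1 - \|X - \sum_{i \le q} F_i D_i
  X\|^2 / \|X\|^2$. Because the partial reconstruction has rank at most
  $q$, this can never exceed the PCA curve — the comparison between the two
  curves is therefore a guaranteed bound, not an empirical accident.
* **Single-marginalization limit.** When the data contain only one
  marginalization and $\lambda = 0$, $A_\phi = I$ and the fit reduces
  exactly to PCA; this limit is the main solver correctness oracle in the
  test suite.

## The signal-variance split

The fraction of signal variance per marginalization is
$\|X_\phi\|^2 / \sum_\psi \|X_\psi\|^2$. Computed on a trial-averaged
tensor this raw ratio is biased: with $K$ trials the condition means retain
sampling noise of variance $\sigma^2/K$ per entry, and that noise
distributes over the marginalizations in proportion to their degrees of
freedom ($T-1$, $(S-1)T$, $(V-1)T$, $(S-1)(V-1)T$ out of $SVT$). At
cortical firing rates, 40 ms bins and 7–15 trials, the bias is large —
tens of percentage points away from the noiseless shares, mostly inflating
the interaction term. `explained_variance_split()` therefore estimates the
per-entry noise variance from within-condition trial scatter, allocates it
across marginalizations by degrees of freedom, and subtracts it (clipping
at zero) whenever trial-resolved data are available; `noise = "none"`
gives the raw ratio. The correction assumes approximately homoscedastic
noise within a neuron; heteroscedasticity across conditions makes it
approximate but, in the regimes the generator covers, the residual error is
well under one percentage point.

## The synthetic generator

Because the original recordings are not publicly deposited, the package
ships a generator whose ground truth is analytic. Each neuron's noiseless
rate is

$$
r_n(s, v, t) = b + \sum_\phi \sum_k w_{n\phi k}\, g_{\phi k}(s, v, t),
$$

where each latent profile $g$ satisfies its marginalization's zero-mean
constraints *exactly* (condition-independent profiles are centered in time;
parameter/visual contrasts are centered over levels; interaction contrasts
are outer products of centered contrasts). Loadings are i.i.d. standard
normal and each marginalization's summed part is then rescaled so the
population signal-variance split equals the requested fractions exactly in
the noiseless limit — `planted_fractions()` is therefore an exact oracle,
and the variance bookkeeping uses the same population quantity
$\sum_\phi \|X_\phi\|^2$ that the split estimator reports.

Defaults, chosen once as plausible for parietal cortex and then left alone:
baseline 10 spikes/s; signal RMS 3 spikes/s per tensor entry; Poisson
spike counts per 40 ms bin (so trial rate variance is $\approx$ rate/0.04
on flat neurons); 7–15 trials per condition; two latents per
marginalization with smooth random Gaussian-bump temporal profiles.
Poisson rates are clipped at zero; because the loading-times-profile
product is heavier-tailed than a Gaussian, the default settings clip a few
tenths of a percent of entries, and the generator warns whenever clipping
touches more than 0.1% — exactness tests therefore use high baselines or
noiseless Gaussian mode, where recovery is exact to $10^{-6}$. An optional
mode plants a two-cluster structure over five grip levels (three levels
sharing one profile, two another), off by default.

What the generator does **not** emulate: biophysical spiking dynamics,
spike-history effects, inter-neuron noise correlations (neurons are
conditionally independent, as in any pseudo-population), eye-movement
confounds, and non-stationarities across sessions. Passing recovery tests
on this generator validates the estimators' algebra and calibration, not
the neural interpretation of any particular dataset.

## Decoding

`decode_timecourse()` decodes the task parameter (or the visual condition)
with stratified Monte-Carlo leave-group-out cross-validation: each of 100
iterations holds out one random trial per neuron per condition, assembles
them into per-condition test pseudo-trials, averages the remaining trials
into a training set, refits the target marginalization's decoding axis on
the training set, and classifies each test pseudo-trial at each bin by the
nearest class mean of the training projections. The classifier uses the
leading decoding axis by default (`q_axes` raises the dimension); nearest
class centroid on a demixed axis is the natural reading of "decoding axes
as a linear classifier", and one pseudo-trial per condition cell per
iteration is the natural reading of the stratified hold-out.

Significance uses a shuffle null: condition labels are permuted across
trials within each neuron (preserving trial counts), the full
cross-validated decoder is rerun, and a bin counts as significant when the
observed accuracy exceeds the 95th order statistic of 100 shuffles.
Reported intervals are maximal runs of at least 10 consecutive significant
bins — isolated false-positive bins, expected at rate $\alpha$, never
survive the run rule. `min_population_analysis()` repeats all of this on
random neuron subsets (100 and an intermediate size per task in the
original design; the full population is always included).

## Discrimination distance curves

For the symmetric 2 × 2 comparison, the projections of the leading
parameter component are averaged over the visual levels within each
parameter level, and the per-bin euclidean distance between the two
level-averaged curves measures how well the population separates the
parameter over the trial; the same construction on the leading visual
component gives the visual curve. With $k$ components the distance is the
$k$-dimensional norm per bin ($k = 1$ by default, matching single-curve
reports).

Confidence bands resample *neurons* with replacement, refitting the
entire dPCA on every resample — the axes are estimates too, and
reprojecting fixed axes would understate the uncertainty. Neuron-level
resampling was a genuine open choice (value-level or trial-level resampling
are defensible readings); neurons are the exchangeable sampling unit of a
pseudo-population, so they are the default. Bands are percentile 2.5/97.5
over 100 resamples; bins where the two curves' bands do not overlap, in
runs of ≥ 10 bins, are separation intervals, and the decision is symmetric
in the two curves. A complementary randomization test permutes condition
labels within neurons, recomputes the difference of the two curves, and
reports per-bin p-values as $(\mathrm{count}+1)/(n_{\mathrm{iter}}+1)$, so
the attainable resolution at 100 iterations is about 0.01.

## Chi-squared comparisons of variance percentages

Variance percentages across and within tasks are compared with a Pearson
chi-squared test (no continuity correction by default; a Yates flag is
provided) on a groups × 2 table that treats each percentage as a count of
"percentage points captured" out of a base of 100 per group. The sampling
model behind a chi-squared on variance percentages is an interpretive
assumption, not a derived property — the base-100 convention is stated
prominently because halving or doubling the base changes every p-value.
Under this convention the comparisons (24, 11), (24, 24), (11, 24),
(11, 15, 19), (15, 11) and (19, 24) reproduce the expected
significant/non-significant pattern, with e.g.
$\chi^2(1) = 5.85,\ p = 0.016$ for 24% vs 11%.

## Problem sizes in the shipped tests

Unit tests run on reduced instances (tens of neurons, 20–40 bins, a few CV
iterations) chosen so the full suite completes in well under a minute while
still exercising every code path; the acceptance-style checks use
study-scale populations — 150 neurons × 175 bins for variance recovery,
100 neurons for decoding with 25 CV iterations × 25 shuffles, 80 neurons
with 50 bootstrap resamples and 100 randomization iterations for the
distance analysis. These sizes are the package's own trade-off between
statistical resolution and runtime; recovery tolerances (±3 percentage
points on planted shares, ±3 bins on planted windows) are set by the
resampling noise observed at exactly these sizes, not tuned per seed.

## Known limitations

* The noise-subtraction in the variance split assumes within-neuron
  homoscedasticity; strongly rate-dependent noise (e.g. very low baselines
  with strong modulation) leaves a residual bias.
* The decoder is intentionally minimal (nearest centroid on one axis);
  it measures the linear information carried by the demixed axis, not the
  total decodable information.
* Distance curves compare read-outs in projection units; they are
  meaningful within a fitted population but not across populations with
  different scales.
* The chi-squared base-100 convention is an assumption; treat across-task
  significance calls as descriptive.
* HDF5 containers are not read or written; the canonical interchange
  formats are the long CSV and JSON design files.
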