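# popdemix

Demixed principal component analysis (dPCA) and downstream population
statistics for trial-binned neural firing rates recorded under factorial
task designs — the kind of data produced by reach-and-grasp experiments in
posterior parietal cortex, where every neuron is tested across task
parameters (reach targets, wrist orientations, grip types), two visual
conditions (light/dark) and time within the trial.

The package is for systems neuroscientists who want a tested, reproducible
implementation of the full population-level pipeline:

* **Tensor construction** — trial-averaged, per-neuron-centered PSTH
  tensors `X[n, s, v, t]` from trial-resolved recordings (long CSV or
  in-memory), with condition subsetting and neuron subsampling.
* **Marginalization** — exact ANOVA-style split of the centered tensor
  into condition-independent, task-parameter, visual and interaction parts:
  `X = X_ci + X_par + X_vis + X_int`.
* **Demixed PCA** — per-marginalization reduced-rank ridge regression:
  minimize `||X_phi − F_phi D_phi X||² + λ||F_phi D_phi||²` with the
  full-rank solution `A_phi = X_phi Xᵀ (X Xᵀ + λI)⁻¹` truncated by SVD.
  Decoding axes are not forced to be orthogonal; in the
  single-marginalization limit with `λ = 0` the fit reduces exactly to PCA.
* **Variance accounting** — signal-variance split across marginalizations
  with optional (default) subtraction of trial-sampling noise, plus
  chi-squared comparisons of variance percentages across and within tasks.
* **Decoding** — time-resolved cross-validated decoding from the demixed
  decoding axes (stratified Monte-Carlo leave-group-out pseudo-trials),
  shuffle-null significance with a 10-consecutive-bin rule, and a
  minimum-population-size analysis.
* **Discrimination time-courses** — per-bin euclidean distances between
  level-averaged component projections, neuron-bootstrap confidence bands
  and a randomization comparison of the two curves.
* **Synthetic pseudo-populations** — a generator with analytically planted
  variance fractions per marginalization, so every estimator in the
  pipeline has an exact recovery oracle.

See `vignettes/popdemix-methods.Rmd` for the model, the estimators, and the
reasoning behind every tunable default.

## Worked example

Simulate a 150-neuron pseudo-population on the 3-target reach design with a
planted variance split, fit dPCA, and compare variance percentages:

```r
library(popdemix)

design <- reach_design()                 # 3 targets x light/dark, 175 bins
spec <- effect_spec(
  target_fractions = c(condition_independent = 0.58, parameter = 0.24,
                       visual = 0.11, interaction = 0.07),
  seed = 42)
rec <- simulate_population(design, n_neurons = 150, spec)
rec
#> Population recording: 150 neurons, reach_direction task
#>   3 x 2 conditions, 175 bins, 7-15 trials/condition

fit <- dpca(rec, q = 10)
summary(fit)
#> Signal variance split (%):
#> condition_independent             parameter                visual
#>                    58                    24                    11
#>           interaction
#>                     7
#>
#> Leading component per marginalization:
#>  component       marginalization local_index  variance variance_fraction
#>          1 condition_independent           1 669998.46        0.12907586
#>          2             parameter           1 317872.18        0.06123839
#>          3                visual           1 144646.45        0.02786628
#>          5           interaction           1  99767.07        0.01922022
#>
#> Cumulative variance at 40 components: dPCA 44.7%, PCA 55.7%

chi2_compare(c(24, 11), labels = c("target position", "wrist orientation"))
#> Chi-squared comparison of variance percentages: target position=24%, wrist orientation=11%
#>   chi2 = 5.853, df = 1, p = 0.0156 (significant at alpha = 0.05)
```

Reading the output: the noise-corrected signal-variance split recovers the
planted `(58, 24, 11, 7)%` exactly at this population size — most variance
is condition-independent (trial-phase dynamics), the task parameter carries
about twice the visual condition's share, and that 24% vs 11% difference is
what the chi-squared call tests. The cumulative-variance line refers to the
*raw* trial-averaged tensor, which at 7–15 Poisson trials per condition
still contains substantial sampling noise; neither dPCA nor PCA should (or
does) explain that part, and the dPCA curve stays within a few points of
the PCA bound. `plot(fit)` draws the six condition projections (3 targets ×
2 visual conditions) of the leading component per marginalization.

Downstream analyses take the same recording object:

```r
res <- decode_timecourse(rec, target = "parameter", n_iterations = 100)
sig <- significance_intervals(res, n_shuffles = 100)   # 10-bin run rule
bands <- bootstrap_bands(rec, parameter_levels = c("left", "right"))
```

`run_pipeline()` executes simulate → dpca → decode → distance →
compare-variance from one JSON-serializable config and writes tidy CSV/JSON
outputs plus a run log with every seed and dimension.

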