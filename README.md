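# accumimic

Sequential-sampling models and model-mimicry analyses for deadlined
value-based choice.

## The problem

In speeded two-bundle value choices (two fractals per bundle, each worth
€0.10–€0.80, a 750 ms response deadline), drift diffusion models (DDMs) can
show decision thresholds apparently *decreasing* on difficult trials — a
pattern that has been read as motivated control over the decision process.
`accumimic` provides the machinery to stress-test that inference:

* a **synthetic task generator** for balanced bundle designs, value
  regressors (`signVD`, `absVD`, `maxVD/minVD`, `maxOV/minOV`, `OV`), unequal
  fractal weighting, and subject-level parameter variation;
* a **DDM model zoo** of 14 trial-level regression specifications with static
  or linearly collapsing bounds, simulated by Euler–Maruyama with a
  continuity-corrected absorbing boundary, plus closed-form oracles
  (two-barrier absorption probabilities and first-passage densities) for the
  static case;
* a rectified **leaky competing accumulator** (LCA) with leak, mutual
  inhibition, collapsing bound, and deadline omissions — a control-free model
  in which higher overall value speeds decisions through accumulator dynamics
  alone;
* **inverse binomial sampling** (IBS) likelihood estimation over stratified
  RT-decile categories, with bounded, noise-robust derivative-free fitting;
* **quantile-based BIC** model comparison
  (`BIC = −2 Σ N p_i ln π_i + M ln N`) with bootstrap confidence intervals;
* pipelines for **model recovery**, **parameter recovery**, and the
  **mimicry experiment**: fit DDMs to LCA-generated behaviour and measure the
  artifactual value-dependent "threshold control" they report.

No participant data ship with the package; all analyses run on synthetic
data whose design constants (22 subjects × 160 trials, the euro value grid,
the 750 ms deadline) match the task setting the models address.

## Worked example

```r
library(accumimic)

design <- build_design(n_subjects = 22, n_trials = 160, seed = 7)

# the design orthogonalises value difference and overall value under equal
# weighting, but not under the behavioural 5:1 weighting
design_correlations(design, weighting(1))$r_wabsVD_wOV
#> [1] -0.01889451
design_correlations(design, weighting(5))$r_wabsVD_wOV
#> [1] -0.3219874

# control-free LCA behaviour under the 750 ms deadline
trials <- generate_behavior(design, default_lca_params(), "lca", seed = 11)
rt_quantile_summary(trials)$conditions
#>   difficulty    n  accuracy omission_rate
#> 1       easy 1756 0.9089317    0.02448747
#> 2       hard 1764 0.5213415    0.07029478
```

Easy choices (large equal-weight value difference) are more accurate; both
conditions show omissions, and RTs are right-skewed. Fitting the static
`"Original*"` DDM to such LCA data by IBS (`fit_model`) yields a *positive*
threshold slope on `absVD` — lower thresholds for harder choices — and
fitting the collapsing `"VDOV both"` DDM yields *negative* overall-value
threshold slopes, although neither mechanism exists in the generator:

```r
tab <- normalize_rt(trials)
fit <- fit_model(tab, "Original*", config = list(restarts = 1), seed = 99)
round(fit$par_natural$a_absVD, 2)
#> [1] 1.32
```

`run_mimicry()` packages this experiment (replicate simulate-and-fit runs,
bootstrap CIs, sign verdicts, and a constant-drive negative control), and
`run_model_recovery()` / `run_parameter_recovery()` validate the selection
and estimation machinery.

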