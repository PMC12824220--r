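---
title: "Sequential-sampling models, simulation-based likelihoods, and mimicry in deadlined value-based choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential-sampling models, simulation-based likelihoods, and mimicry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In deadlined value-based choice tasks, participants pick between two bundles
of learned rewards under severe time pressure (here: two fractals per bundle,
each worth 0.10 to 0.80 euros, a 750 ms response deadline, and forfeiture of
the trial's reward on a miss). A drift diffusion model (DDM) fitted to such
data can show the decision threshold apparently *decreasing* on difficult
trials, which has been interpreted as motivated control: people invigorating
responses when choices are hard. This package implements the modelling
machinery needed to probe that inference: a family of trial-level regression
DDMs with static or collapsing bounds, a control-free rectified leaky
competing accumulator (LCA), simulation-based likelihood estimation, quantile
BIC model comparison, and pipelines for model recovery, parameter recovery,
and model mimicry. The mimicry experiment is the centrepiece: behaviour is
simulated from an LCA with *no* value-dependent threshold mechanism, DDMs are
fitted to it, and the fitted threshold coefficients show artifactual
"control" — threshold effects of difficulty and of overall value that are not
in the generative process.

## The synthetic task generator

No participant dataset ships with the package; `build_design()` constructs
designs with the task's defining properties: each subject receives `n_trials`
bundle pairs (default 160) whose fractal values lie on the 0.10–0.80 euro
grid, with trials stratified approximately uniformly over cells of
(overall-value bin × equal-weight value-difference bin), default 4 × 4, and
left/right assignment randomised. Whether such balancing should be an exact
factorial or approximate is underdetermined by the task description; the
stratified-sampling construction reproduces the balancing property without
asserting any particular trial list. `n_trials` must be divisible by
the number of balance cells, which is why 160 works with the default 16
cells.

The regressors of the model zoo are computed by `compute_regressors()`:
`signVD`/`absVD` are the signed/absolute equal-weight bundle value
differences (left minus right of the fractal-pair means), `maxVD`/`minVD`
compare only the two high-valued or only the two low-valued fractals,
`maxOV`/`minOV` sum them, and `OV` is the total set value. These identities
(`absVD = |signVD|`, `OV = maxOV + minOV`, `signVD = (maxVD + minVD)/2`) are
property-tested on random designs.

A key design confound motivates `design_correlations()`: the balanced design
orthogonalises overall value and value difference *under equal weighting of
the two fractals in a bundle*. Behaviourally, the high-valued fractal carries
about five times the weight of the low-valued one, so the package's default
unequal weighting is `weighting(5)` (w_high = 5/6). Re-weighting the bundle
values with that ratio makes the absolute value difference and overall value
substantially correlated (about −0.3 on the default design, versus ≈ 0 under
equal weights), which is one route by which overall-value effects masquerade
as difficulty effects.

Subject-level parameter variation (`sample_subject_params()`) draws
positivity-constrained parameters on the log scale, unit-interval parameters
(`z`, `p_outlier`, the LCA drive ratio `m`) on the logit scale, and
unconstrained regression coefficients from normals. Group-level spreads are
deliberate choices, not estimates: coefficient scales are set to 30 % of the
coefficient magnitude (plus a small floor), reflecting the several-fold
participant heterogeneity typical of drift/threshold regressions, and were
fixed before the recovery experiments were run.

## The DDM model zoo

`model_registry()` holds 14 model specifications. Each maps regressors to
trial-level parameters by linear formulas: drift `v` on the identity scale
(no intercept; signed value regressors), threshold `a` and collapse rate
`theta` through a softplus link (so regression-driven thresholds stay
positive without hard clipping), and, in the condition-split variant, the
starting point `z` through a logistic link. Static-bound models fix
`theta = 0`; "angle" models collapse the bound linearly,
`B(t) = max(0, a − theta·t)`; "init"-type collapsing models estimate a single
free collapse rate, "rate"-type models regress the collapse rate while
keeping a constant initial threshold. Response coding maps the upper bound to
the *left* response; accuracy coding (used by the condition-split model) maps
it to the objectively better bundle by flipping the signed regressors
trial-wise. Free-parameter counts (`count_free_params()`) include every
regression coefficient and the scalar extras (`z`, `p_outlier`, a constant
collapse rate, drift variability) but exclude non-decision time, the
convention under which the continuous static model has 5 free parameters and
the full collapsing model 14.

`simulate_ddm()` integrates the diffusion with an Euler–Maruyama scheme,
diffusion coefficient fixed at 1 (the conventional identifiability scaling),
start `a(2z − 1)`, symmetric absorbing bounds `±B(t)`. Two numerical choices
matter:

* **Bound-crossing bias correction.** Discrete-time barrier checks miss
  intra-step excursions, biasing absorption probabilities by O(√dt). The
  simulator therefore pulls the effective bound inward by `0.5826·√dt`
  (the Broadie–Glasserman–Kou continuity correction). With it, simulated
  absorption probabilities agree with the classical two-barrier closed form
  to within one binomial standard error at 2 × 10⁵ trials and dt = 0.001;
  without it they deviate by several.
* **Omissions are a category, not censoring.** The walk runs to
  `deadline − t0`; unabsorbed mass is an omission outcome. Lapses
  (probability `p_outlier`) produce a uniform response with RT uniform on
  (0, deadline).

`static_ddm_oracle()` supplies the independent closed-form absorption
probabilities and first-passage densities (large-time sine series, truncated
adaptively at a 10⁻¹⁴ relative term size) used to validate the simulator.

## The rectified LCA

Two accumulators with activations floored at zero race to a shared linearly
collapsing bound. Each step applies input drive `I = b(m·v_max + (1−m)·v_min)`
computed from the option's own fractal pair, leak `k`, inhibition `w`, and
pre-rectification Gaussian noise scaled by `σ√dt`. Three formulation
ambiguities in this model family were resolved as follows, each switchable
or documented:

* A common printed form of the two-unit update applies inhibition to the
  second unit's *own* activation, making `w` redundant with leak; since the
  accumulators compete through *mutual* inhibition, the default is
  cross-inhibition, with the self-inhibition variant available via
  `printed_inhibition = TRUE` for auditability.
* "Boundary collapse rate" is interpreted as a linear collapse of the shared
  bound (not a gain modulation), floored at zero; if the floor is reached
  before any crossing, the accumulator with the larger activation wins at
  that moment, ties broken by a seeded fair coin.
* Values enter in euros; the drive scale `b` absorbs units.

The default generative regime (`default_lca_params()`: t0 = 0.2 s, b = 11,
m = 5/6, k = 6, w = 5, a0 = 1.2, c = 1.0, σ = 0.9) was chosen once so that
simulated behaviour matches the qualitative empirical regime of such tasks —
accuracy ≈ 0.80, right-skewed RTs (skewness ≈ 0.5), ≈ 5 % omissions under
the 750 ms deadline, and overall-value speeding of ≈ 50 ms between high- and
low-value halves — and is the reference generator for the mimicry pipeline.
The drive-ratio default m = 5/6 mirrors the 5:1 behavioural weighting
asymmetry.

## Simulation-based likelihood and fitting

Because collapsing-bound DDMs and LCAs lack tractable likelihoods, fitting
uses inverse binomial sampling (IBS) over stratified RT-decile categories.
`normalize_rt()` first removes between-subject RT variance (subtract each
subject's mean, re-add the grand mean) so that group-level RT quantiles are
not dominated by individual differences; the operation is idempotent and
preserves the grand mean. `build_bins()` then computes empirical RT decile
edges separately for correct and error trials within a median split on
overall value (the fitting stratification; orthogonal to the equal-weight
value-difference hypothesis), with one omission category per split level —
42 categories in all. Edges are right-closed: an RT equal to an edge falls in
the lower bin. Simulated trials are always categorised with the *empirical*
edges.

`ibs_loglik()` simulates each observed trial until the first category match;
a match on draw K contributes `−Σ_{j<K} 1/j`, an unbiased estimate of the
log category probability. Because an uncapped loop need not terminate on
zero-probability categories, draws are capped (default 10⁴ for the generic
estimator; 100 inside `fit_model()`, flooring a trial's contribution at
−H₉₉ ≈ −5.18 and flagging it). The estimator's variance is tracked with the
squared-reciprocal companion sum and falls as 1/repeats.

`fit_model()` maximises the IBS likelihood with bounded multi-start
Nelder–Mead on a logit-transformed parameter box. Two devices make the noisy
objective tractable: common random numbers (each evaluation reuses the same
seed stream, so the objective is a deterministic function of the parameters
given the fit seed), and in-evaluation early abort once the accumulated
negative log-likelihood exceeds the best-so-far by 5 %. Regressors are
z-scored per dataset for optimiser conditioning; the scalings are stored and
fitted coefficients are also reported back on the natural (euro) scale.
This family of analyses is often fitted with Bayesian adaptive direct search
or hierarchical Bayesian DDM machinery; neither is re-implemented here — any
bounded derivative-free method robust to objective noise satisfies the role,
and all model comparison is group-level maximum likelihood with quantile BIC
rather than DIC.

## Quantile BIC and model comparison

`quantile_bic()` scores a simulated dataset against empirical data over the
BIC stratification (correct/error × easy/hard equal-weight value difference,
median split, RT deciles plus omission categories, summed jointly over all
categories): `BIC = −2 Σ N p_i ln π_i + M ln N`. Simulated cell
probabilities are floored at `1/(2·n_simulated)` before the log, since the
criterion is undefined on empty simulated cells; floored cells are counted
and flagged. Free-parameter counts use the registry convention (LCA: 8).
`compare_models()` simulates `n_sim` datasets per fitted model, reports
per-model BIC distributions, pairwise mean differences with percentile
bootstrap confidence intervals, win fractions, the conservative
best-single-simulation difference, and verdicts on the conventional 2/6/10
evidence scale.

## Recovery and mimicry pipelines

`run_model_recovery()` crosses generating and fitting models over the trio
{static continuous, static value-split, collapsing value-split}; each fit is
scored by the mean quantile BIC of datasets re-simulated from it. The
collapsing-bound generator should be recovered on its own data; the
static-bound row is *reported* rather than asserted, because model selection
in this family is known to lean towards collapsing bounds — the pipeline
quantifies that bias instead of hiding it. `run_parameter_recovery()` draws
generating parameter vectors from the group distribution, refits, and
reports per-parameter correlations and bias; comparisons are made on the
fitted (z-scored) parameterisation, where intercepts are identified at the
mean regressor. With ten datasets of ≈ 10⁴ trials (the 22 × 160 design
concatenated three times) the drift coefficient recovers strongly (r ≈ 0.9),
while the threshold intercept recovers only moderately (r ≈ 0.6): at this
trial count the 42-category quantile likelihood carries a genuine
drift–threshold–lapse ridge, and fitted points on the ridge reach
truth-level likelihood, so no optimiser setting recovers the intercept more
precisely. This identifiability limit of the categorical simulation-based
stack is itself informative about what the mimicry fits can and cannot pin
down; the threshold *slopes* tested by the mimicry verdicts are sign-stable
despite it.

`run_mimicry()` is the headline pipeline: simulate behaviour from the
control-free LCA, fit the static continuous DDM and the full collapsing DDM
to it, and inspect the fitted threshold-formula coefficients on the natural
scale across replicate simulate-and-fit runs (percentile bootstrap over
replicates). Two sign verdicts are emitted: the static fit's threshold slope
on absolute value difference is reliably *positive* — since absVD measures
easiness, that is precisely "lower thresholds for harder choices" — and the
collapsing fit's threshold slope on the max-pair overall value is reliably
*negative* ("higher overall value, lower threshold"). The min-pair
overall-value slope is reported but not asserted; at these problem sizes it
hovers near zero. A negative control replaces each option's drive with the
same constant for every trial, removing all value information, and the
artifacts collapse. Two subtleties are worth recording. First, on null data
the threshold slopes are only weakly identified — the fitting strata
condition on overall value and accuracy is flat — so control estimates
wobble around zero rather than sitting exactly there, and because the
softplus positivity link is convex a nonzero slope on a skewed regressor can
very slightly improve fit even on value-free data. The control check is
therefore effect-size collapse (control means several-fold below the
mimicry effects, with no artifact-direction interval for the overall-value
slope), not a point-null on a handful of replicates. Verdict stability is
checked across independent master seeds.

## Problem sizes and budgets

Defaults were chosen so a full test-and-acceptance cycle runs on a single
CPU in tens of minutes: fitting uses dt = 0.005 s and generation dt = 0.001 s
(choice probabilities agree across these steps within Monte-Carlo error);
mimicry replicates use one pass over the 22 × 160 design (3 520 trials),
which is the smallest size at which the artifact coefficients keep a
consistent sign across replicates; parameter recovery uses ten datasets of
three concatenated passes (≈ 10⁴ trials); model recovery uses compact
designs with two datasets per generator and single-start fits. These sizes
are stated in the function defaults and can be scaled up freely.

## What passing tests do and do not show

The synthetic generator emulates the task's design constants, deadline
omissions, balancing, and subject heterogeneity, but not learning of fractal
values during training, motor biases beyond the starting point, or any
sequential (trial-history) structure — all absent from the models too.
Passing recovery and mimicry tests therefore demonstrate properties of the
*modelling pipeline* (identifiability, selection behaviour, artifact
generation) under the stated generative regimes, not claims about any
particular participant dataset. The package deliberately excludes the
hierarchical Bayesian stack (DIC, posterior credible intervals) common in
this literature; bootstrap confidence intervals over replicates stand in
for credible intervals, and all headline comparisons use quantile BIC and
IBS log-likelihoods.
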