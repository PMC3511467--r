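---
title: "Comparing temporal discounting models by likelihood, AIC and Bayesian model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing temporal discounting models by likelihood, AIC and Bayesian model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempodisc)
```

## The modelling problem

In an inter-temporal choice task a participant repeatedly chooses between a
fixed immediate reward (20€ throughout this package) and a larger delayed
reward. The data are binary choices indexed by the delayed amount and the
delay. A discount function maps amount `A` and delay `D` (in days,
fractional values allowed) to a subjective value, and a stochastic choice
rule maps the value difference between the two options to a choice
probability. The scientific questions are (i) which functional form of
discounting describes individuals and populations best once model
complexity is accounted for, and (ii) whether the parameters of the
favored form are separately interpretable.

### The candidate discount functions

`model_catalog()` lists the five candidates:

* **H** — hyperbolic, `A / (1 + kD)`. One parameter; implies "decreasing
  impatience": a week's wait matters more now than a year from now.
* **E** — exponential, `A exp(-kD)`. One parameter; the stationary,
  economically "rational" benchmark, in which a fixed added delay always
  multiplies value by the same factor.
* **GM** — `A / (1 + kD)^s`. Raising the whole denominator to a power is
  algebraically identical to exponential discounting of log-compressed
  (Weber–Fechner) time: `A exp(-s log(1 + kD))`. The package asserts this
  identity to machine precision in its test suite.
* **R** — `A / (1 + k D^s)`. Hyperbolic discounting of power-scaled time.
* **CS** — constant sensitivity, `A exp(-(aD)^b)`. The impatience level is
  carried by `a`, time sensitivity by `b`. `b = 1` recovers E exactly, so
  departures from stationary discounting are read directly off `b`.
  `b << 1` produces a present–future dichotomy (everything non-immediate
  similarly devalued); `b >> 1` an extended present (little discounting up
  to some horizon, steep beyond it).

Exponents below 1 in GM, R and CS admit a psychophysical reading —
compressive non-linear scaling of subjective time — which is why the
package ships a one-sample test of exponents against 1
(`exponent_vs_one()`).

At `D = 0` all five functions return `A` exactly. For CS with `b < 1` the
term `(aD)^b` is defined by its limit 0 at `D = 0`, which R's
exponentiation already yields; the exponent's lower bound (0.01) keeps the
`0^0` singularity out of the search space.

### The choice rule

`choice_probability()` is a logistic in the value difference with a
stochasticity parameter β:

P(choose delayed) = 1 / (1 + exp(−(SV_LL − SV_SS)/β)).

β is a *temperature*: the value difference is divided by it, so larger β
means a shallower sigmoid and noisier choices, and β → ∞ approaches
indifference (p = 0.5) everywhere. The reverse (inverse-temperature)
convention, in which the difference is multiplied by β, is exposed via
`beta_convention = "inverse"` for sensitivity analyses; all defaults,
presets and reported estimates use the temperature form. Because values
are in euros, β is in euros too: it is roughly the value difference at
which choices are ~73% consistent.

## Estimation

`fit_subject()` maximizes the summed log choice probability of each
subject's chosen options. Numerical choices, and why:

* **Optimizer.** Derivative-free Nelder–Mead simplex (`stats::optim`),
  relative tolerance 1e-6, at most 5000 iterations per start. The
  likelihood surface of dual-parameter models has curved ridges; a simplex
  is robust there and needs no gradients of the clamped objective.
* **Reparameterization.** All parameters (k/a, s/b, β) are positive and
  searched on the log scale, which enforces positivity without penalty
  terms. Box bounds (k, a ∈ [1e-8, 10]; s, b ∈ [0.01, 20]; β ∈ [1e-6,
  100]) are applied by clamping inside the objective; they are wide enough
  to contain typical laboratory estimates by an order of magnitude while
  keeping the likelihood finite. Estimates landing on a bound are flagged
  per parameter.
* **Multi-start.** 20 random starts by default, drawn log-uniformly on
  [1e-4, 1] for rates, uniformly on [0.25, 2.5] for exponents, and
  log-uniformly on [0.1, 10] for β. Starts are drawn one full vector at a
  time, so under a fixed seed a larger `n_starts` extends the start set
  rather than reshuffling it — the returned maximum is then monotone in
  `n_starts`, which the tests exploit.
* **Probability floor.** Choice probabilities are clamped to
  [1e-12, 1 − 1e-12] before the log. Near-deterministic subjects otherwise
  produce −∞ log-likelihoods whenever a single choice disagrees with the
  model at small β. Log-probabilities are computed via the stable log-CDF
  form of the logistic, never by `log(p)`.
* **Degenerate subjects.** A subject who always chose the same option
  leaves the likelihood flat once probabilities saturate; the fit then
  returns the canonical boundary representative of that flat region (rate
  at the bound, β minimal), with a warning and boundary flags, rather than
  an arbitrary interior point or an exception.
* **Free-parameter count.** AIC = −2LL + 2n and BIC = −2LL + n log(trials)
  count β as free: n = 2 for H/E and n = 3 for GM/R/CS. Since β is
  estimated per subject and model, the alternative (excluding β) shifts
  every model's score by the same 2, leaving all ΔAIC comparisons
  unchanged; the convention is stated here because it does change absolute
  scores.

`fit_cohort()` derives one seed per (subject, model) from a master seed,
so whole-table fits are bit-reproducible, and converts per-subject
failures into flagged rows instead of aborting.

## Model comparison

`delta_scores()` min-centers scores per subject (each row's best model at
0) and, separately, min-centers the *column sums* for the group-level
ΔAIC — relative differences are meaningful, absolute scores are not.
Per-subject winner ties are broken toward fewer free parameters, then by
the fixed order H, E, GM, R, CS; parsimony-consistent and deterministic.
`pairwise_wilcoxon()` runs two-sided signed-rank tests on per-subject score
differences (the same subjects underlie every model, so the paired test is
primary; the unpaired rank-sum variant is an option), exact for n ≤ 25
without ties, zero differences dropped, uncorrected by default with a Holm
option.

### Random-effects Bayesian model selection

ΔAIC sums and winner counts both ask "which single model fits everyone
best" and a few extreme subjects can dominate the sums. `bms_exceedance()`
instead treats the generating model as a random effect: population model
frequencies get a Dirichlet prior (all-ones by default), each subject's
log model evidence is approximated by −AIC/2 (or −BIC/2), and a
variational scheme alternates between per-subject model responsibilities
and Dirichlet counts until the concentration vector moves less than 1e-4
(at most 500 iterations). Each subject contributes at most one unit of
responsibility, which is what bounds the influence of outliers. Evidences
are mean-centered within subject before exponentiation — an invariance the
tests assert — so no overflow occurs.

The *exceedance probability* of model k is the posterior probability that
its population frequency exceeds every competitor's. For two models it is
the regularized incomplete beta function `1 − I₀.₅(α₁, α₂)`, computed
exactly; for more it is estimated from 10⁶ seeded Dirichlet draws (via
gamma draws and an argmax, standard error ≤ 0.5/√10⁶ per entry). The
conventional decisiveness threshold P > 95% is reported as a flag. The
closed form doubles as an independent oracle for the Monte-Carlo path in
the acceptance suite.

## Parameter identifiability

Whether a dual-parameter model's estimates are *separately* interpretable
is an identifiability question. `cohort_mean_correlations()` rebuilds each
subject's negative log-likelihood on the natural parameter scale,
approximates its Hessian at the ML estimate by central finite differences
with absolute step 1e-3 (exact on quadratics; a relative-step option
exists), inverts it to the asymptotic covariance and normalizes to
correlations. β is included in the differentiated objective (3×3 for
dual-parameter models), but the reported summary is the correlation
between the two discounting parameters.

Hessians at boundary, plateau or ridge estimates are frequently not
usable; the package declares a Hessian non-invertible when the Cholesky
factorization fails, the condition number exceeds 1e8, or implied
variances are non-positive, and reports the count per model instead of
averaging those subjects. Because the CS impatience parameter `a` often
sits near zero, an absolute step of 1e-3 conditions its Hessian poorly;
with `rescale_cs = TRUE` the CS objective is differentiated in the
rescaled coordinate `100·a`. For an exactly quadratic objective
correlations are scale-invariant, so the rescale only improves
finite-difference conditioning — the tests assert the invertible count
never decreases under it.

## Indifference-point analysis

The classical, R²-based workflow is included deliberately — it is still
widespread — together with the diagnostic that argues against relying on
it. `staircase_indifference()` estimates each delay's indifference amount
as the midpoint of the staircase's terminal bracket (lowest accepted,
highest rejected delayed amount); the bracket-midpoint estimator is an
assumption of this package, since titration data determine the point only
up to the termination criterion. Amounts are normalized to discount
fractions (20€ / indifference amount), which removes the amount from every
model's curve. `fit_indifference_curve()` fits the fraction-vs-delay curve
by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with the same
random multi-start scheme as the likelihood fits plus one deterministic
coarse-grid start — dual-parameter curves have rate–exponent ridges on
which all-random starts occasionally stall short of the nested optimum. R²
is 1 − SSres/SStot about the mean fraction and is reported as computed; it
is negative when data are flatter than their mean, and −Inf degenerates
(zero SStot) are not disguised. `group_median_points()` aggregates
fractions by per-delay medians (even counts: mean of the central pair) and
refuses mixed delay grids, which must be aggregated per subgroup.

The acceptance suite demonstrates the R²–rate confound this workflow
suffers from: across simulated hyperbolic subjects with fixed choice noise,
fitted R² correlates positively with the generating k, because steep
discounters' indifference points deviate more from their mean, inflating
explainable variance. Model selection in this package therefore rests on
the likelihood-based criteria above.

## The synthetic cohort generator

`generate_cohort_dataset()` produces the study conditions every recovery
test runs on. What it emulates:

* **Adaptive adjusting-amount design.** Seven delays (1, 2, 7, 14, 30, 90,
  180 days), immediate 20€, delayed amounts at least 20.5€ with no upper
  limit. After two successive choices of the delayed reward the delayed
  amount is reduced; after two successive immediate choices it is
  increased. Per-delay termination when the gap between the lowest
  accepted and highest rejected amount reaches the delay-specific
  criterion (1.0, 1.5, 2.0, 2.0, 3.0, 4.0, 4.0 €).
* **Fixed-offer design.** Six delays (0.25, 1, 7, 30, 90, 180 days);
  offers bounded to [20.5€, 80€], half placed uniformly below and half
  above the hyperbolically predicted indifference amount
  `20(1 + k̂D)` (clipped to the bounds, with degenerate sides flagged).
* **Agents.** Softmax choosers with parameters drawn from population
  presets calibrated to published medians and inter-quartile ranges of
  laboratory samples: two healthy-adult presets (one per task design) and
  a pathological-gambler preset with markedly steeper rates. Rates and β
  are log-normal (meanlog at the preset median, sdlog matched to the IQR
  ratio); exponents are truncated normal.

Where the protocol leaves mechanics open, the package fixes them once:
initial delayed amount 50€; adjustment step 15€, halved at each direction
reversal with a floor of 0.25€; an amount counts as accepted or rejected
only when confirmed by the same two-successive-choices evidence that
triggers an adjustment (isolated inconsistent choices neither move nor
terminate the staircase, which keeps sessions near the intended 100–150
trials for realistic β); the immediate amount stands in as the initial
rejected delayed amount so floor-pinned staircases terminate cleanly; and
the fixed-offer k̂ is obtained by matching the agent's true discount
fraction at 30 days (a deterministic stand-in for the two-stage protocol's
pre-task estimate — pass `k_hat` to `generate_fixed_offer_set()` to
emulate an estimated one). Seeds flow master → per-agent → per-delay, so
identical configurations reproduce byte-identical cohorts, and ground
truth is returned in a component separate from the trials so generating
parameters cannot leak into fitting inputs.

What the generator does *not* emulate: session effects, lapses or
attention failures (no trembling-hand mixture), magnitude effects, reward
type (real vs hypothetical), individually tailored delay grids, or the
episodic-cue manipulation beyond its parameter-level signature. Passing
recovery tests therefore certifies the pipeline's internal consistency
under its own assumptions — that the estimator, the selection machinery
and the diagnostics recover what generated the data — not that any given
empirical dataset satisfies those assumptions.

## Validation sizes and what the suite shows

The acceptance layer (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) recomputes, at sizes chosen to exercise each claim
while keeping a full run in the minutes range on one CPU:

* nesting identities on a 10⁴-point (amount, delay) grid, tolerance 1e-12;
* optimizer log-likelihoods vs an exhaustive 40³ log-spaced lattice on
  three 30-trial subjects (margin ≥ −0.01);
* Monte-Carlo exceedance vs the incomplete-beta closed form at 10⁶ draws,
  within three standard errors, on ten random two-model problems;
* parameter recovery on 50 agents per generating model under the adaptive
  design (Spearman ρ of log rates ≥ 0.8; β within a factor of 2 for ≥ 80%
  of agents pooled);
* model recovery on five replicate 40-agent CS cohorts at low β
  (exceedance for CS > 0.95 in at least four);
* the GM/R vs CS correlation contrast on matched 40-agent cohorts;
* the R²–k confound on 100 hyperbolic subjects;
* type-I error of the group comparison within binomial 99% bounds of 0.05
  over 1000 null replicates.

## Group and context statistics

`compare_parameter()` mirrors the applied workflow for comparing fitted
parameters between groups (e.g. patients vs controls) or within-subject
conditions: a square-root transform — which keeps the zero lower bound,
unlike the log, which diverges for near-zero rates — followed by a
two-tailed t-test (pooled variance by default, Welch optional; paired
variant for conditions), always reported alongside the matching Wilcoxon
test on untransformed values (ranks are transform-invariant).

## Known limitations

* AIC/BIC evidence approximations ignore posterior parameter uncertainty;
  no hierarchical/shrinkage estimation across subjects is provided.
* Protected exceedance probabilities and family-level comparisons are out
  of scope.
* The GM rate is weakly identified by construction (its near-perfect
  trade-off with the exponent is precisely what the Hessian analysis
  shows); its marginal recovery hovers near the 0.8 Spearman bound across
  seeds, so GM point estimates of k should not be interpreted in
  isolation.
* Recovery guarantees are relative to the generator's assumptions (see
  above); apply the diagnostics, not just the winner, to real data.
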