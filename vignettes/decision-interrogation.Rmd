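---
title: "Interrogating a health-economic decision model with hteval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrogating a health-economic decision model with hteval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Health-technology appraisal committees routinely want to know what happens
to a cost-effectiveness conclusion when an assumption changes: drop a
doubtful trial from the evidence synthesis, adjust it for suspected bias,
price a product differently, discount effects at another rate.  hteval
answers such questions by chaining four layers — evidence synthesis,
decision-model execution, economic post-processing and influence analysis —
behind one seeded, scriptable interface, so each "what if" is a small
scenario file and a reproducible run rather than a bespoke re-analysis.

This vignette documents the models and algorithms each layer implements,
the defaults and why they were chosen, and the limits of what the packaged
validation can show.

## Evidence synthesis

### Effect scale and data modes

Studies enter either as 2x2 arm counts or as a precomputed log odds ratio
with standard error — never both, so the two modes cannot silently
disagree.  Counts are converted by the standard estimator
$y = \log\frac{ad}{bc}$, $\mathrm{se} = \sqrt{1/a + 1/b + 1/c + 1/d}$,
with the Haldane–Anscombe correction (0.5 added to *all four* cells) applied
only when some cell is zero.  An arm with no subjects is rejected outright:
no correction can make its odds informative.

### Bias adjustment

The committee-facing questions "is this trial rigorous?" and "is this trial
relevant?" map to *internal* and *external* biases, each acting either
*additively* on the log odds ratio or *proportionally* on the treatment
effect.  Per study, elicited biases pooled over the selected assessors give
a total additive shift $\alpha$ with variance $\sigma^2_A$ (sums, assuming
independent biases) and a total proportional factor
$\pi = \prod_b \bar m_b$ with delta-method variance
$\sigma^2_\pi = \pi^2 \sum_b \bar v_b / \bar m_b^2$.  The adjusted effect
and first-order propagated variance are

$$y_{adj} = \frac{y - \alpha}{\pi}, \qquad
  \mathrm{var}_{adj} = \frac{\mathrm{se}^2 + \sigma^2_A}{\pi^2}
  + \frac{(y-\alpha)^2 \,\sigma^2_\pi}{\pi^4}.$$

Assessors are pooled as an equal-weight mixture — mean
$\bar m = K^{-1}\sum_a m_a$ and exact mixture variance
$\bar v = K^{-1}\sum_a (v_a + m_a^2) - \bar m^2$ — because assessor weights
are not elicited and equality is the neutral choice.  Working on the log-OR
scale keeps additive shifts symmetric and the proportional action a simple
scaling of the effect.

**Validity domain.**  The adjustment is first-order.  Validated against a
$10^6$-draw simulation of $(y^* - A)/P$ with normal $A$ and $P$, both
moments agree within a few percent while the coefficient of variation of
the proportional factor stays at or below about 0.15.  Beyond that the
comparison itself degenerates: a normal denominator has no finite inverse
moments, so the simulated variance of the ratio is driven by rare
near-zero denominators and does not stabilise at any sample size.  Tightly
elicited proportional biases (CV ≲ 0.15) are therefore the intended use;
wider elicitations should be modelled on the log scale instead (an
additive bias on the log OR *is* a proportional bias on the OR).

### Synthesis

Two engines share the random-effects model
$y_i \sim N(\theta_i, v_i)$, $\theta_i \sim N(\mu, \tau^2)$:

* **`dl`** — DerSimonian–Laird moments: fast, deterministic, used for
  interactive loops.  $\hat\tau^2 = \max\{0, (Q - (k-1)) /
  (\sum w_i - \sum w_i^2/\sum w_i)\}$ with fixed-effect weights
  $w_i = 1/v_i$, then an inverse-variance pool under
  $w_i^* = 1/(v_i + \hat\tau^2)$ with a normal 95% interval.
* **`bayes`** — Gibbs sampling with vague priors
  $\mu \sim N(0, 10^4)$, $\tau \sim U(0, 5)$.  $\theta_i$ and $\mu$ have
  conjugate normal full conditionals; $\tau$ is updated by slice sampling
  (stepping-out with width `tau_upper/20`, capped at 50 expansion steps per
  side, then shrinkage — no tuning parameter is exposed).  The default run
  retains 5000 draws after 1000 burn-in sweeps.  Points are posterior
  medians with central 95% credible intervals.

With `tau_upper = 0` (or a single study) the hierarchy collapses to
$y_i \sim N(\mu, v_i)$ and $\mu$ is drawn iid from its conjugate
posterior.  This is the correct sampler for the collapsed model: the
$\theta$-based chain freezes as $\tau \to 0$ because $\theta_i$ and $\mu$
become mutually pinned.

Every `run_meta()` also fits the *unadjusted* companion on the same study
subset (the grayed-out overlay in forest plots), reusing the same seed so
that switching every bias toggle off reproduces the companion bit for bit.
The value handed to the decision model is the DL point OR in `dl` mode and
the posterior median OR in `bayes` mode; in stochastic runs the full set
of posterior OR draws is handed over instead (below).

## The decision-model engine

A model is an ordered set of parameter specifications, strategy and
treatment tables, and a pure outcome function mapping one complete
parameter record to cost, QALY and clinical outcomes per
(strategy, treatment).

* **Deterministic mode** evaluates the outcome function once at each
  parameter's distribution **mean** (not median — the difference matters
  for skewed families such as lognormal and gamma, and is called out here
  because linear models propagate means exactly).
* **Stochastic mode** evaluates it over seeded draws.  Each parameter
  draws from its own RNG substream derived from the run seed and the
  parameter's position, so replacing one parameter's distribution never
  perturbs another's draws — scenario contrasts isolate exactly the
  parameter they change.

Correlated quantities must stay correlated: parameters declared
`empirical` with a shared `block` name are resampled by one common row
index per simulation, so whatever joint structure the stored samples carry
(e.g. posterior draws from one fit) survives into the PSA.  This is the
single-language analogue of estimating correlated parameters inside one
analysis component.  `attach_effectiveness()` uses it to register the
posterior OR draws for `or_eff`; a DL result in stochastic mode instead
becomes a lognormal on the log-OR point and SE, with a notice.

## The anti-D example model

The packaged fixture mirrors routine antenatal anti-D prophylaxis (AADP)
for RhD-negative pregnant women: sensitization during pregnancy risks
haemolytic disease of the newborn (HDN) in a subsequent pregnancy.  Three
strategies (no AADP / primigravidae only / all RhD-negative women) give
coverages $0$, $p_{prim}$, $1$; four products share one effectiveness OR
and differ only in dose cost.  Sensitizations under coverage $c$ are
$N[c\,\mathrm{expit}(\mathrm{logit}(s_0) + \log \mathrm{OR}) + (1-c)s_0]$;
affected fetuses and losses cascade with a single subsequent-pregnancy
stage discounted at lag $t_{lag}$.  QALYs and life-years are reported as
negative losses so "more is better" holds uniformly downstream.

All numbers are openly synthetic fixture choices with realistic
magnitudes (baseline sensitization risk ~1%, protective OR 0.4, ~£30
doses, £2,900 lifetime management, £15,000 per HDN case, 100,000-women
cohort); they are **not** the inputs of any appraisal, and the model
collapses the real multi-pregnancy cascade to one stage.  Its job is to
exercise every downstream layer with auditable arithmetic: the default
outcome table is pinned to an independent hand computation to six
significant figures.  Distribution spreads in `antid_model()` (beta for
probabilities, gamma for costs and QALY losses, lognormal for the OR,
uniform 0–7% for the effect discount rate) are chosen so every
distribution's mean equals the documented default, keeping deterministic
runs on the audited numbers.

## Economic post-processing

* **INMB**: per draw, $\lambda\,\Delta E - \Delta C$; intervals are
  empirical 2.5/97.5 percentiles.
* **Frontier**: alternatives sorted by ascending mean cost (ties by
  descending effect); weakly dominated options removed (an exact
  cost-and-effect tie keeps the first-listed alternative, for
  deterministic output); then interior options whose incremental ICER
  exceeds that of the next step are removed iteratively until the
  frontier's ICERs strictly increase (extended dominance).  The survivors
  are exactly the support points of $\max_\lambda (\lambda E - C)$ over
  $\lambda \ge 0$, which is how the property tests verify the algorithm
  against an independent oracle.
* **CEAC**: at each willingness-to-pay value, an alternative's probability
  is the fraction of draws in which its net benefit is maximal; exact ties
  split the draw equally among the tied set, so the curve normalises to 1
  by construction and is order-independent.  All strategy×treatment
  combinations compete in one comparison as mutually exclusive options.
* **Cost per clinical unit** uses means of draws
  ($\Delta \bar C / |\Delta \bar k|$), not per-draw ratios, avoiding the
  mean-of-ratios instability; deltas below $10^{-9}$ are flagged undefined
  rather than divided by.
* Default willingness-to-pay grid: 0–50,000 per QALY in steps of 500.

## Influence analysis

The deterministic tornado varies one parameter at a time over its one-way
range — explicit `low`/`high` if declared, else the 2.5th/97.5th
quantiles of its distribution — with everything else at central values,
and sorts bars by descending width (ties by name).  Point parameters are
skipped; ICER bars whose incremental effect changes sign across the range
are flagged non-interpretable instead of plotted.

The stochastic counterpart fixes one parameter at each range end while all
others are *sampled*, and uses the mean outcome of the two conditional
PSAs as bar ends; the same underlying draw set is reused with only the
conditioned column overwritten, so endpoint contrasts are free of
between-run Monte-Carlo noise.  The reference bar at the bottom is the
mean and 95% interval of the outcome under the unconditional PSA.  For
outcomes linear in independent parameters the two tornado variants agree
up to Monte-Carlo error, which the tests exploit.

## Scenarios and reproducibility

A scenario is a named JSON bundle of parameter overrides, a meta-analysis
configuration and run options; round-trips through storage are lossless.
`run_scenario()` derives all component seeds deterministically from one
scenario-level seed, and its output directory
(`<name>/{meta,psa,econ,tornado}/*.csv`) carries a manifest with the seed,
model fingerprint, package version and per-file md5 hashes —
deliberately no wall-clock timestamp, so identical runs are byte-identical
and `verify_manifest()` can re-check any archived result.

## The synthetic evidence generator

`gen_trials()` emulates a multi-study binary-outcome evidence base:
per-study true effects $\theta_i \sim N(\mu, \tau^2)$, control-arm logits
$\ell_i \sim N(m, s^2)$, binomial events at $\mathrm{expit}(\ell_i)$ and
$\mathrm{expit}(\ell_i + \theta_i)$.  Defaults mirror an anti-D-like base:
8 trials, true OR 0.4, $\tau = 0.2$, 1% control risk, 500–3,000 women per
arm.  `gen_elicitations()` jitters only the elicited *means* across
assessors (variances stay at the descriptor's value) so the pooled-bias
ground truth stays in closed form.  Degenerate 0-event arms are left in
the data and handled by the continuity rule — the generator does not
resample its way around them.

What the generator does *not* emulate: real elicitation behaviour
(anchoring, dependence between assessors), non-binomial outcome types, and
selective publication.  Passing recovery tests therefore show correctness
of the estimation machinery under the stated model, not robustness to
those phenomena.

A caveat the recovery study itself surfaced: with ~1% event risks the
empirical log-OR is attenuated toward zero at realistic arm sizes (mean
bias ≈ +0.05 at true log OR −0.7), a well-known sparse-data property of
the estimator.  The packaged recovery study therefore uses a well-powered
design (10% control risk), where DL coverage sits at 0.89–0.97 across
seeds and bias is within Monte-Carlo error of zero; rare-event syntheses
should be read with that attenuation in mind.

## Problem sizes used in validation

The shipped checks run, per invocation: the delta-method oracle on a
20-configuration grid at $10^6$ simulation draws each; DL recovery over
100 replications of 20 studies; the frontier oracle on 1,000 random
instances of up to six alternatives; Gibbs runs of 5,000 retained draws;
and end-to-end scenario runs at 5,000 simulations — sizes chosen so the
whole suite completes in about a minute while keeping Monte-Carlo bands
narrow enough for the stated tolerances.

## Known limitations

* The delta-method bias adjustment is first-order and loses accuracy for
  proportional-bias CVs above ~0.15 (see above); correlated biases are out
  of scope (variances add under independence).
* The anti-D model is a single-stage fixture, not a reproduction of any
  appraisal's model; Markov cohort traces and patient-level simulation are
  out of scope.
* Tornado plots compare exactly two strategies at a time; with more
  strategies they remain pairwise probes, not a global ranking.
* Value-of-information, publication-bias diagnostics and network
  meta-analysis are not implemented.
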