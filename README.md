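# hteval — interactive interrogation of health-economic decision models

Appraisal committees deciding on new health technologies constantly ask
"what if": what if that doubtful trial is dropped from the meta-analysis,
what if its results are adjusted for suspected bias, what if a product is
priced differently or effects are discounted at another rate?  Answering
each question normally means a bespoke re-analysis by the modelling team.
hteval makes the whole pipeline scriptable and fast enough for that loop:
evidence synthesis → decision model → economics → influence analysis, all
seeded and reproducible, with every "what if" captured as a small scenario
file.

It is aimed at health-economic analysts and methodologists who build or
review cost-effectiveness models and want their sensitivity analyses to be
replayable artifacts rather than one-off spreadsheet edits.

## What it computes

**Bias-adjusted random-effects meta-analysis** on the log odds ratio scale.
Expert-elicited biases — internal (rigor) or external (relevance), acting
additively or proportionally — are pooled over assessors by equal-weight
mixture moments and applied per study as

y_adj = (y − α) / π,  var_adj = (se² + σ²_A)/π² + (y − α)² σ²_π / π⁴,

where α, σ²_A sum the additive biases and π, σ²_π combine the proportional
ones (first-order propagation).  Synthesis is either DerSimonian–Laird
(instant, deterministic) or a Gibbs sampler for
y_i ~ N(θ_i, v_i), θ_i ~ N(μ, τ²) with vague priors μ ~ N(0, 10⁴),
τ ~ U(0, 5), slice-sampled τ, 5000 retained draws after 1000 burn-in.
Any subset of studies, bias types and assessors can be toggled; the
unadjusted companion fit is always computed alongside for comparison.

**A decision-model engine** that evaluates a user-defined outcome function
deterministically at distribution means or stochastically over seeded
draws (probabilistic sensitivity analysis).  Correlated inputs — e.g. the
posterior OR draws loaded by `attach_effectiveness()` — travel as joint
"empirical blocks" so their correlation survives into the PSA.

**Economic post-processing**: incremental net monetary benefit
INMB = λ·ΔE − ΔC with percentile intervals; the ICER efficiency frontier
with dominance and extended dominance; cost-effectiveness acceptability
curves (ties split exactly); incremental clinical outcomes with cost per
unit.

**Influence analysis**: tornado tables/plots over one-way parameter ranges
(2.5th–97.5th quantiles by default), plus a stochastic variant that fixes
one parameter while sampling the rest, with the PSA mean ± 95% interval as
a reference bar.

A worked example model ships with the package: an antenatal anti-D
prophylaxis style decision tree (three coverage strategies, four products
sharing one effectiveness OR) with openly synthetic inputs, plus
generators for trial data and bias elicitations with known ground truth.

## Worked example

```r
library(hteval)

st   <- read_studies(antid_example_path("studies.csv"))
elic <- read_elicitations(antid_example_path("elicitations.csv"))

res <- run_meta(st, elic, meta_config(method = "bayes", mcmc = list(seed = 1)))
res
#> <meta_result> method = bayes
#>   pooled OR 0.2976  [0.1760, 0.4871]   tau = 0.2659
#>   pooled log OR -1.2119  [-1.7374, -0.7193]
#>   unadjusted companion OR 0.3660  [0.2349, 0.5614]
#>   8 studies
```

Bias adjustment pulls the pooled OR from 0.37 down to 0.30: the elicited
biases say the trials overstate control-arm risk and understate the
effect, and adjusting for them makes prophylaxis look *more* effective,
with wider uncertainty (tau = 0.27 between-study SD on the log scale).

Load the posterior into the decision model and run a 5000-draw PSA:

```r
model <- attach_effectiveness(
  read_model_definition(antid_example_path("antid.yaml")), res)
psa <- run_model(model, run_options("stochastic", n_sims = 5000, seed = 1))
es  <- econ_summary(psa)
es$icer_table
#>    alternative    cost  effect               status  icer
#>  s1:partobulin 7789513 -1214.5             frontier    NA
#>        s1:dgam 7789513 -1214.5            dominated    NA
#>        ...
#>        s2:dgam 8043077  -880.1 extendedly_dominated    NA
#>        s3:dgam 8423710  -378.1             frontier 758.2
#>        ...
```

Only two options survive: doing nothing, and universal prophylaxis with
the cheapest product (D-Gam) at an ICER of 758 per QALY gained.  Giving
D-Gam to primigravidae only is extendedly dominated — the ICER of the
step reaching it exceeds that of skipping straight to universal coverage.
(QALYs are reported as negative losses, so −378 is better than −1214.)

```r
inmb(psa, "s2:partobulin", "s1:partobulin", 20000)[c("mean", "lo", "hi")]
#> INMB s2 vs s1 (Partobulin, wtp 20000): 6234032 [982394, 15307500]
es$ceac[es$ceac$lambda == 20000, ][1:1, ]  # top row shown
#>  alternative probability
#>      s3:dgam      0.9972
```

At a willingness to pay of 20,000 per QALY, universal D-Gam is
cost-effective in 99.7% of draws for this 100,000-women cohort model.
`tornado()` then ranks the drivers of that conclusion (here the baseline
sensitization risk dominates), and any variant — a study excluded, a
bias toggle flipped, a price changed — is a `scenario()` JSON file whose
`run_scenario()` output tree is byte-reproducible and hash-manifested.

The same loop is available from the shell via the installed
`exec/hteval` script (`run`, `meta`, `tornado`, `compare` subcommands).

## Scope notes

The example model is a deliberately simple fixture with synthetic inputs —
it exercises the machinery and is not a reproduction of any appraisal's
model.  See the methods vignette (`vignettes/decision-interrogation.Rmd`)
for the models, defaults, numerical choices and known limitations,
including the validity domain of the first-order bias adjustment.
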