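---
title: "Mixed-effect Bayesian networks: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effect Bayesian networks: model, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mebnet` models a longitudinal study in which $s$ subjects are measured on a
shared week grid (typically 0, 4, 8, 12). Each of $v$ biomarker responses
(blood concentrations) is regressed on the same $p$ standardized predictors
(nutrient intakes, sex, medication). The network is a *bipartite* directed
graph: predictors form one layer, responses the other, every
predictor–response edge is admitted and nothing else, so there are exactly
$v \times p$ candidate effects. Because the graph is bipartite and the
responses share no parents other than the observed predictors, the joint
posterior factorizes into $v$ independent local distributions, which the
package estimates one at a time and then assembles (`mebn()`).

Each local distribution is a mixed-effect regression. For subject $k$ at
one measurement,

$$\mu = X\beta + Z b_k, \qquad b_k \sim N(0,\, T C T'), \qquad
T = \mathrm{diag}(\sigma_b),$$

where $\beta$ are the *general* (population-level) effects and $b_k$ the
subject's *personal* deviations; the full personal effect of a predictor is
$\beta_j + b_{jk}$. $C$ is the correlation matrix of personal effects with
Cholesky factor $L$ ($C = LL'$). Sampling uses the non-centered
parameterization exclusively: $b_k = T L z_k$ with $z_k \sim N(0, I)$, which
is simultaneously the definition of how personal effects are generated and
the parameterization with the best sampler geometry for hierarchical models.
By default $Z$ contains the intercept column (subjects may have personal
baselines) and all predictors; columns can be dropped via
`mebn_spec(personal = ...)` when an effect is known not to vary between
persons.

Successive observations of a subject are serially correlated through an
AR(1) process on the residuals:

$$y^{(t)} = \mu^{(t)} + \rho\,(y^{(t-1)} - \mu^{(t-1)}) + \epsilon_t,
\qquad t = 2, \dots, n_k,$$

with $|\rho| < 1$. The first observation carries no AR term (the recursion
starts at $t = 2$); in the synthetic generator it is drawn from the
stationary marginal so early weeks are not artificially calm. Whether the
baseline week should itself be modeled as an outcome or only feed the AR
term is a genuine design fork; the default models it (it carries
information about $\beta$ and $b_k$), and `baseline_outcome = FALSE` demotes
it to an input-only role, in which case first-week values contribute no
likelihood.

Observation families are Normal or Gamma, both with an **identity link**:
$Y \sim \mathrm{Gamma}(\alpha, \alpha / \mu)$ so that $E[Y] = \mu$ and
$\mathrm{Var}[Y] = \mu^2/\alpha$. The identity link keeps general and
personal effects additive on the concentration scale, which is what makes
them directly interpretable and comparable across families. Its price is
that $\mu$ must stay positive: the likelihood soft-bounds the mean at
$10^{-6}$, which is benign when the intercept (the typical concentration
level) dominates the effect sizes, and degenerate otherwise. The simulator
applies the same floor to rare nonpositive means, logs how often it fired in
the truth record, and refuses configurations where more than 1% of
observations are affected.

## Priors

Two regimes for the general effects:

* **Vague** (`prior_vague()`): $\beta_0 \sim \mathrm{Cauchy}(0, 10)$,
  $\beta_j \sim \mathrm{Cauchy}(0, 2.5)$. Used when general effects are the
  object of study and even weak signals should emerge.
* **Regularized horseshoe** (`prior_rhs()`): per-coefficient half-Cauchy
  local scales $\lambda_j$, global scale $\tau$ with half-Cauchy($0, \tau_0$)
  prior, and slab $c^2 \sim \mathrm{Inv\text{-}Gamma}(\nu/2, \nu s^2/2)$
  limiting the largest coefficients. The global-scale guess is
  $\tau_0 = \frac{p_0}{p - p_0}\frac{\sigma}{\sqrt n}$ (`rhs_tau0()`), from
  the expected number $p_0$ of truly nonzero effects; $\sigma$ defaults to 1
  on the standardized scale. Defaults $\nu = 1$ (increase if sampling is
  difficult) and $s = 2$: the slab scale is not pinned down by theory, and
  $s = 2$ keeps "large" coefficients in the few-units range that standardized
  effects occupy. The intercept keeps its vague Cauchy prior in both regimes.

Priors the model needs but that are genuinely open choices: personal-effect
sds $\sigma_b \sim$ half-Student-t(3, 0, 1) (weakly informative on the
standardized scale) and $C \sim \mathrm{LKJ}(\eta = 2)$, mildly favoring
moderate correlations. Both are standard defaults for non-centered
hierarchical models and both are configurable (`lkj_eta`).

### The LKJ prior without an LKJ primitive

The MCMC backend is JAGS (via `rjags`), which has no LKJ distribution. The
package therefore samples the Cholesky factor through its spherical
parameterization: row $j$ of $L$ is a point on the unit hemisphere, and with
angle cosines $x_{jm} = 2u_{jm} - 1$, $u_{jm} \sim
\mathrm{Beta}(a_m, a_m)$, $a_m = (q - m + 2\eta - 1)/2$, the implied
distribution of $C = LL'$ is *exactly* LKJ($\eta$) — this follows from a
change of variables on the LKJ-Cholesky density, and the package's test
fixtures verify the construction against the closed-form marginal
$p(r) \propto (1 - r^2)^{\eta - 1 + (q-2)/2}$. The same representation is
inverted when a known correlation matrix is installed in a point-mass
posterior (`mebn_local_from_params()`).

Because JAGS is a Gibbs/slice sampler rather than HMC, there are no
divergence diagnostics; convergence is monitored with split-chain R-hat and
effective sample size on the scalar parameters (reported in
`$diagnostics`). Defaults are 2 chains, 500 adaptation + 500 burn-in + 1000
kept iterations; all configurable.

## Standardization

All predictors — including binary ones like sex and medication — are
standardized to sample mean 0, sd 1 (`standardize_predictors()`), so
coefficient magnitudes are directly comparable effect strengths. The
transform record allows exact inversion and maps binary-column effects back
to per-category differences ($\beta / \mathrm{sd}$ per unit of the original
coding). Responses are left in their concentration units; NRMSE (below)
makes errors comparable across them.

## Prediction and evaluation

Prediction is ancestral sampling (`predict()`): for each retained posterior
draw, predictor values enter the linear predictor with that draw's $\beta$
and $b_k$, the AR(1) adjustment
$\mu_t + \rho (y_{t-1} - \mu_{t-1})$ is applied where the previous week's
observation is available, and an observation is drawn from the family.
Subjects unseen at fit time get population-level predictions ($b = 0$,
flagged in the output). The point estimate for error metrics is the
posterior predictive *mean* — consistent with a squared-error metric;
whether a mean or single draws should be used is not externally fixed, so
the choice is documented here once.

$$\mathrm{NRMSE} = \frac{\sqrt{\tfrac1n \sum_j (\hat y_j - y_j)^2}}{\bar y},$$

with $\bar y$ the mean *observed* value of that response over the evaluation
set, and the network-level error the unweighted mean over responses.

Cross-validation (`cv_folds()`, `run_cv()`) splits the time series into
three parts, one per post-baseline week: split $i$ holds out week $i$'s
measurements for a tenth of the subjects at a time (10 folds, sizes within
one of each other), so every (subject, post-baseline week) cell is held out
exactly once per plan; week 0 is only ever an input. Training keeps the
held-out subjects' other weeks, so their personal effects remain estimable.
Two guards against leakage: held-out rows are removed from the training
table entirely, and when a training row's *previous* week is held out, the
AR term for that row is dropped rather than fed the held-out value.
`run_cv()` logs the train/test row partition of every fold so the property
is auditable, and reports both NRMSE and the direction-of-change
classification: predict only whether a concentration increases or decreases
relative to its last observed value, with the deterministic tie rule
"equal counts as decrease" on both the predicted and the observed side
(ties have measure zero for continuous values). A baseline adapter
(`run_cv_baseline()`) runs any user-supplied classifier — e.g. a
gradient-boosted tree — through the identical fold plan for a paired
comparison; no such classifier is bundled.

## Personal-effect analysis

`effect_table()` assembles the subjects × (response, predictor) matrix of
posterior mean personal effects $\hat\beta + \hat b_k$, the quantity
clustered for self-similar reaction groups. `kmeans_cluster()` is standard
k-means (best of 25 seeded restarts); `elbow_scan()` reports the
within-cluster sum-of-squares curve (raw and as a fraction of total SS,
since the "ratio" normalization is a matter of taste) with a warm start from
the previous $k$ so the curve is provably non-increasing. The suggested $k$
— the largest second difference of the curve on the log scale, i.e. its
relative curvature, which is robust to unevenly separated clusters where the
raw-scale version is dominated by the first drop — is advisory: the elbow is
a visual heuristic, and the tool never silently fixes $k$.

`rank_varying_effects()` sorts effects by the posterior mean of
$\sigma_b$, the inter-subject variation, keeping those above 0.10 by
default, and reports the extreme subjects' personal effects with central
90% credible intervals (5%–95% posterior quantiles throughout the package).
`export_effect_graph()` emits the weighted signed edge list of either the
general network ($\hat\beta$) or one subject's personal network
($\hat\beta + \hat b_k$), optionally truncated to the top-$n$ edges, as a
data frame or GraphML.

## The synthetic generator

`simulate_study()` draws data from the exact generative model above —
standard-normal predictors (binary columns Bernoulli(0.5), constant within
subject), then *re-standardized to exact sample moments* so the recorded
true coefficients apply to the design the fitting code sees; random slopes
from $N(0, TCT')$; AR(1) recursion with a stationary first point (for the
Gamma family the $t = 1$ shape is deflated to $\alpha(1 - \rho^2)$ so the
variance matches the stationary inflation); family noise. Every latent is
kept in a truth record that serializes losslessly, and
`recovery_report()` scores a fit against it (bias, RMSE, 90%-interval
coverage per parameter class).

`make_sysdimet_like()` is the canonical fixture: 106 subjects × weeks
0/4/8/12, 20 continuous nutrient predictors plus binary sex and
cholesterol-medication columns (22 predictors, hence 110 candidate
effects), four Gamma responses (total/HDL/LDL cholesterol, glucose) and one
Normal response (insulin). Intercepts sit near typical concentration levels
and effect magnitudes echo the reported scale of inter-subject variation
(largest personal-effect sd ≈ 4.3, on insulin), so desk-scale tests probe a
realistic signal-to-noise regime. What the generator does *not* emulate:
correlated nutrient co-intake, non-linear or time-varying effects, missing
data patterns, or measurement error in food records — passing tests on this
generator show the estimation machinery is correct and calibrated under the
model's own assumptions, not that real dietary data satisfy them.

## Numerical choices and problem sizes

Degenerate inputs: zero-variance predictor columns are refused by name;
Gamma responses must be strictly positive; a single personal column makes
$C$ the 1×1 matrix; subjects absent from a fit are predicted at the
population level rather than erroring inside prediction loops. Draw
thinning for prediction takes evenly spaced indices, so results are
bit-reproducible under a fixed seed.

The test-suite problem sizes — e.g. 50 subjects × 4 weeks with 10
predictors for interval-calibration replicates, 30–80 subjects for recovery
and cross-validation checks, 2 × (250–500)/500 MCMC iterations — were
chosen as the smallest configurations at which the checked properties
(coverage within binomial tolerance, sign/magnitude recovery of $\rho$ and
$\sigma_b$, horseshoe-vs-vague shrinkage ordering) are stable across seeds;
they are desk-scale by design. Full-scale analyses (106 subjects, 22
predictors, 5 responses) run with the same code path and default sampler
settings.

## Known limitations

Only bipartite structures are supported — no structure learning, no
response–response edges, no latent correlation between concentrations. The
Gamma identity link is undefined for nonpositive means, which restricts
admissible effect sizes relative to the intercept. JAGS mixes more slowly
than HMC on the horseshoe's funnel geometry; for hard posteriors increase
iterations or $\nu$. Inverse inference (choosing predictor levels to reach
a target concentration) is out of scope.
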