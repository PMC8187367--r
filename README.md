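# mebnet

Mixed-effect Bayesian networks for quantifying **general** and **personal**
effects of predictors — nutrient intakes, sex, medication — on repeatedly
measured biomarker responses such as fasting blood concentrations.

People react differently to the same diet. If a study measures $s$ subjects
at a few time points, a population-level regression answers only what a
nutrient does *on average*. `mebnet` models the whole system as a bipartite
Bayesian network: $p$ standardized predictors in one layer, $v$ responses in
the other, all $v \times p$ edges admitted. The joint posterior factorizes
into independent local distributions, each a mixed-effect regression

$$\mu_{k} = X_k\beta + Z_k b_k,\qquad
b_k \sim N(0,\;T C T'),\qquad T = \mathrm{diag}(\sigma_b),$$

with general effects $\beta$, subject-level deviations $b_k$ (sampled
non-centered as $b_k = TLz_k$, $C = LL'$), an AR(1) term
$y^{(t)} = \mu^{(t)} + \rho(y^{(t-1)} - \mu^{(t-1)}) + \epsilon_t$ linking a
subject's successive observations, and Normal or identity-link Gamma
observation families so effects stay additive on the concentration scale.
The *personal effect* of predictor $j$ on subject $k$ is
$\beta_j + b_{jk}$; its inter-subject standard deviation $\sigma_{b_j}$
measures how personal that effect is. General effects take either vague
Cauchy priors or the regularized horseshoe with global-scale guess
$\tau_0 = \frac{p_0}{p-p_0}\frac{\sigma}{\sqrt n}$.

Estimation is MCMC via JAGS (`rjags`). On top of the fit the package
provides ancestral-sampling prediction, posterior predictive checks, NRMSE
metrics, subject-level time-series cross-validation with
direction-of-change classification, personal-effect clustering (k-means +
elbow curve), ranked variation tables, effect-graph export, and a synthetic
study generator that draws from the exact generative model with a known
truth record.

## Worked example

Simulate a small study from known parameters, fit the network, and inspect
general and personal effects:

```r
library(mebnet)

cfg <- sim_config(
  s = 30, p = 4, v = 2, personal = c("x01", "x02"),
  beta    = rbind(c(10, 1, -0.8, 0.4, 0),    # y1: intercept 10, strong x01/x02
                  c(8, 0.5, 0, 0, 0.7)),     # y2
  sigma_b = rbind(c(0.5, 0.6, 0.4),          # personal baseline + slopes
                  c(0.3, 0.4, 0.2)),
  rho = 0.3, families = c("gamma", "normal"), dispersion = c(60, 0.8))
sim  <- simulate_study(cfg, seed = 7)
spec <- attr(sim, "spec")

fit <- mebn(sim$data, spec, chains = 2, adapt = 300, burn = 300, iter = 400,
            seed = 3)
round(coef(fit), 2)
#>    (Intercept)  x01   x02   x03   x04
#> y1        9.87 1.00 -0.91  0.47 -0.30
#> y2        7.97 0.65  0.01 -0.06  0.74
```

The posterior means recover the generating coefficients (first row: truth
10, 1, −0.8, 0.4, 0). In-sample fit and a subject's personal effects:

```r
metric_report(fit, n_draws = 100, seed = 5)$per_response
#>   response      nrmse     ybar   n
#> 1       y1 0.12377527 9.844771 120
#> 2       y2 0.09882663 7.987780 120

head(personal_effects(fit, "S001"), 3)
#>   response   predictor     b_mean      b_q05    b_q95 effect_mean effect_q05
#> 1       y1 (Intercept)  0.5526646 -0.1389952 1.624560   10.425945  9.6409873
#> 2       y1         x01  0.6157283 -0.2208033 1.549370    1.615533  0.7860453
#> 3       y1         x02 -0.4321084 -1.4200247 0.176806   -1.341686 -2.3867063
#>   effect_q95
#> 1 11.5455855
#> 2  2.5267209
#> 3 -0.6077609
```

Subject S001's reaction to `x01` (posterior mean 1.62, 90% CI [0.79, 2.53])
is stronger than the general effect 1.00 — the `b_mean` column is their
personal deviation. Cross-validated prediction and the direction-of-change
classification use the same fold plan the evaluation harness logs:

```r
plan <- cv_folds(unique(sim$data$subject_id), n_folds = 3, seed = 2)
run_cv(sim$data, spec, plan, chains = 1, adapt = 200, burn = 200,
       iter = 200, n_draws = 50, seed = 11)
#> Cross-validation over 9 fold fits (0 failed)
#>  response in_nrmse cv_nrmse in_acc cv_acc
#>        y1   0.1308    0.159  0.822  0.800
#>        y2   0.0985    0.121  0.833  0.822
#>   network   0.1146    0.140  0.828  0.811
```

Out-of-sample NRMSE (0.14) exceeds in-sample (0.11), and about 81% of
held-out direction-of-change calls are correct on this synthetic study.
Personal-effect clustering:

```r
et <- effect_table(fit)
elbow_scan(et, k_range = 1:5, seed = 1)   # WSS curve + suggested k
kmeans_cluster(et, 2, seed = 1)
#> k-means clustering of personal effects: k = 2
#>   cluster 1: 21 subjects (70.0%)
#>   cluster 2: 9 subjects (30.0%)
```

A full-scale fixture mirroring a dietary-intervention design (106 subjects,
22 predictors, 5 responses, 110 candidate effects) comes from
`make_sysdimet_like(seed)`. A thin CLI over these functions lives at
`inst/cli/mebnet.R` (`simulate`, `fit`, `predict`, `cv` subcommands).

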