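# mgcgm

Bayesian **m**ultilevel **G**aussian **c**opula **g**raphical **m**odels
with an adaptive graphical lasso prior, for mixed-type survey data —
continuous, ordinal and binary items with missing cells, respondents
clustered in schools, clinics or sites.

## What it does

Questions in a long questionnaire are interrelated in ways that pairwise
correlations misrepresent: a link between two items may be entirely
mediated by a third, and ordinary partial correlations are undefined for
mixed types.  `mgcgm` models all items jointly through a latent Gaussian
layer,

```
y_icl = F_l^{-1}(Phi(z_icl)),   z_ic | b_c ~ N_p(b_c, Omega^{-1}),   b_c ~ N_p(0, Psi),
```

where a zero entry `omega_lj` of the latent precision matrix means items
`l` and `j` are conditionally independent given everything else and the
cluster effects `b_c`.  Three ingredients make this workable on real
surveys:

* the **extended rank likelihood**: inference uses only the ordering of
  each observed column, so the marginals `F_l` are never specified and
  continuous, ordinal and binary items enter one joint model; missing
  cells (missing at random) are integrated over;
* an **adaptive graphical lasso prior** on `Omega`: element-specific
  double-exponential shrinkage with `lambda_lj ~ Gamma(s, t)` hyperpriors,
  so strong conditional associations are left alone while weak ones are
  shrunk toward zero;
* **cluster random effects** with an inverse-Wishart prior on their
  covariance `Psi`, from which cohort contrasts (e.g. survey waves a
  decade apart) are derived.

Everything is estimated by a block Gibbs sampler (truncated-normal latent
sweeps, column-wise precision updates via the Laplace scale-mixture
augmentation).  From one MCMC run the package computes cohort contrasts,
conditional (regression-type) coefficients of any response on all other
items, sparse conditional-dependence graphs, posterior-predictive risk
scores for rare binary outcomes, and a frequentist coverage study used to
calibrate the shrinkage hyper-parameter.

## Worked example

Simulate a 4-variable multilevel dataset from a known model, coarsen two
columns to ordinal/binary, blank 5% of cells, and fit:

```r
library(mgcgm)
set.seed(1)
truth <- calibration_truth()           # built-in SPD Psi and Omega (4 x 4)
sim <- simulate_latent(m = 12, cluster_size_mean = 40,
                       Omega_true = truth$Omega, Psi_true = truth$Psi)
dat <- discretize_latent(sim$Z, sim$cluster,
                         types = c("continuous", "ordinal", "binary", "continuous"),
                         thresholds = list(NULL, c(0.25, 0.5, 0.75), 0.6, NULL))
dat <- inject_missing(dat, rate = 0.05, mechanism = "MCAR")

fit <- mgcgm(dat, t = 1e-4, n_iter = 4000, thin = 5, burn_frac = 0.5,
             n_chains = 2, seed = 2)
fit
#> Multilevel Gaussian copula graphical model (4 variables, 12 clusters)
#>   adaptive graphical lasso prior: s = 0.01, t = 0.0001
#>   2 chain(s) x 4000 iterations, thin 5, burn-in 50%: 800 saved draws
#>   parameters with PSRF > 1.05: 0.0% (Omega), 0.0% (Psi)
```

`summary(fit)` prints the posterior mean precision and random-effect
covariance on the identified scale (total latent variance 1 per variable):

```r
summary(fit)
#> Posterior mean precision matrix (Omega):
#>        V1     V2     V3     V4
#> V1  2.022 -0.631  0.008  1.003
#> V2 -0.631  1.453  0.005 -0.433
#> V3  0.008  0.005  1.732 -0.003
#> V4  1.003 -0.433 -0.003  2.635
```

The generating truth has `omega_12 = -0.918`, `omega_14 = 1.209` and
near-zero `omega_13`, `omega_34`: the strong conditional associations are
recovered (V1–V2, V1–V4, V2–V4) while the weak ones are shrunk to
essentially zero — the intended behaviour of the adaptive prior.
Conditional coefficients of the other items on `V1` and the strongest
edges:

```r
association_report(fit, response = "V1")
#>   predictor     mean      lo     hi  flag
#> 1        V2  0.31287  0.2116  0.399  TRUE
#> 2        V3 -0.00394 -0.0538  0.055 FALSE
#> 3        V4 -0.49827 -0.6492 -0.347  TRUE

top_edges(fit, quantile_frac = 0.5)
#>   from to     weight       pcor sign
#> 1   V1 V4  1.0033703 -0.4346689   -1
#> 2   V1 V2 -0.6305252  0.3679006    1
#> 3   V2 V4 -0.4326864  0.2211584    1
```

The `flag` column marks predictors whose 95% highest-density region
excludes 0; `sign` labels edges as positive/negative partial associations.
For a rare binary outcome, fit with `store_z = TRUE` and call
`predict(fit, outcome = "...")` (or `predictive_score()`) to obtain
per-person posterior-predictive risk scores in [0, 1].

A thin command-line interface over the same functions is installed at
`inst/scripts/mgcgm` (`simulate | fit | summarize | predict | coverage`).

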