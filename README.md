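# autoccu

Autologistic dynamic occupancy models for opportunistic detection data.

## What problem this solves

Monitoring a rare or endangered species often produces *presence-only*
records: community scientists and agencies report where the species was
found, but not where they looked and failed. `autoccu` implements a
data-integration design for this situation: records of *common congeners*
from the same observer community are used to infer nondetections — if
congeners were recorded in a grid cell during a week but the focal species
was not, that week is coded as a focal nondetection. On top of the resulting
weekly detection histories the package fits a Bayesian multi-season
(dynamic) occupancy model whose colonization and extirpation probabilities
respond to the number of occupied neighboring cells (a metapopulation
"rescue effect") and to seasonal drought, while correcting for imperfect,
seasonally varying detection. It is aimed at ecologists and conservation
analysts who need annual occupancy estimates, and trend statements that are
not artifacts of growing search effort.

## The model

For grid cell `i`, season `t`, week `j`:

    z[i,1]   ~ Bernoulli(psi[i,1]),
               logit psi[i,1] = alpha_psi + beta1 herb_i + beta2 DEV_i
                                + beta3 hay_i + beta4 CU_i
    z[i,t]   ~ Bernoulli( z[i,t-1] (1 - eps[i,t]) + (1 - z[i,t-1]) gam[i,t] )
               logit eps[i,t] = alpha_eps[t-1] + be1 theta[i,t-1]
                                + be2 PDSI[i,t] + be3 CU_i      (gam likewise)
    theta[i,t] = sum of z[n,t] over the (<= 8) Moore neighbors n of i
    y[i,j,t] ~ Bernoulli( z[i,t] p[i,j,t] ),
               logit p[i,j,t] = alpha_p[j,t] + beta_p count[i,t],
               alpha_p[j,t] ~ Normal(alpha_p[j-1,t], sigma_p)

with standardized land-cover proportions (`herb`, `DEV`, `hay`), a binary
conservation-unit indicator `CU`, the May–July mean Palmer Drought Severity
Index `PDSI` (standardized; negative = drier), the raw occupied-neighbor
count `theta`, and the seasonal congener count as a survey-effort covariate.
Priors are Normal(0, 2) on coefficients and half-Normal(2) on `sigma_p`.
Fitting is by Metropolis-within-Gibbs MCMC (Gibbs on the latent occupancy
lattice, adaptive random-walk Metropolis on coefficients) with a compiled
core; derived output includes finite-sample and unconditional occupancy,
occupied-cell counts, extirpation/colonization response curves, WAIC, and a
posterior predictive (Bayesian p-value) goodness-of-fit check. A synthetic
data generator reproduces the structure of the motivating data (which are
location-restricted) and small instances come with exact posteriors by
brute-force enumeration, used throughout the test suite.

## Worked example

```r
library(autoccu)

# a synthetic data set at the default study conditions:
# 20 x 20 grid, 6 seasons, 18 weekly occasions, drought in season 5
scenario <- sim_scenario(seed = 11)
sim <- simulate_dataset(scenario)
head(sim$focal, 3)
#>   cell_id       date species_tag
#> 1      26 2017-06-05       focal
#> 2      26 2017-06-02       focal
#> 3      26 2017-06-05       focal

# build the weekly detection history from the two record streams
history <- build_history(sim$focal, sim$nonfocal, sim$grid, scenario$years)
history
#> detection history: 400 cells x 6 seasons x 18 weeks
#>   surveyed cell-years: 1064; detections (y=1): 427; nondetections (y=0): 4506

fit <- autoccu(history, sim$covariates, sim$grid,
               config = mcmc_config(n_chains = 3, n_iter = 10000,
                                    n_burnin = 4000, n_thin_total = 1500,
                                    seed = 2))
fit
#> Autologistic dynamic occupancy model (Bayesian fit)
#>   data: 400 cells x 6 seasons x 18 weeks; 1064 surveyed cell-years
#>   dynamics: autologistic; detection: weekly
#>   chains: 3; retained draws: 1500
#>   max Gelman-Rubin (coefficients): 1.054 (converged)

s <- summary(fit)
round(s$coefficients[c("beta_gam_theta", "beta_eps_theta", "beta_eps_pdsi",
                       "beta_p"), ], 3)
#>                  mean    sd   q2.5  q97.5  rhat p_gt0
#> beta_gam_theta  0.668 0.148  0.396  0.957 1.053 1.000
#> beta_eps_theta -0.502 0.154 -0.809 -0.206 1.018 0.000
#> beta_eps_pdsi  -1.404 0.836 -2.992  0.285 1.004 0.053
#> beta_p         -0.047 0.075 -0.197  0.103 1.002 0.268

round(cbind(year = scenario$years, s$psi_fs[, c("mean", "q2.5", "q97.5")]), 3)
#>      year  mean  q2.5 q97.5
#> 2017 2017 0.467 0.362 0.607
#> 2018 2018 0.580 0.434 0.714
#> 2019 2019 0.436 0.314 0.594
#> 2020 2020 0.432 0.365 0.517
#> 2021 2021 0.397 0.318 0.500
#> 2022 2022 0.563 0.489 0.657

bayes_pvalue(fit, n_draws = 400, seed = 3)$p
#> [1] 0.75
```

Reading the output: `beta_gam_theta > 0` and `beta_eps_theta < 0` recover
the generating rescue effect — colonization rises and extirpation falls as
more neighboring cells are occupied (`p_gt0` is the posterior probability
the effect is positive). `beta_eps_pdsi < 0` means extirpation increases
under drought (drier = more negative PDSI). The `psi_fs` table gives annual
finite-sample occupancy over surveyed cells with 95% intervals, and a
Bayesian p-value near 0.5 indicates no evidence of misfit. With three
short-ish chains the neighbor effects carry visible posterior uncertainty;
`plot(fit, "response")` draws the full response curves.

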