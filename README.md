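# dynmix

Dynamic multi-species N-mixture models and metapopulation forecasting for
stage-structured plant communities.

## The problem

Long-term monitoring of plant communities usually produces *counts per life
stage* — seedlings (R), saplings (S), reproductive adults (A) in fixed plots —
rather than the individual-based histories that demographic models
traditionally require. `dynmix` repurposes such multi-species abundance data
to infer stage-specific demography and its dependence on climate and on
neighbours, and then forecasts the whole interacting community. It was built
for the setting of a Mediterranean shrub community monitored in 18 plots of
5 × 5 m (five co-dominant species, annual surveys, a rainfall covariate), but
every design dimension is a parameter.

The pipeline separates the **direct** pathway of a climate driver (rainfall
entering a species' own survival models) from the **indirect** pathway
(rainfall changing the abundances of heterospecific neighbours, which then
alter the focal species' density covariates) — the distinction that decides
whether a drier future harms a species or releases it from competition.

## The model

Latent stage abundances evolve through an annual process, per species and
plot:

    survivors_S ~ Binomial(S_t, θ)            sapling survival
    movers      ~ Binomial(survivors_S, τ)    transition S → A
    gains       ~ Binomial(R_t, γ)            seedling recruitment to S
    survivors_A ~ Binomial(A_t, φ)            adult survival
    S_{t+1} = survivors_S − movers + gains
    A_{t+1} = survivors_A + movers
    R_{t+1,j} ~ Poisson( Σ_j' D[j,j'] · ρ · A_{t,j'} )   seed production + dispersal

with logit-linear survival models

    logit θ = a0 + a_rain·rain_t + a_intra·A_intra + a_inter·A_inter
    logit φ = b0 + b_rain·rain_t + b_intra·A_intra + b_inter·A_inter,

where `A_inter` is the summed adult abundance of all heterospecific modelled
species in the plot (standardized by stored constants), τ and γ are
species-level constants, and ρ is fixed at the empirical
seedlings\_{t+1}/adults\_t ratio. The joint posterior over all species'
coefficients and the latent seedling abundances is sampled with MCMC (JAGS).
Fitted rates feed per-plot 3 × 3 matrix population models over (R, S, A),
coupled into a (3P) × (3P) metapopulation matrix by a column-stochastic seed
dispersal matrix `D`; λ (the dominant eigenvalue) measures local population
growth, and perturbation analyses report the % change of λ under +10%
changes of rainfall or densities inside specific rate models.

## Worked example

Simulate a reduced synthetic community with known truth, fit it, and run the
downstream analyses:

```r
library(dynmix)

truth <- make_truth(n_species = 3, effect_scale = 0.3, seed = 1)
topo  <- default_topology(n_plots = 10, retention = 0.9)
sim   <- simulate_community(truth, topo, n_years = 15,
                            rainfall = make_rainfall(15, seed = 2), seed = 3)
sim$data
#> Count dataset: 10 plots x 15 years (2007-2021) x 3 species
#>   seedling (R) counts observed in year(s): 2007, 2008
#>   rainfall: attached  topology: attached

fit <- fit_model(sim$data, dynmix_config(warmup = 800, draws = 1050), seed = 4)
fit
#> Posterior: 2100 draws (2 chains) over 30 parameters, 3 species
#>   max R-hat 1.089; min ESS 47
```

Only two years carry seedling counts (emulating sparse recruitment data);
the remaining seedling abundances are sampled as discrete latent states.
Eigenvalue sensitivities at the joint community equilibrium:

```r
pars <- params_from_posterior(fit)                    # posterior means
eq   <- find_equilibrium(pars, sim$data$rainfall$mean, topo, fit$std)
sens <- sensitivity_table(pars, eq$state, rain = sim$data$rainfall$mean,
                          std = fit$std)
head(sens[order(-abs(sens$mean_pct_change)), ], 4)
#>    species  rate driver mean_pct_change
#> 9     sp03 theta  intra           -2.43
#> 10    sp01   phi  intra           -2.22
#> 6     sp03   phi   rain            1.35
#> 16    sp01   phi  inter            1.05
```

Read: a +10% increase of intraspecific adult density inside the sapling
survival model of `sp03` lowers its local λ by 2.4% on average across plots
(competition); a +10% rainfall increase in `sp03`'s adult-survival model
raises λ by 1.4%. `indirect_rainfall_sensitivity()` reports the analogous
effect routed through neighbours' survival only. Hold-out forecast skill from
posterior draws:

```r
fc <- forecast_holdout(sim$data, fit, 2007, 2021, n_draws = 200, seed = 5)
fc
#> Forecast 2007 -> 2021 (fully dynamic; 200 draws)
#>   stage  mse     r  r_lo  r_hi  n
#> 1     R   NA    NA    NA    NA  0
#> 2     S 20.6 0.964 0.925 0.983 30
#> 3     A 12.0 0.972 0.941 0.987 30
```

MSE and Pearson r (with Fisher-z 95% CI) compare posterior-mean predicted
abundances against the observed final-year counts over all plot × species
cells. `run_scenario()` + `compare_scenarios()` contrast a drier future
(below-average rainfall drawn with probability 0.8 over 50 years, 100 runs)
with baseline resampling of the observed series, in fully dynamic or
"no-dynamic" (historically resampled interspecific densities) mode.

A thin command-line wrapper is installed at `exec/dynmix`
(`dynmix simulate|fit|diagnose|project|sensitivity|forecast|evaluate
config.yaml`).

## Package layout

- `R/pipeline_io.R` — CSV/YAML readers and writers, dataset validation, config
- `R/synthetic_data.R` — ground-truth generator emulating the study design
- `R/demographic_model.R` — process kernels shared by simulator, likelihood, projections
- `R/inference.R` — JAGS model, diagnostics, posterior-predictive GOF, recovery
- `R/metapopulation.R` — matrix models, dispersal coupling, λ, equilibria, projection
- `R/perturbation.R` — direct and indirect (neighbour-mediated) λ sensitivities
- `R/scenarios_forecast.R` — climate scenarios, hold-out forecasts, skill metrics
- `vignettes/dynmix-methods.Rmd` — modelling assumptions and design choices
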