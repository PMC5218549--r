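# sarprobit

Spatial binary-choice analysis for owner-level survey data, built for
studies of family forest owners' stated willingness to harvest (WTH)
timber. When survey respondents are georeferenced to their parcels, nearby
owners tend to state correlated management preferences — because they share
biophysical conditions, markets, and social ties. Ignoring that correlation
biases a standard binary-choice analysis and, more importantly, hides the
*spillover* component of covariate effects: how a change at one ownership
propagates to its neighbors across the landscape.

## The model

Each owner i states a binary choice driven by a latent utility difference:

    WTH_i = 1  iff  y*_i > 0
    y*    = rho W y* + X beta + e,     e ~ N(0, I_n)

where `W` is an n x n row-standardized spatial weight matrix built from
parcel coordinates by **Delaunay triangulation** (two owners are neighbors
iff they are vertices of a common triangle; each row of W is 1/|N(i)| on
its neighbor set), and `rho` in (0, 1) measures spatial dependence in the
latent preferences. With `rho = 0` the model collapses to the familiar
probit `P(WTH_i = 1) = Phi(x_i' beta)`.

Estimation is Bayesian: priors `beta ~ N(0, 1)` per coefficient and
`rho ~ U(0, 1)`, sampled by MCMC (single-site Gibbs sweeps over the
truncated-normal latent utilities, a conjugate normal draw for `beta`, and
a griddy Gibbs draw for `rho` using exact eigenvalue-based log-determinants
of `I - rho W`). A non-spatial probit fitted by maximum likelihood serves
as the comparison model.

Because the reduced form is `y* = (I - rho W)^{-1}(X beta + e)`, a one-unit
change in covariate r at owner j moves outcome probabilities at *every*
owner. The package decomposes the average impact per the impact matrix
`S_r = diag(phi(eta)) (I - rho W)^{-1} beta_r` into

* **direct** = mean diagonal of `S_r` (own-ownership effect),
* **total** = mean row sum of `S_r`,
* **indirect** = total − direct (the spatial spillover),

so additivity holds exactly.

## Worked example

The generator reproduces the covariate and spatial structure the models
assume (242 owners, published covariate moments, spatial dependence 0.167),
so the full workflow runs without confidential data:

```r
library(sarprobit)

owners <- simulate_survey(sim_config(n = 242, seed = 1))
mean(owners$wth)
#> [1] 0.3016529            # simulated WTH prevalence, near the study's 0.29

w <- spatial_weights(owners, planar = TRUE)
neighbor_stats(w)
#>       n min_neighbors max_neighbors min_mean_dist_km max_mean_dist_km
#> 1   242             3             9             3.64             38.9

m1 <- fit_probit(owners)                       # Model 1 analogue
glance(m1)
#>       n loglik pct_correct converged
#> 1   242  -120.        76.0 TRUE

m3 <- fit_sar_probit(owners, w,                # Model 3 analogue
        config = mcmc_config(n_draws = 4000, burn_in = 1000,
                             seed = 1, n_chains = 2))
head(tidy(m3), 3)
#>   term               estimate std_error    mcse p_value prob_positive
#> 1 spatial_dependence    0.185     0.117 0.00340  0.114          1
#> 2 (intercept)          -0.551     0.525 0.00920  0.294          0.149
#> 3 beauty                0.270     0.202 0.00382  0.182          0.914

eff <- average_effects(m3, owners, w)
dplyr::filter(eff, term %in% c("sawlog", "past_harvest"))
#>   term          direct indirect total
#> 1 sawlog         0.279   0.0612 0.340
#> 2 past_harvest   0.138   0.0303 0.169

indirect_share(eff, c("sawlog", "past_harvest", "age55", "income_ge_50k"))
#> [1] 18.00078             # % of the total impact that is spatial spillover
```

The `spatial_dependence` row is the posterior of `rho`: here 0.185 with
posterior SD 0.117, against a generating value of 0.167. The effect rows
read, e.g.: owners holding forest for sawlog production have a 27.9
percentage-point higher harvest probability themselves (direct), and their
presence raises neighbors' probabilities by a further 6.1 points in
aggregate (indirect). `run_replication()` drives the whole four-model
comparison (probit and SAR probit, all owners and residential owners only)
and writes publication-layout tables.

If you have the original deposited spreadsheet, `read_survey(path)` loads
and validates it and the same pipeline replicates the published tables.

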