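# camtrapcomm

Community analysis of camera-trap surveys: relative activity indices,
Bayesian multi-species hierarchical occupancy modelling, and diel
activity overlap.

`camtrapcomm` is aimed at ecologists monitoring mammal communities with
remote camera grids, in particular where anthropogenic pressures —
proximity to human settlements and the activity of free-roaming dogs
and cats — may shape where native species occur and when they are
active. The package takes raw trigger records and deployment logs
through the full analysis chain used in such studies:

1. **Validation and effort accounting.** Three delimited tables
   (detections, deployments with malfunction gaps, site covariates) are
   cross-validated; trap-nights are active nights minus malfunction
   nights.
2. **Independence filtering and RAI.** Consecutive triggers of a
   species at a site count as one event unless ≥ 30 min apart (measured
   from the last *retained* event) or individually distinguishable.
   The relative activity index is
   `RAI = 100 × independent events / trap-nights`,
   computed overall and as seasonal means of monthly RAIs at sites with
   ≥ 60 effort days in ≥ 2 seasons, with Mann-Whitney U tests between
   seasons.
3. **Multi-species hierarchical occupancy.** For species *i* at site
   *j*, with `z`, `y`, `K` the latent occurrence, occasions with
   detection, and occasion count:

       z[i,j]        ~ Bernoulli(psi[i,j])
       y[i,j] | z    ~ Binomial(K[j], z[i,j] * p[i,j])
       logit psi[i,j] = a0_i + a1_i dist_j + a2_i dogRAI_j + a3_i dogRAI_j^2
                        + a4_i catRAI_j + a5_i catRAI_j^2
       logit p[i,j]   = b0_i + b1_i Cuddeback_j + b2_i Reconyx_j
                        + b3_i dogRAI_j + b4_i catRAI_j
       a_ki ~ Normal(mu_k, sigma_k^2)   (community hyper-distribution)

   RAIs enter as standardized `log(RAI + 1)`; quadratic terms are
   squares of the standardized columns. Occurrence is interpreted as
   *site use* (closure relaxed). Fitting is Metropolis-within-Gibbs
   MCMC in compiled code, with Gelman-Rubin diagnostics (converged when
   R-hat < 1.1), equal-tailed 95% percentile summaries, site-level
   species richness from the `z` draws, and stepwise covariate
   retention (keep a candidate iff the 95% CI of its community mean
   excludes zero).
4. **Diel overlap.** Event clock times are mapped to the circle and
   smoothed with a von Mises kernel density estimate (plug-in
   concentration from the sample's ML von Mises concentration, divided
   by the smoothing factor `adjust`). Overlap between two activity
   densities is `Δ = ∫ min(f, g)`, estimated by Δ1 (shared grid,
   smoothing 1.25; small samples) or Δ4 (own-point density ratios,
   smoothing 1.00; larger samples, default switch at n = 50), with
   bootstrap CIs (10,000 replicates at fidelity scale) and seasonal
   comparison by CI disjointness with a compact letter display.

A synthetic-data generator (`simulate_community()`,
`paper_scale_config()`) reproduces this generative structure — 121
sites, 9 native species, ~143-day deployments, crepuscular/nocturnal
von Mises diel mixtures — so every stage can be exercised against known
truth.

## Worked example

```r
library(camtrapcomm)

cfg <- simulation_config(n_sites = 40, n_species = 5, seed = 2024)
sim <- simulate_community(cfg)
ds  <- validate_dataset(sim$detections, sim$deployments, sim$covariates)

ev  <- filter_independent_events(ds$records, interval_minutes = 30)
tn  <- compute_trap_nights(ds$deployments)
rai <- compute_rai(ev, tn)
#> events: 504   total trap-nights: 5331

natives <- grep("^native", unique(ev$species_id), value = TRUE)
h   <- build_detection_history(ev[ev$species_id %in% natives, ],
                               ds$deployments, occasion_length_days = 10,
                               species = natives)
des <- prepare_covariates(ds$covariates, rai,
                          setNames(h$brand, h$sites), h$sites)
fit <- fit_community_occupancy(h, des$occ, des$det,
                               mcmc = mcmc_config(seed = 7))
fit
#> Multi-species occupancy fit: 5 species x 40 sites
#> 3 chains x 1200 kept draws; max R-hat = 1.057 (converged)

head(summarize_posterior(fit)$hyper)
#>                    parameter  mean  sd ci_low ci_high
#>        mu_alpha[intercept]    1.79 1.3  -0.69    4.65
#>  mu_alpha[dist_settlement]  -1.24 2.0  -6.14    2.44
#>          mu_alpha[dog_rai]   7.25 2.9   2.27   13.61
#>       mu_alpha[dog_rai_sq]  -5.51 2.6 -11.57   -0.96
#>          mu_alpha[cat_rai]  -0.89 1.8  -4.94    2.84
#>       mu_alpha[cat_rai_sq]  -4.19 3.0 -10.60    1.73

site_richness(fit)$study_mean
#> mean site richness: 1.52   95% CI: 1.35 1.77

a <- to_radian_time(ev$timestamp[ev$species_id == "native01"])
b <- to_radian_time(ev$timestamp[ev$species_id == "dog"])
estimate_overlap(a, b, n_boot = 1000, seed = 7)
#> Delta1 overlap = 0.908 [0.721, 0.977] (n = 49, 62; 1000 bootstrap)
```

Reading: the community mean of the dog-RAI linear term is positive and
its quadratic term negative with a CI excluding zero — the simulated
hump-shaped occurrence response to dog activity is recovered; mean
estimated richness is 1.52 of 5 species per site; the first native
species' diel activity overlaps strongly with dog activity (Δ1 = 0.91),
with a wide CI at these sample sizes.

## Command line

```sh
camtrap-community validate --detections det.csv --deployments dep.csv --covariates cov.csv
camtrap-community simulate --out simdir --seed 1 --sites 121 --species 9
camtrap-community rai      --detections ... --out outdir --interval-minutes 30
camtrap-community fit      --detections ... --out outdir --chains 3 --iters 6000 --seed 1
camtrap-community overlap  --detections ... --species-a native01 --species-b dog --estimator auto
camtrap-community run      --detections ... --out outdir --profile desk
```

The script is installed under `inst/cli/`; `--profile paper` switches to
the fidelity MCMC (3 × 50,000 after 10,000 burn-in, thin 50) and 10,000
bootstrap replicates.

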