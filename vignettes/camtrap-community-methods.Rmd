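---
title: "Methods: activity indices, community occupancy and diel overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity indices, community occupancy and diel overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camtrapcomm)
```

This vignette documents the statistical machinery of `camtrapcomm`, the
assumptions behind each stage, the tunable parameters and their
defaults, the choices made where the underlying field protocol leaves
the design open, and what the synthetic-data generator does and does
not emulate.

## Data model and effort accounting

The package consumes three tables: detection records (site, species,
timestamp, optional individual tag), deployments (per-site active and
malfunction date intervals with a camera brand), and site covariates.
Timestamps are naive local clock times: the analyses are single-region
by design, and the diel analysis needs clock time only, so no timezone
arithmetic is applied. Settlement geometry is reduced to representative
points and distances are planar Euclidean on projected coordinates; at
park scale (~15 km) the projection error is negligible relative to the
covariate's role in the model. Any projected metric CRS is accepted.

A *trap-night* is a calendar night of functioning effort: nights
covered by active intervals minus nights covered by malfunction
intervals, with partial first/last days counting (sub-day effort is not
recorded in the field logs). The year is partitioned into three
four-month seasons — December–March (cold), April–July (hot/dry),
August–November (hot/wet) — matching the regional climate regime the
protocol was designed around.

## Independence filtering and RAI

Consecutive triggers of the same species at the same site are collapsed
unless separated by at least `interval_minutes` (default 30) or carrying
distinct individual ids. The gap is measured from the **last retained**
event, not the preceding raw trigger: under the raw-gap alternative an
unbroken chain of sub-interval triggers would collapse hours of activity
into one event. This is a deliberate, configurable choice; it makes the
filter idempotent and monotone in the interval, both of which are
property-tested.

`RAI = 100 × events / trap-nights` per site and species. Seasonal RAI
is the arithmetic mean of the site's monthly RAIs within the season,
where each calendar month uses its own effort denominator and months
with zero effort are omitted rather than zero-filled (a zero-filled
month would claim knowledge of activity during unobserved time). Sites
qualify for seasonal comparison only with ≥ 60 effort days in each of
≥ 2 seasons, reducing spatial confounding between seasons. Seasonal
distributions are compared with a Mann-Whitney U test: exact by full
enumeration of label assignments (midranks, so ties are handled exactly)
up to combined n = 20 — enumeration is cheap there — and a normal
approximation with tie and continuity corrections beyond.

One window choice is not dictated by the protocol: the carnivore RAIs
used as occupancy covariates are computed over each site's **full
deployment**; this is flagged in the documentation and can be changed by
passing a different `rai_table`.

## The multi-species hierarchical occupancy model

For species $i$ and site $j$:

$$z_{ij} \sim \mathrm{Bernoulli}(\psi_{ij}), \qquad
  y_{ij} \mid z_{ij} \sim \mathrm{Binomial}(K_j,\; z_{ij} p_{ij})$$

$$\mathrm{logit}\,\psi_{ij} = \alpha_{0i} + \alpha_{1i}\,\mathrm{dist}_j
  + \alpha_{2i}\,\mathrm{dog}_j + \alpha_{3i}\,\mathrm{dog}_j^2
  + \alpha_{4i}\,\mathrm{cat}_j + \alpha_{5i}\,\mathrm{cat}_j^2$$

$$\mathrm{logit}\,p_{ij} = \beta_{0i} + \beta_{1i}\,\mathrm{Cudd}_j
  + \beta_{2i}\,\mathrm{Recon}_j + \beta_{3i}\,\mathrm{dog}_j
  + \beta_{4i}\,\mathrm{cat}_j$$

with every coefficient family drawn from a community normal
hyper-distribution, $\alpha_{ki} \sim N(\mu_k, \sigma_k^2)$. Carnivore
RAIs enter as $\log(\mathrm{RAI}+1)$, then standardized to mean 0,
sd 1; quadratic columns are squares of the *standardized* linear
columns. Occurrence is read as "site use" rather than closed-population
occupancy: several species' home ranges span multiple cameras, so the
closure assumption is relaxed and $\psi$ is the probability of use
during sampling.

**Occasions.** The protocol does not state how continuous effort was
discretized. The package partitions each site's ordered effort nights
into consecutive blocks of `occasion_length_days` (default 10; a
typical ~143-day deployment then yields ~14 occasions, a standard
regime for detection estimation), the trailing partial block counting
if non-empty. The default is declared, not inferred, and configurable.

**Priors.** Unstated in the protocol; the package uses conventional
vague community priors, $\mu_k \sim N(0, 10^2)$ and $\sigma_k \sim
U(0, 10)$, both configurable via `occu_priors()`. With a single species
the community layer is unidentifiable and the coefficients get the
fixed $N(0, 10^2)$ prior instead.

**Sampler.** Metropolis-within-Gibbs in compiled code: $z_{ij}$ from
its exact Bernoulli full conditional (pinned at 1 wherever $y_{ij} >
0$), coefficients by per-parameter adaptive random-walk proposals with
adaptation frozen at the end of burn-in (so retained draws target the
exact posterior), $\mu_k$ from its conjugate normal full conditional,
and $\sigma_k$ by sampling the precision from its Gamma full
conditional under the transformed uniform prior, rejecting draws
outside $(0, 10)$. The contract tested is posterior correctness — a
brute-force grid posterior on a toy problem, an ML oracle at large n,
and hyper-parameter recovery on simulated data — plus bit-level seed
reproducibility, not any particular sampler flavor. Desk-scale defaults
are 3 chains × 6,000 post-burn-in iterations (burn-in 1,000, thin 5);
the fidelity profile reproduces the field protocol's 3 × 50,000 /
10,000 / 50.

**Summaries.** Convergence is Gelman-Rubin
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ with pass declared strictly
below 1.1; constant chains are reported as 1 with a warning. Intervals
are equal-tailed 95% percentile intervals under R's default quantile
rule, stated explicitly for reproducibility. Site richness summarizes
the $z$ draws, not $\psi$, so it is conditioned on the observed
detections; because "mean richness" can average site posterior means or
per-draw across-site means, both summaries are emitted. Stepwise
covariate retention evaluates detection candidates first, then
occurrence candidates, in user-supplied order (the original order is
not recorded in the protocol), keeping a candidate iff the 95% CI of
its community mean excludes zero; every fit and decision is logged.

## Diel activity and overlap

Clock times map to radians, $t \mapsto 2\pi\,\mathrm{seconds}/86400$.
Activity densities are von Mises kernel mixtures. The kernel
concentration is Taylor's plug-in rule applied to the sample's ML von
Mises concentration $\hat\kappa$:

$$\kappa_{\mathrm{kernel}} =
  \left(\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
       {4\sqrt{\pi}\, I_0(\hat\kappa)^2}\right)^{2/5} \Big/ \mathrm{adjust}$$

so a larger `adjust` always smooths more. The protocol names only the
smoothing factors (1.25 for Δ1, 1.00 for Δ4), inheriting the bandwidth
rule from its analysis software without printing it; the rule above is
therefore declared here and validated against closed-form quadrature
oracles rather than against a formula. $\hat\kappa$ is capped at
$10^5$ for degenerate samples. Densities are overflow-safe (scaled
Bessel normalization) and integrate to 1 on the circle by construction.

The overlap coefficient is $\Delta = \int \min(f, g)$ over the diel
cycle. Δ1 evaluates both KDEs on a shared 128-point grid and integrates
the pointwise minimum by the trapezoid rule on the closed circle; Δ4
averages the capped density ratios $\min(1, \hat g/\hat f)$ at each
sample's own points and is exactly symmetric and exactly 1 on identical
samples. The size rule follows the estimators' known small/large-sample
performance: Δ1 when the smaller sample is below 50, Δ4 otherwise
(boundary to Δ4). Pairs with under 8 detections per group are skipped —
density estimates below that are unusable, matching the smallest group
size the reference protocol retained.

Bootstrap CIs resample each sample at its own size, re-estimating the
kernel concentration per replicate; the percentile interval is the
default (basic available), 10,000 replicates at fidelity scale and
1,000 as the desk default. Two seasonal estimates differ significantly
when their 95% CIs are disjoint; letters are assigned to the maximal
cliques of the not-different graph, so groups sharing a letter are not
distinguishable. Overlap samples are pooled across all cameras and
years by default (a switch restricts them to the seasonal-RAI camera
subset).

A numerical caveat established during development: Δ1 at smoothing 1.25
carries an upward smoothing bias (~0.012 at n = 2000 for two antipodal
von Mises(·, 2) densities) that exceeds its sampling SD at large n, so
percentile bootstrap intervals around Δ1 cannot attain nominal coverage
of the true overlap at that scale. Δ4 is nearly unbiased in the same
setting, and the acceptance suite's coverage check accordingly uses Δ4,
consistent with the size rule at those sample sizes.

## The synthetic world

`simulate_community()` generates deployments (staggered starts, mean
length 143 days, occasional malfunction gaps), covariates, carnivore
event streams, and native detections exactly through the model above:
species coefficients from the community hyper-distributions, $z$ from
$\psi$, occasion-level detections from $p$, and each detected occasion
expanded into ≥ 1 records (shifted-geometric count) with times of day
from species-specific von Mises mixtures (crepuscular dawn/dusk
bimodality for half the natives, nocturnal for the rest; diurnal dogs
and cathemeral cats, both with dawn/dusk peaks).

Defaults state the world once: 121 sites and 9 native species; the
printed community coefficient means (distance +0.41; dog RAI +3.13 with
quadratic −3.34; cat RAI 0.49/−0.82; detection: Cuddeback −0.25,
Reconyx −0.37, dog 0.11, cat 0.43) are used as generator means for the
corresponding families. Quantities never printed are illustrative and
documented as such: occurrence intercept mean −0.4 (community mean
occurrence ≈ 0.40) with sd 1.2 (spanning the reported 0.06–0.76 species
range), detection intercept logit(0.24) with sd 0.9, hyper-sds of 0.3–0.8
for covariate families, log-normal settlement distances over ~50–3000 m,
and carnivore activity rates centred near ~1.2 (dog) and ~0.5 (cat)
events per 100 trap-nights.

Two coherence devices matter for testing. Carnivore streams are
generated so that the RAI the *pipeline recomputes* from them is the
very value entering the occupancy design matrix (the generated counts
are the design covariate), and same-day events are laid ≥ 1 h apart so
the 30-min independence filter keeps every generated carnivore record.
The generator does **not** emulate: spatial autocorrelation or animal
movement between cameras, unmodelled heterogeneity in detection,
non-von-Mises activity shapes, solar-time (sunrise-anchored) activity,
or observer errors in species identification. A green recovery test
therefore establishes that the inference machinery is self-consistent
at realistic scale — not that any of these field complications are
handled.

## Numerical and reproducibility choices

* All seeded paths (MCMC, bootstrap, simulation) are bit-reproducible;
  chains run sequentially from one seeded stream.
* Exact Mann-Whitney enumeration switches to the normal approximation
  at combined n = 20.
* Degenerate inputs: constant covariates error at standardization;
  empty detection tables abort validation; sites with zero effort are
  dropped from histories with a warning; density ratios at zero-density
  points are capped at 1 with a warning.
* The pipeline manifest records the config echo, seeds, package
  version, per-stage timings and MD5 digests of every output table;
  because timings are embedded, determinism is asserted on the output
  tables and the digest map, not on the manifest file itself.

## Known limitations

* Species-level inferences shrink toward the community mean; with few
  detections a species' estimated response largely reflects the
  hyper-distribution (inherent to the model class).
* RAI is an activity index, not density; no abundance interpretation is
  attempted.
* Richness covers the modelled species only; no data augmentation for
  never-detected species.
* Δ1's smoothing bias at large n (above) means its bootstrap CI is best
  read as precision of the estimator, not of the true overlap.
* The stepwise retention procedure inherits the usual caveats of
  sequential testing; the audit log exists so its path is inspectable.
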