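# hydroniche

Water-source partitioning and stability analysis for revegetated dryland
plant communities, built around dual stable isotopes of water.

## The problem

In sand-binding revegetation systems (xerophytic shrubs planted into
straw checkerboards, progressively colonized by semi-shrubs and herbs),
long-term sustainability hinges on *vertical water-source partitioning*:
herbs draw on the 0–20 cm layer recharged by rain, semi-shrubs on
20–40 cm, shrubs on the 40–100 cm store. Because root water uptake does
not fractionate hydrogen or oxygen isotopes, xylem water is an isotopic
mixture of the soil layers a plant taps, and the mixture can be inverted
statistically. `hydroniche` is for ecohydrologists who want that whole
chain — from raw δ²H/δ¹⁸O sample tables to a site-level stability verdict
— as tested, scriptable R functions.

## What it computes

* **Meteoric water line & d-excess** — OLS of δD on δ¹⁸O for
  precipitation (`fit_meteoric_line()`), d-excess `δD − 8·δ¹⁸O`
  (`d_excess()`), δ-notation arithmetic (`delta_from_ratio()`).
* **Bayesian mixing model** (`run_mixing()`) — for mixture replicate *i*
  and isotope *j*,
  `y_ij ~ N(Σ_k p_k μ_jk, σ_j²)`, `p ~ Dirichlet(α)`, half-normal priors
  on the residual SDs, zero uptake discrimination, residual-only error.
  Sampling is adaptive random-walk Metropolis on additive-log-ratio
  coordinates with a Haario-style joint proposal; split-chain R̂ is
  reported. Draws aggregate from 8 soil layers to reporting depth groups
  (`aggregate_layers()`, `summarize_posterior()`).
* **Herb-to-shrub ratio** — `R_h/s = C_h / C_s`, the mean herb 0–20 cm
  contribution over the mean shrub 40–100 cm contribution
  (`herb_shrub_ratio()`), classified stable (< 0.9), semi-stable
  (0.9–1.4) or unstable (> 1.4) (`classify_stability()`), plus age
  trends (`age_trend()`), proportional-similarity niche overlap
  (`niche_overlap()`) and ANOVA/Tukey comparisons (`anova_tukey()`).
* **Shrub–herb biomass model** —
  `dW_s/dt = r_s φ_s(R) W_s − u_s W_s`,
  `dW_h/dt = r_h φ_h(R) W_h − u_h W_h`, with
  `φ_s = exp(−k·max(R − R₀, 0))`, `φ_h = 2/(1 + exp(b(R − R_c)))` and
  `R = k_h W_h / (k_s W_s)`: RK4 trajectories (`simulate_dynamics()`),
  analytic Jacobian (`jacobian_analytic()`), trace/determinant
  eigenvalues with regime classification (`eigen_stability()`,
  `site_stability()`), bifurcation scans and regime calibration
  (`bifurcation_scan()`, `calibrate_regimes()`).
* **Synthetic-data generator** (`generate_chronosequence()` and friends)
  — a nine-site restoration chronosequence (planted 1953–2020 plus a
  natural control) with known injected truths, so every stage is testable
  without field data.

## Worked example

```r
library(hydroniche)
settings <- generator_settings(seed = 1)

# 1. Local meteoric water line from synthetic precipitation
lmwl <- fit_meteoric_line(generate_precipitation(settings))
print(lmwl)
d_excess(-70, -10)   # a point on the global line -> exactly 10

# 2. Soil-layer sources and a shrub xylem mixture at the control site
sites <- default_chronosequence()
ck <- sites[sites$site_id == "CK", ]
sources <- summarize_sources(generate_soil_profile(ck, settings))
xylem <- generate_xylem(ck, "shrub", sources, settings, target = 0.523)
post <- run_mixing(xylem$samples[1:3, ], sources, mixing_config(seed = 302))
summarize_posterior(aggregate_layers(post))

# 3. Stability from the contribution ratio, and from the biomass model
R <- herb_shrub_ratio(36.7, 26.3)
classify_stability(R)
site_stability(1.61, dyn_params())
```

Output:

```
Meteoric water line: dD = 7.64 d18O +9.67  (R^2 = 0.951, n = 26)
[1] 10

      source mean_pct sd_pct ci_low_pct ci_high_pct
1    0-20 cm    18.64   6.59      6.265        31.4
2   20-40 cm     9.41   7.87      0.283        28.8
3  40-100 cm    50.09  17.75     14.953        80.3
4 100-120 cm    21.86  12.84      0.958        47.9

[1] "semi-stable"
max Re(lambda) = 0.0109 -> marginal
```

Reading it: the 26 generated precipitation events reproduce the local
line (slope just below 8, intercept just above 10 — the arid-zone
signature of sub-cloud evaporation); the mixing posterior attributes
50.1 % of the shrub's water to the 40–100 cm block against an injected
truth of 52.3 %, with the truth inside the 95 % credible interval; a plot
with `C_h = 36.7` and `C_s = 26.3` sits at the critical ratio 1.4
(semi-stable); and a site at ratio 1.61 evaluates marginal-to-unstable
under the default biomass-model breakpoints.

## The analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study-shaped analysis over the synthetic chronosequence, writing
tables under `results/`:

```sh
Rscript analysis/01_generate_data.R        # dataset + truth table
Rscript analysis/02_meteoric_line.R        # LMWL, d-excess
Rscript analysis/03_mixing_contributions.R # mixing posteriors, all sites/species
Rscript analysis/04_stability_ratio.R      # R_h/s classes, age trend, overlap, ANOVA
Rscript analysis/05_dynamics.R             # eigenvalue regimes, bifurcation, calibration
```

Step 3 is the slow one (54 MCMC runs; some minutes on one CPU). The
drivers print what they find, including honest caveats: posterior
estimates shrink toward the Dirichlet prior where the soil profile
separates the layers weakly, and the step-4 narrative contrasts the
estimated age trend with the injected truth.

## Documentation

`vignettes/water-source-partitioning.Rmd` documents the models, every
tunable default (with units and rationale), the numerical choices, and
the known limitations — including the identifiability regime of
near-collinear sources and what the calibration search does and does not
establish about the eigenvalue analysis.
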