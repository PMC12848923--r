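---
title: "Water-source partitioning and stability in revegetated drylands: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-source partitioning and stability in revegetated drylands: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In sand-binding revegetation systems of arid China, shrubs, semi-shrubs and
herbaceous plants coexist on a water budget of under 200 mm of annual
precipitation. Whether such a community is sustainable depends on *where in
the soil profile* each functional group takes its water: herbs root in the
top 0–20 cm and track recent rain, semi-shrubs exploit the 20–40 cm layer,
and shrubs reach the 40–100 cm store. Dual stable isotopes of water (δ²H,
δ¹⁸O) make this partitioning measurable, because root uptake does not
fractionate: xylem water is an isotopic mixture of the soil layers tapped.

`hydroniche` implements the full quantitative chain for such a study over a
restoration chronosequence (stands planted 1953–2020 plus a natural
control, CK, sampled in 2022):

1. a synthetic-data generator emulating the isotope structure of the system,
2. meteoric-water-line regression and d-excess,
3. a from-scratch Bayesian dual-isotope mixing model,
4. the herb-to-shrub ratio statistic $R_{h/s}$ with stability thresholds,
5. a two-compartment shrub–herb biomass model with eigenvalue stability
   analysis.

## Synthetic-data generator

No public dataset accompanies the study system, so the generator *is* the
study-conditions definition: every downstream stage is exercised against
data whose ground truth is recorded.

**Precipitation.** δ¹⁸O is drawn uniformly on $[-15, 5]$ ‰ (the reported
range; the source gives no distribution, and a uniform draw reproduces the
range without inventing seasonal structure). δ²H follows the local meteoric
water line $\delta D = 7.8\,\delta^{18}O + 12.2$ plus Gaussian noise. The
default noise SD is derived, not guessed: with
$R^2 = s^2 v_x / (s^2 v_x + \sigma^2)$, $v_x = 400/12$ and the reported
$R^2 = 0.963$, $\sigma \approx 8.83$ ‰. Samples that stray past the
$[-200, 50]$ ‰ sanity envelope (possible for the most enriched events) are
redrawn. Expected fit at $n = 26$: slope 7.8, intercept 12.2,
$R^2 = 0.963$.

**Soil profiles.** Nine depth intervals (0–5 … 120–150 cm), three
replicates each. Layer-mean δD follows
$\delta D(d) = \delta_{deep} + (\delta_{surf} - \delta_{deep})
e^{-d/\ell}$ at the interval midpoint — evaporative enrichment at the
surface decaying toward a depleted deep store. The control profile
(surface −75 ‰, deep −110 ‰, $\ell = 45$ cm) spans ≈ 31 ‰ top to bottom;
younger stands get stronger contrast and shorter $\ell$, older stands
flatter profiles, mirroring the observed pattern. δ¹⁸O derives from δD
through a soil evaporation line (slope 5.5, intercept −20 ‰ — typical
arid-zone values, configurable; the source reports none). Within-layer
replicate SDs default to 2 ‰ (δD) and 0.4 ‰ (δ¹⁸O); the source states
none, and these match routine cryogenic-extraction repeatability. They are
placeholders in the sense that no field value anchors them.

**Xylem.** For each group the truth vector places the configured
main-block mass (shrub → 40–100 cm, semi-shrub → 20–40 cm, herb → 0–20 cm)
split across block layers by thickness, and spreads the remainder with
geometric decay (ratio 0.5 per layer step) away from the block. Expected
xylem isotopes are the proportion-weighted source means (zero
discrimination at uptake); residual SDs default to 1.5/0.3 ‰.

**Chronosequence defaults.** Shrub deep-water means are anchored at the
two reported old-stand values (55.6, 57.6 %) and the remaining six chosen
once so that the Pearson correlation with restoration age across the eight
dated stands is 0.862 — the generator injects exactly the trend the
analysis is asked to recover. Herb shallow means are derived per site as
$R_{h/s} \times C_s$ from the site-wise ratio series (0.81 … 1.61, CK
1.4), so the ratio analysis reproduces the published classification from
first principles. Semi-shrubs appear only at 1995a, 2009a, 2015a, 2020a
and CK (their successional decline), with mid-layer means correlating with
age at $r \approx 0.89$ among those sites. CK has no restoration age and
is excluded from every trend; it is ordered last with age max + 1.

A single master seed fans out to fixed per-stage offsets
(precipitation +100, soil +2000 + 10·site, xylem +30000 + 10·site +
group), so any stage regenerates identically in isolation.

**What the generator does not emulate:** event-scale rainfall timing,
spatial heterogeneity within plots, groundwater (inaccessible at > 80 m in
this system), root-profile dynamics, and — importantly — any deviation of
soil δ¹⁸O from a single evaporation line. Real soils show depth-dependent
d-excess; the generator's collinear line makes the second isotope nearly
redundant, which is the conservative case for the mixing model (see
below). Passing tests therefore demonstrate correctness of the machinery
and honest behavior under a hard, realistic identifiability regime; they
do not certify accuracy on data richer than the emulation.

## The mixing model

For mixture replicate $i$ and isotope $j$:
$$y_{ij} \sim N\!\Big(\sum_k p_k \mu_{jk},\; \sigma_j^2\Big), \qquad
p \sim \mathrm{Dirichlet}(\alpha), \qquad
\sigma_j \sim \mathrm{HalfNormal}(s_j),$$
with discrimination fixed at zero and a *residual-only* error term: source
variances are deliberately not propagated into the likelihood, matching
the "residual" error configuration of the standard tool for this analysis.
Defaults: $\alpha = 1$ per source (uniform on the simplex), $s_j = 5$ ‰,
eight sources (0–5 … 100–120 cm; the deepest sampled interval is excluded
because eight intervals were supplied as sources while nine were sampled —
the scheme is a config object, not a hard-coded guess).

**Sampler.** Component-wise random-walk Metropolis on additive-log-ratio
coordinates of $p$ (last source as reference) plus $\log\sigma_j$, with
per-coordinate step sizes adapted every 100 burn-in iterations toward
25–45 % acceptance. Desk-scale default: 3 chains × 20 000 iterations,
10 000 burn-in, thinning 10 (3 000 retained draws); the "long" setting of
the reference tool corresponds to ~300 000 iterations. Split-chain
$\hat R$ is reported per proportion and exceeding 1.05 warns rather than
fails. Aggregation to depth groups happens per draw, after sampling, so
posterior correlations are preserved. A floor of 0.1 ‰ guards the source
collinearity check against single-replicate layers.

Correctness is established two independent ways: on two-source,
single-isotope problems the sampler is compared with a dense grid
normalization of prior × likelihood (total variation < 0.05), and the
prior is recovered exactly when the likelihood is switched off.

**A known, honest limitation.** With eight sources lying on one
evaporation line, the likelihood constrains essentially a single linear
functional of $p$. The posterior is then close to uniform on the simplex
slice satisfying that constraint, and its *group* means shrink toward the
prior means (37.5 / 12.5 / 37.5 % for the 0–20 / 20–40 / 40–100 cm
groups). The recovery harness (`recovery_experiment()`) quantifies this:
concentrated truths such as 78.6 % shallow or 19.8 % mid-layer are
recovered with a systematic deficit of roughly five points, while the 95 %
credible intervals cover the truth essentially always. This is a property
of the model class under near-collinear sources — verified against an
independent JAGS implementation of the identical model — not a sampler
artifact. In the identifiable limit (two well-separated sources, noiseless
mixture) the bias vanishes, which the test suite checks.

## The stability statistic

Per plot, $C_h$ is the mean 0–20 cm contribution over herb species and
$C_s$ the mean 40–100 cm contribution over shrub species;
$R_{h/s} = C_h / C_s$. Classification: stable for $R < 0.9$, semi-stable
for $0.9 \le R \le 1.4$, unstable for $R > 1.4$. The boundary convention
is closed on both ends of the middle class because the eigenvalue table
treats $R = 1.4$ as the *critical* (bifurcation) value rather than an
unstable one; the thresholds are exposed as configuration. Ratios are kept
at full precision and rounded only in report tables.

## The shrub–herb biomass model

$$\frac{dW_s}{dt} = r_s\,\phi_s(R)\,W_s - u_s W_s,\qquad
\frac{dW_h}{dt} = r_h\,\phi_h(R)\,W_h - u_h W_h,\qquad
R = \frac{k_h W_h}{k_s W_s},$$
with $\phi_s(R) = e^{-k\max(R - R_0,\,0)}$ and
$\phi_h(R) = 2/(1 + e^{b(R - R_c)})$. Rates default to the long-term
monitoring values $r_s = 0.35$, $u_s = 0.08$, $r_h = 0.80$, $u_h = 0.25$,
$k = 1.2$, $b = 3.0$. $R_0$ and $R_c$ are unreported; the package
identifies them with the stability thresholds 0.9 and 1.4 — the natural
reading, since $R_0$ is where herb pressure begins to suppress shrubs and
$R_c$ is the critical ratio.

Design choices that were genuinely open:

* **$k_h = k_s = 1$.** The published Jacobian entries
  ($J_{12} = r_s \partial\phi_s/\partial R$,
  $J_{21} = -r_h R^2 \partial\phi_h/\partial R$) follow from the chain
  rule only when $k_h / k_s = 1$; the general form carries the ratio on
  the off-diagonals and is available as `form = "general"`.
* **Evaluation point.** Because each equation is linear in its own
  biomass, the Jacobian depends on the state only through $R$; the
  per-site evaluation uses the printed equilibrium expressions
  $W_s^* = r_s\phi_s/u_s$, $W_h^* = r_h\phi_h/u_h$ to fix the reported
  biomasses. Those expressions are rate ratios imposed at a given $R$
  rather than self-consistent coexistence equilibria — a dimensional
  oddity of the source formulation that is implemented verbatim and
  documented, not silently corrected.
* **Kink handling.** $\phi_s$ has a kink at $R_0$; the analytic Jacobian
  uses the one-sided derivative from the right, and finite-difference
  verification excludes a $10^{-3}$ neighborhood of the kink.
* **Marginal band.** Regimes are classified from the dominant eigenvalue
  real part with a zero tolerance of 0.02, chosen so that a reported
  critical value of 0.01 classifies as marginal; configurable.
* **Integrator.** Classical fixed-step RK4 (step 0.01 time units) via
  `deSolve`; the field is linear in each biomass so exact trajectories
  stay positive, and the integrator clips at a $10^{-12}$ floor with a
  warning if discretization ever crosses it. A structural check exploits
  the model's ratio closure: with $k_h = k_s$, $R(t)$ obeys the autonomous
  equation $\dot R = R[(r_h\phi_h - u_h) - (r_s\phi_s - u_s)]$, and
  trajectories are required to match a separate integration of that
  scalar equation to $10^{-6}$.

**Attainability of the published regime pattern.** The published per-site
eigenvalue real parts (−0.23 … 0.07) could not be derived from the stated
parameters under any straightforward reading — under the default
breakpoints ($R_0 = 0.9$) every site ratio below $R_0$ gives
$J_{11} = r_s - u_s = 0.27 > 0$ and classifies unstable, the opposite of
the published labels. `calibrate_regimes()` therefore treats the regime
*labels* (not the printed magnitudes) as a calibration target: it searches
$\{R_0, R_c, k, b\}$ by coarse grid plus Nelder–Mead on a
misclassification-count objective (hinge distance of the dominant real
part breaks ties) and emits a per-target attainability report, with every
achieved label re-verified by re-evaluating the classifier at the fitted
parameters. The search *does* find parameters reproducing the full
three-class pattern (near $R_0 \approx 0.11$, $R_c \approx 0.92$,
$k \approx 1.2$, $b \approx 6$): there the shrub entry $J_{11}$ stays
mildly positive while the herb entry $J_{22}$ is negative, and the
stabilizing cross-coupling $-J_{12}J_{21} \propto \phi_s R^2
(\partial\phi_h/\partial R)^2$ peaks near the sigmoid midpoint — strong
herb–shrub feedback at low ratios yields stable spirals
($\det J > 0$, $\mathrm{tr}\,J < 0$), and as the feedback fades at high
ratios the determinant changes sign and a saddle appears. The published
magnitudes themselves remain unreproduced, and the package defaults keep
$R_0 = 0.9$, $R_c = 1.4$ (the threshold-identified reading) rather than
adopting the fitted values.

## Problem sizes and numerical tolerances

The shipped configuration runs the whole chain on a desk machine: 26
precipitation events; 9 sites × 9 layers × 3 replicates of soil; 3
replicates per species for 6 species; mixing chains 3 × 20 000 (tests use
shorter, seeded chains); 200 seeded repeats for the meteoric-line
recovery; 50 for the trend statistic; 1 000 random cases for the
Jacobian and eigenvalue oracles (relative tolerances $10^{-5}$ and
$10^{-9}$); ratio-grid resolution 0.001 for threshold location and 0.005
for bifurcation scans. Simplex conservation is enforced to $10^{-9}$ on
every retained draw.

## Limitations

* The generator's single evaporation line makes δ¹⁸O nearly redundant;
  real dual-isotope data are somewhat more informative, so recovery here
  is a lower bound on practice.
* Posterior shrinkage is profile-dependent: flatter (old-stand) profiles
  separate the source layers less and shrink harder toward the prior.
  Site-comparative statistics computed on posterior *estimates* (the
  pipeline's age trend, the site ratio series) are therefore attenuated
  or even inverted relative to the injected truth, while truth-level
  checks recover the designed values. The analysis drivers print both so
  the gap is visible rather than hidden.
* Within-layer and xylem residual SDs are field-plausible defaults, not
  measured values.
* The mixing model omits concentration dependence, trophic
  discrimination (zero by construction for water) and hierarchical
  effects across sites, matching the configuration it mirrors.
* The biomass model is deterministic, two-compartment and spatially
  implicit; its equilibrium expressions are reproduced as printed,
  dimensional oddity included.
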