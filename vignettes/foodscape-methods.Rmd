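---
title: "foodscape: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foodscape: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`foodscape` measures neighbourhood food environments from establishment
registries and relates them to tract demographics. This vignette records
the models, the knobs that matter, what the synthetic generator does and
does not emulate, and the numerical and design decisions a maintainer
would otherwise have to reverse-engineer.

## 1. Outlet taxonomy

Establishments are classified by 6-digit NAICS code into seven food
retail categories plus `NON_FOOD`, then into health tiers: healthy
(supermarkets/grocery, fruit & vegetable markets, supercentres),
intermediate (full-service restaurants), unhealthy (convenience stores,
limited-service restaurants, dollar stores). Two data-hygiene rules fire
before the tier map:

* **Corner-store rule.** Registries code many small corner stores as
  grocery stores. A 445110 record with *fewer than five* employees is
  reclassified as a convenience store. The threshold is strict:
  employees 0–4 reclassify, 5 does not, and the rule uses the record's
  year-specific employee count (registries also carry first-observed
  counts; that variant is not implemented because the year-specific one
  is the only defensible choice for a panel).
* **Dollar-name rule.** 452319 is general merchandise, not a dollar-store
  code. Only records whose name contains the case-insensitive substring
  "dollar" (after whitespace trimming) count as dollar stores; the rest
  are out of scope.

**Dollar-store tier.** The three-tier literature motivates placing dollar
stores with unhealthy outlets (limited fresh produce, calorie-dense
packaged goods), but there is no universal convention. The default is
`UNHEALTHY`; `health_tier(..., dollar_tier = )` and the pipeline config
override it, and the bundled tests pin the default.

## 2. Environment indices

**mRFEI** = 100 · healthy / (healthy + unhealthy) per tract-year, in
[0, 100]. Low values indicate food deserts/swamps, high values food
oases. The denominator *excludes* intermediate outlets by default,
following the CDC-style convention healthy ÷ (healthy + less-healthy);
full-service restaurants therefore never move the score. This is a
genuine design choice (three-tier schemes are sometimes aggregated with
all tiers in the denominator), so `denominator = "all"` is available and
the choice is surfaced in `build_indices_panel()`.

**HHI** = Σ s² over percentage market shares, in (0, 10000]; 10000/k for
k equal firms. Two decisions were open:

* *Share basis*: sales, not outlet counts — HHI is defined on market
  shares and registries carry sales; count-based HHI would collapse to
  10000/k everywhere.
* *Firm definition*: firm = establishment, with no chain roll-up. A
  chain-linkage rule would need ownership data the inputs do not carry;
  under this convention HHI measures local outlet concentration, and
  users with chain identifiers can pre-aggregate sales before calling
  `compute_hhi()`.

Bands follow the antitrust convention: < 1500 competitive, 1500–2500
moderate, ≥ 2500 high. The 2500 boundary goes to HIGH ("2500 or greater
is highly concentrated" is the operative phrasing; the "1500–2500"
phrasing overlaps it).

Tract-years with no in-scope outlet keep a row with mRFEI = HHI = 0, band
`EMPTY` and `no_outlets = TRUE`: the panel stays balanced and the Poisson
estimator consumes the zeros; the flag lets index-only consumers exclude
them.

The USDA food-desert classifier is a background utility: low income
(poverty ≥ 20 % OR median family income ≤ 80 % of the area median) AND
low access (≥ 500 persons AND ≥ 33 % of population beyond one mile from a
supermarket). Its access inputs are taken as given; computing 1-mile
populations from geometry is out of scope.

## 3. Gi* hot-spot analysis

For tract i with self-inclusive weights (w_ii = 1, binary):

z_i = [Σ_j w_ij x_j − X̄ W_i] / (S · sqrt((n Σ_j w_ij² − W_i²)/(n−1))),

with X̄ the global mean and S the global root mean squared deviation.
Bins use two-sided normal critical values fixed to six decimals
(1.644854 / 1.959964 / 2.575829) for bit-stable 90/95/99 % binning. No
multiple-testing correction is applied by default — raw confidence bins
are the field's reporting convention — but `hotspot_panel(fdr = TRUE)`
switches to Benjamini-Hochberg-adjusted bins for sensitivity analysis.

*Weights.* Queen contiguity (default) links polygons sharing at least one
boundary vertex after rounding coordinates to 1e-8. This is exact for the
bundled lattice worlds and for boundary files whose shared borders share
vertices — the typical case for census products — but is an
approximation to true shared-boundary-point queen contiguity, which
needs a geometry engine. A fixed distance band on centroids is also
provided; its default band is the smallest distance leaving no tract
isolated. Isolates produce a recorded warning, single-tract inputs an
error (the statistic is undefined).

*Numerical choices.* S is computed in centred form (the textbook
"Σx²/n − X̄²" cancels catastrophically on near-constant fields). An
exactly constant field errors ("degenerate field"); a field constant up
to floating-point noise (S below 1e-10 of the field scale) returns all
zeros rather than standardising rounding error into spurious clusters —
Gi* is scale-invariant, so without this tie-break machine noise would
produce ordinary-looking z-scores.

*HHI hot spots* are supported but typically uninformative when many
tract-years have zero or missing-market HHI; mRFEI is the intended field.

`compare_years()` labels first-to-last-year transitions (stable-hot,
cold→hot, emerging-cold, …; anything ending at bin 0 is "none") and
tallies hot/cold tract counts per year.

## 4. Two-way fixed-effects PPML

The conditional mean is E[Y_it] = exp(X_it'β + C_it'γ + α_i + γ_t) with
tract effects α_i and year effects γ_t. mRFEI and HHI are continuous
non-negative outcomes; the Poisson *pseudo*-likelihood requires only
y ≥ 0 and a correctly specified mean, which is why it is the standard
estimator for non-negative outcomes with many zeros. Race/ethnicity
regressors enter as percentages (0–100), so coefficients are
semi-elasticities per percentage point.

**Dropping.** Before estimation, the panel is reduced to a fixed point
by iteratively removing (a) singletons — observations alone in a tract
or year group, which contribute no identifying variation — and (b)
separated groups — tract or year groups whose outcome is all zero, whose
log-link intercept diverges to −∞. Counts of both are reported in the
fit. A post-fit check additionally counts observations with fitted means
below 1e-12; full linear-programming separation detection is out of
scope and documented as such.

**Algorithm.** IRLS with the working response z = η + (y−μ)/μ and
weights μ; both fixed-effect dimensions are absorbed from z and the
regressors by weighted alternating projections, iterated until the
largest within-sweep adjustment falls below 1e-10; β then comes from
weighted least squares on the demeaned system, and the
Frisch–Waugh–Lovell identity recovers η without materialising dummies.
Outer convergence: relative deviance change < 1e-9, max 200 iterations —
chosen for bit-stable tests, not speed. Collinear regressors are detected
once by pivoted QR on the weighted demeaned design and dropped with a
warning (the generator's linked poverty/race attributes make this a real
case, not a corner case).

*Step-halving.* Deviance is forced non-increasing from the second
iteration onward, halving the step up to 30 times. The first iteration
is exempt: the IRLS start μ = (y + ȳ)/2 is near-saturated, so its
deviance lies *below* that of any model with covariate structure, and a
monotonicity requirement there deadlocks the fit (this bit the
HHI-outcome models in development). Non-finite deviance is halved at any
iteration.

**Inference.** Cluster-robust sandwich at the tract level: bread from the
absorbed (demeaned, weighted) regressors, meat from cluster-summed scores
(y−μ)·x̃, small-sample factor G/(G−1). With one observation per cluster
this reduces to HC standard errors. No further degrees-of-freedom
correction is applied. Pseudo-R² is reported as the squared correlation
of y and μ̂ — the "R²" of a PPML fit has no canonical definition, and
this one is cheap, bounded and monotone in fit quality.

`run_model_suite()` fits the study grid: {mrfei, hhi} × {race
(White/Black/Asian), Hispanic} × {all, metro, non-metro} — Hispanic is a
separate model because it is an ethnicity axis measured independently of
the race split — plus SVI robustness fits ({overall}, {four sub-themes})
per outcome on the full sample: sixteen fits, returned as a tidy
coefficient table with per-model drop bookkeeping.

## 5. The synthetic world

The generator emulates the *shape* of the real inputs — a NETS-like
establishment registry, a Census/ACS-like attribute panel, tract
polygons — with known ground truth. Defaults describe a stylised 2000 -
2019 US tract panel:

* **Lattice.** n×m unit squares with GEOID-style ids; real GeoJSON is
  accepted by the same readers everywhere.
* **Race/ethnicity.** Tract-level Dirichlet(8, 1.5, 0.8, 0.7) shares for
  (White, Black, Asian, other) in percent; Hispanic independent
  Beta(2, 6)·100. Each share gets a tract-specific *linear* drift
  (slopes N(0, 0.3/0.15/0.1/0.2) pp/year, jointly rescaled so no
  trajectory leaves its bounds — clipping the slope, not the path, keeps
  trajectories exactly linear, which the tests exploit). The drift is
  what identifies race coefficients within tract once fixed effects
  absorb the levels.
* **Controls.** Population lognormal (median ≈ 4000) with tract-specific
  growth; % bachelor Beta-distributed with a mild upward drift; poverty
  linked linearly to minority share plus tract noise *and* tract-year
  noise with sd 1.5 pp — without the latter, poverty is perfectly
  collinear with `pct_white` after tract demeaning and every fit drops
  it.
* **SVI.** Within-year rank-normalised transforms of poverty/minority
  attributes, so the assumed correlation structure (higher minority
  share ⇒ higher minority-status-and-language sub-theme) holds by
  construction; scores are uniform on [0, 1] by design.
* **Outlets.** Per tract-year and category, counts are Poisson with
  log-mean log(base) + Σ β·attribute + tract effect (sd 0.25) + year
  effect (sd 0.1). Default base rates (supermarket 1.2, fruit & veg 0.4,
  supercentre 0.2, convenience 2.2, dollar 0.6, full-service 2.0,
  limited-service 2.6, non-food 3.0 per tract-year) give ≈ 9 in-scope
  outlets per tract-year and a mean mRFEI near 20 % — between the CDC's
  national mRFEI (~10 %) and the study-period national means (~26 %),
  i.e. a realistic density, chosen once and not revisited.
* **β scope.** The spec-level description puts the planted coefficients
  on "outlet intensity"; applied to *every* category they would cancel
  out of mRFEI (numerator and denominator scale together) and be
  unrecoverable from any healthiness measure. `beta_scope = "healthy"`
  (default) applies them to healthy-tier categories only, so a negative
  Asian coefficient produces a genuinely unhealthier environment in
  Asian-share tracts and the healthy-outlet count is a clean Poisson
  recovery target; `"all"` remains available.
* **Rule coverage.** Grocery employee counts are bimodal (a
  `small_grocery_prob = 0.3` mass on 0–4 employees vs a ≥ 20 mode) so the
  corner-store rule bites on a known expected fraction;
  `nondollar_name_frac = 0.25` of 452319 records get non-dollar names.
  Sales are lognormal with category medians and sdlog 0.8 — heavy tails
  keep HHI variation non-degenerate.
* **Planted cluster.** Optionally, healthy-category intensity is
  multiplied inside a Euclidean cell radius of a centre tract.
* **Seeds.** One root seed; per-table child seeds derived
  deterministically (stable under partial regeneration); byte-identical
  outputs under identical configs, verified by hashing in the tests.

**What it does not emulate** — and hence what a green test does *not*
establish: establishment relocation/survivorship dynamics, sales
imputation conventions of commercial registries, within-store product
range, chain ownership, realistic tract geometry, or spatially
autocorrelated demographics. The generator validates the *machinery*
(classification, aggregation, detection, estimation, inference), not the
substantive national findings, which require the proprietary inputs.

## 6. Acceptance-test interpretations

Three places needed an interpretation, decided once:

* **Coverage criterion.** "β̂ within 2 clustered SEs of the truth in
  ≥ 90 % of 50 replicates" is evaluated per coefficient. The joint
  all-coefficients event has nominal probability ≈ 0.9545³ ≈ 0.87 for a
  perfectly calibrated estimator of three coefficients, so the joint
  reading is unattainable by construction; componentwise coverage is the
  standard check.
* **Planted-cluster criterion.** The detection test feeds Gi* the
  *period-mean* mRFEI surface of the default 20-year world. A single
  year's mRFEI over ~9-outlet tracts is noise-limited (centre z ≈ 3.5 ±
  0.9, so bin +3 in only ~⅔ of seeds); the persistent planted cluster is
  the target, and the period mean is its natural summary (centre z ≈ 11).
  Per-year analysis remains the default pipeline behaviour.
* **Sign-recovery example.** The model-suite test plants
  β_asian = −0.05 (not the default −0.006) so the effect is identifiable
  from within-tract drift at the 400-tract test scale; the test asserts
  the recovered *sign*, which is the example's claim.

## 7. Known limitations

* Queen contiguity is vertex-based (see §3); pathological boundary files
  with non-shared vertices on shared borders under-link.
* Gi* inference uses the normal approximation only (as in the standard
  GIS tooling); conditional permutation inference is not implemented.
* Separation detection is the all-zero-group rule plus a fitted-mean
  check; exotic separation patterns through regressors are not caught.
* HHI treats each establishment as a firm; chain concentration is
  understated.
* The CLI is a thin file-to-file wrapper; very large registries are
  bounded by `data.table` memory, not streaming.
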