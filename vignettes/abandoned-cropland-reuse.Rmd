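---
title: "Methods: detecting abandoned cropland and modelling its reuse potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting abandoned cropland and modelling its reuse potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallowland)
```

`fallowland` implements a complete analysis chain around abandoned
cropland: detect abandonment in annual land-cover class series, model
where abandoned land could be returned to production (recultivation)
or restored to forest by natural regrowth (reforestation), convert
those suitabilities into food-production and net climate-mitigation
potentials, and allocate land under trade-off scenarios. This vignette
is the package's account of the underlying science: the decision
rules, the models and their assumptions, the parameters that matter,
and the choices made where the design was genuinely open.

## Abandonment detection

The unit of analysis is a pixel with one land-cover class code per
year (nominally 300 m, 9 ha). All cropland classes in the codebook are
merged into a single cropland layer before any rule is applied.

**Temporal filter.** Annual class products carry single-year
misclassifications, so a moving-window filter is applied first: for
each pixel-year, if the class differs from the modal class of the
centered five-year window and that mode holds a strict majority
(&ge; 3 of 5 years), the year is reassigned to the mode. Window ends
are padded by edge replication. This removes exactly the isolated
single-year flips while leaving any run at least as long as the
majority count intact. One-sentence descriptions of such filters are
ambiguous between modal replacement, run-length erasure and
forward-fill; we implement centered modal replacement because it is
the variant that targets single-year errors and nothing else, and we
verify it in the tests against an independent brute-force windowed-mode
oracle.

**Decision rules.** A pixel is *abandoned* when

1. it is historically stable cropland — cropland in every year of
   1992–1997 inclusive;
2. it later converts to non-cropland and the first qualifying
   non-cropland run lasts at least `min_fallow_years` (default 5, the
   FAO threshold) **and persists to the end of the record**;
3. the destination is not an excluded conversion class (built-up,
   wetland) — and, by a deliberately strict reading, an excluded class
   appearing in *any* later year also excludes the pixel as a
   conversion (`converted_excluded`), since urbanized land should
   never be counted as reusable;
4. it never returns to cropland: a qualifying fallow run followed by
   at least one cropland year makes the pixel
   `recultivated_excluded` — excluded from the abandoned pool, but the
   training presence for the suitability model below.

Runs shorter than `min_fallow_years` that return to cropland are
*short-term fallow*: they are skipped, not classified, and scanning
continues. Pixels that were never (or never stably) cropland are
`never_cropland`; everything else that is stably cropland —
including too-recent conversions that cannot satisfy the five-year
rule within the record — remains `stable_cropland`.

One caveat follows from the skip-and-continue semantics: on a pixel
with several interleaved fallow episodes, raising `min_fallow_years`
can disqualify an early recultivated run and thereby *expose* a later
qualifying run, so the abandoned count is not globally monotone in the
threshold. On single-episode trajectories — which is what the
synthetic generator produces and what dominates real landscapes — the
count is monotone, and the property suite tests it there.

## Recultivation suitability

The real-world analogue trains a maximum-entropy model on nine driver
layers and historically recultivated pixels. Here that stage is a
regularized logistic presence–background model: covariates are
standardized over the study region; the presences are the
`recultivated_excluded` pixels; the background is a uniform draw
(default 10,000, excluding presences); and a ridge-penalized logistic
fit (`lambda = 1e-4`, enough to resolve collinear drivers without
biasing well-conditioned fits) provides the propensity. The interface
also accepts any precomputed recultivatability grid, so output from an
external suitability model can be dropped in unchanged.

Presence–background intercepts are not identified at the landscape
scale — they encode the sampling ratio, so the raw logistic output
sits near the training prevalence. For thresholding we therefore use
the conventional default-prevalence calibration of maximum-entropy
outputs: `predict(model, stack, tau = 0.5)` centers the linear
predictor over the region and anchors a pixel with average drivers at
0.5. The *recultivatable* set is then `recultivability > 0.2`
(strictly greater; a pixel at exactly 0.2 is excluded) **and** outside
protected areas. The published cut does not state which output scale
it applies to; the calibrated logistic output is our documented
choice.

Reforestation suitability is simpler: a pixel qualifies when its
potential natural vegetation is forest or woodland. The protected-area
mask does not restrict reforestation — natural regrowth inside
protected areas is desirable, not excluded. Crossing the two booleans
on abandoned pixels gives the four-way typology `recult_only` /
`reforest_only` / `both` / `neither`.

## Potentials

**Food.** Per-pixel consumer-level calorie productivity is the
harvest-share-weighted mean of per-crop calorie yields, discounted for
supply-chain loss and consumer waste:

$$\mathrm{productivity}_i \;=\; \sum_j \mathrm{yield}_j \,
  \frac{\mathrm{harvested\_area}_{i,j}}{\sum_j \mathrm{harvested\_area}_{i,j}}
  \,(1 - \mathrm{loss}_i)\,(1 - \mathrm{waste}),$$

with yields in kcal yr⁻¹ ha⁻¹ (dry-weight calorie basis), a per-pixel
loss fraction, and a uniform waste fraction of 0.17. Pixels without
crop data contribute zero. Selections aggregate to Pcal yr⁻¹
(10¹² kcal).

**Climate.** Reforested pixels earn the total (above- plus
belowground) sequestration rate, in MgCO₂ yr⁻¹ ha⁻¹. Recultivated
pixels pay a clearing debit: the aboveground biomass carbon
accumulated since abandonment is assumed immediately oxidized.
On pixels whose final-year cover is a regenerating class the
accumulated carbon is the aboveground accumulation rate times years
since abandonment (no stock ceiling is applied — regrowth this young
sits well below old-growth stocks, and any cap would be an extra
assumption); on grass/shrub/bareland it is the standing biomass-carbon
stock. Carbon converts to CO₂ by the stoichiometric 44/12. For
annualized accounting the one-time emission is amortized over a
30-year horizon; the one-time figure is kept alongside. The asymmetry
is intentional and follows the accounting convention of the analysis
this package implements: the sequestration *credit* includes both
compartments, the clearing *debit* is aboveground only.

**Levers.** Four documented improvement approaches enter as
parameterized multipliers: an irrigation factor on yields; a
yield-gap-closure fraction moving yields toward configured attainable
yields (never downward); a scaling of both loss and waste (0.5 =
halving); and an active-reforestation factor on the sequestration
rate, applied outside protected areas only.

## Allocation scenarios

Each abandoned pixel gets at most one purpose. The representative
scenarios all use every suitable pixel; they differ only in how the
both-suitable pool is split. With per-pixel normalized contributions
$a_i = \mathrm{productivity}_i / F_{\mathrm{tot}}$ (food) and
$b_i = (\mathrm{seq}_i + \mathrm{clear\_rate}_i) / C_{\mathrm{tot}}$
(sequestration forgone plus clearing debit), the combined potential
$A + B$ is additive over pixels, so recultivating a both-suitable
pixel iff $a_i > b_i$ is *exactly* optimal among all-in allocations —
this is the `max_combined` rule, and the test suite confirms it
against exhaustive enumeration on small landscapes. The
`equal_allocation` split uses the same comparative-advantage ranking
and assigns pixels to recultivation until the two purposes hold equal
area (to within one pixel); the published description fixes only the
areas, so the ranking is our recorded choice.

The normalizing maxima are deliberately asymmetric: $F_{max}$ is the
food potential with every recultivation-suitable pixel recultivated,
while $C_{max}$ is the *gross* sequestration with every
reforestation-suitable pixel reforested and no clearing debit. Because
the debit is excluded from the maximum, even the climate-maximizing
scenario lands just below 100% once it recultivates the
recultivation-only pixels.

**Prioritization sweeps.** For a fraction $f$ of the total abandoned
area, pixels are selected for one purpose either in descending order
of the purpose-relevant per-hectare rate (productivity, or gross
sequestration rate for reforestation, which incurs no clearing), with
ties broken by row-major pixel index for reproducibility, or uniformly
at random under a seed. Fractions are of the total abandoned area, so
large fractions can exhaust a suitable pool; the pool is then used in
full and the shortfall flagged. The benefit table reports the
percentage uplift of prioritized over randomized selection and the
area a randomized strategy would need to match the prioritized output
(interpolated along the randomized sweep).

## Accuracy assessment

Validation uses disproportionate stratified sampling — equal counts
per map class — which is the appropriate design for rare classes like
abandoned cropland. With stratum weights $W_i$ (map-class area
proportions) and sample counts $n_{ij}$, the estimated confusion
proportions are $\hat p_{ij} = W_i\, n_{ij}/n_i$; overall, user's and
producer's accuracy and the class F1 (exactly the harmonic mean of UA
and PA) follow from that matrix. The error-adjusted area of class $j$
is $\hat A_j = A_{\mathrm{tot}} \sum_i W_i\, n_{ij}/n_i$ with standard
error

$$\mathrm{SE}(\hat p_{\cdot j}) = \sqrt{\textstyle\sum_i W_i^2\,
  \frac{(n_{ij}/n_i)(1 - n_{ij}/n_i)}{n_i - 1}},$$

and a normal-approximation 95% interval ($1.96\,\mathrm{SE}$).
Estimated class areas always sum to the total map area. No
finite-population correction is applied — validation samples are a
negligible fraction of any real map — and the acceptance suite checks
that the interval attains 95% ± 3 points empirical coverage over 500
stratified draws on a synthetic map with known truth. In synthetic
mode the reference labels come from the generator's noise-free truth,
standing in for visual interpretation of imagery.

## The synthetic generator: what it emulates, and what it does not

All inputs can be simulated on a shared grid so the full chain runs
and is tested without any download:

* **Land-cover series.** Pixels are never-cropland, stable cropland,
  abandoned at a uniformly drawn year (destination drawn with the
  regrowth/grass/shrub/bare mix 65/14/10/11), abandoned-then-
  recultivated, or converted to an excluded class; i.i.d. single-year
  flips add classification noise. Defaults mirror the study-scale
  record: abandonment hits 8% of stable cropland, about 3% of
  abandoned pixels are later recultivated, and the noise rate is 2%.
  The generator emits its own event table, which is the exact oracle
  for the detector (and is recovered exactly at zero noise).
* **Environment stack.** All continuous surfaces are
  Gaussian-smoothed noise fields — no parametric geostatistical model
  is claimed — with a configurable linear gradient; productivity and
  sequestration gradients point in opposite directions by default so
  that prioritization involves a real trade-off. The sequestration
  rate averages 11.5 MgCO₂ yr⁻¹ ha⁻¹ (the reported global mean on
  suitable abandoned cropland) with the aboveground share at 76% of
  the carbon; food waste is 0.17; potential natural vegetation is
  forest/woodland on 80% of the landscape; protected areas cover 18%
  (the share implied by 68 of 83 Mha of reforest-suitable land lying
  outside them). Suitability covariates are built from a latent
  recultivation-propensity field with configured correlation (default
  0.6, enforced exactly in-sample by orthogonalizing the noise
  component), and the same latent field tilts which abandoned pixels
  get recultivated (log-odds slope 3, giving the suitability fit a
  clear but imperfect signal, AUC ≈ 0.85).

Equal-area pixels (9 ha) are used throughout synthetic mode;
latitude-dependent pixel areas are a property of real georeferenced
grids and would only obscure the correctness tests.

What the generator does *not* emulate: spatially or temporally
correlated classification error (real products confuse specific class
pairs and whole regions), mixed pixels, the 1990s reliability dip,
gaps or cloud artifacts, and any real geography of yields or carbon.
Passing tests therefore demonstrate that the *rules and estimators*
are implemented correctly and behave as theory predicts — not that the
pipeline would reproduce real-world magnitudes, which depend on the
real input grids.

## Problem sizes and numerical choices

The bundled analysis scripts (`analysis/01…06`) run the chain on a
120 × 120 grid (14,400 pixels) — our chosen desk-scale study size,
large enough that the rare recultivated class still yields a few
hundred training presences. At that extent the historical
recultivation share is raised (`p_recult = 0.15`, as is the demo
pipeline's default) precisely because 3% of a few hundred events
would leave the suitability stage without a trainable presence set;
the generator's own default keeps the study-scale rate. The test suite
uses 10,000-pixel grids for the exact-recovery checks, 2¹² -sized
enumerations for allocation optimality, 20 seeds for the dominance
property, n = 5,000 for coefficient recovery (signs recovered,
magnitudes within 25%), and 500 stratified draws for interval
coverage.

Numerical conventions, fixed once: strict `>` at the 0.2 suitability
cut; prioritization ties broken by row-major index after a stable
sort; percentages displayed rounded half-away-from-zero to integers
(raw floats are kept in the CSV outputs); MgC→MgCO₂ by 44/12; Pcal =
10¹² kcal, Mt = 10⁶ Mg; and every random draw flows from an explicit
integer seed (the grid seed for data, function arguments for sampling
stages), with internal RNG use isolated so library calls never disturb
the caller's stream.

## A short worked run

```{r demo, eval = FALSE}
cfg <- run_config(grid = list(n_rows = 96, n_cols = 96, seed = 42),
                  out_dir = tempfile("fallowland_"))
res <- run_pipeline(cfg)
res$scenario_outcomes
render_scenario_table(res$scenario_outcomes)
res$accuracy
res$benefit
```

## Known limitations

* The surrogate suitability model is linear in the covariates; it has
  no hinge/product features and no tuning study, so it stands in for
  the modelling *stage*, not for any particular fitted model.
* Clearing accounting ignores soil organic carbon (reported negligible
  or negative for regrowth), crop life-cycle emissions, and biomass
  energy recovery.
* The combined-potential optimality proof covers allocations that use
  all suitable pixels; partial-use optimality is only addressed by the
  greedy prioritization sweeps.
* Abandoned-pasture dynamics, sub-pixel fractions, and people-fed
  conversions are out of scope.
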