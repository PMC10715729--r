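---
title: "Methods: brumation duration and tissue allocation across anurans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brumation duration and tissue allocation across anurans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`brumate` implements a comparative workflow for asking how the length of
winter dormancy (brumation) in ectotherms relates to how males allocate
resources among expensive tissues — brain, body fat, testes, hindlimb
muscles — across a phylogeny of frog and toad species. This vignette
explains the models, their assumptions, the tunable parameters, and the
numerical choices, in the order the pipeline applies them.

## Estimating brumation from temperature series

Anurans stop activity when ambient temperature falls below a
species-specific threshold, so dormancy duration can be estimated by
combining daily mean temperatures at a collection site with experimentally
determined activity thresholds. `annual_brumation_days()` applies a simple
run rule per calendar year: the **active period** opens on the first day of
the first run of at least `persistence` (default 5) consecutive days with
mean temperature strictly above the emergence threshold, and closes on the
last day before the terminal run of at-or-below-threshold days that lasts
to 31 December. Brumation days are the days of the year outside the active
period; a year with no qualifying warm run is scored as fully dormant.

Conventions worth knowing:

* A day exactly at the threshold counts as *inactive*. The rule is
  configurable (`above_strict`), but equality is genuinely ambiguous in the
  underlying field definition and the inactive reading is the conservative
  one.
* Entry and emergence thresholds may differ; emergence opens the active
  period, entry closes it, and the entry threshold defaults to the
  emergence value when only one is measured.
* A mid-year warm spell after the terminal cold run cannot re-open the
  active period; the rule is first-run/terminal-run by construction. For
  strongly seasonal sites this matches intuition; for marginal climates it
  makes the estimate conservative (longer brumation).
* `buffer` (0, 2 or 4 °C) subtracts a constant from both thresholds to
  emulate the thermal shelter of underground burrows relative to air
  temperature.
* Species whose mean estimate is ≤ 27 days are classified non-brumating
  (`classify_brumation()`): short cold snaps are tolerated without
  sustained dormancy and ground microclimates buffer air temperature.

Year-to-year consistency of the estimates is summarised by
`repeatability()`, a Gaussian one-way random-effects intraclass
correlation, `R = σ²_between / (σ²_between + σ²_within)`, with REML
variance components and a parametric-bootstrap percentile CI.

Climate context uses two summaries: the coefficient of variation of
monthly mean temperatures (`climate_cv()`, log-transformed when it enters
regressions) and the dry-season length `dry_season_p2t()`, the number of
months whose precipitation (mm) is below twice the mean temperature (°C).

## The phylogenetic regression engine

All regressions assume the residuals of species values are correlated in
proportion to shared evolutionary history. `phylo_covariance()` builds the
Brownian-motion covariance (shared root-to-tip path lengths);
`apply_lambda()` scales its off-diagonals by Pagel's λ ∈ [0, 1], spanning
a star phylogeny (λ = 0, independent species) to full Brownian structure
(λ = 1). `gls_fit()` solves the generalized least-squares problem through
a Cholesky factorisation — never an explicit inverse, for stability with
near-singular ultrametric covariances — and reports the ML residual rate
(σ̂² = RSS/n) and log-likelihood; ML rather than REML is used throughout
because the λ profile and every downstream information-theoretic
comparison require likelihoods on a common footing.

`fit_pgls()` profiles λ by maximum likelihood on a 21-point grid refined
by bounded golden-section search, which reliably lands boundary estimates
(λ̂ = 0 or 1) when the data call for them. Uncertainty is quantified by a
**parametric bootstrap** (default 100 replicates, seeded): responses are
simulated from the fitted model and the entire fit, λ included, is
repeated, giving percentile intervals for the standardized coefficients
and λ̂. Percentile rather than normal-approximation intervals were chosen
because λ̂ is boundary-constrained. Standardization z-scores the response
and predictors by their plain sample SDs, matching common standardized-
coefficient reporting. Effect sizes use the standard conversion
`r = t / √(t² + df)` with df = n − p − 1 (intercept included in p + 1).

Allometry (`fit_allometry()`) regresses log tissue mass on log cubed
snout-vent length, so isometry (mass ∝ length³) is slope 1; a slope is
called steeper/shallower only when its bootstrap 95% CI excludes 1 (with a
1e-8 numerical guard so exact isometry is reported as proportionate).
Ordinary GLS rather than reduced major-axis regression is used: RMA's
sensitivity to scatter rather than slope makes it a poor allometry
estimator here.

`fit_phylo_logistic()` handles binary responses (e.g. breeding
aggregations). Residual correlation among tips is the Ornstein–Uhlenbeck
correlation implied by the tree at rate α (per unit mean tree height):
small α approaches Brownian correlation, large α approaches independence,
and a star phylogeny is exactly independent for every α, where the fit
reduces to ordinary logistic IRLS. β̂ comes from GEE-type iteratively
reweighted GLS; α̂ maximizes a REML-flavoured working likelihood on a log
grid from 0.05 to 50. Complete or quasi-complete separation is detected
and handled by a Firth-type penalized refit, flagged in the result.

## Partial correlations and the compositional analysis

`phylo_trait_vcv()` estimates the evolutionary trait covariance by GLS
about the phylogenetic mean, `R = (X − 1â′)′ C⁻¹ (X − 1â′)/(n − 1)`,
with λ = 1 by default (Brownian motion). `all_pairwise_partials()` scales
it to a correlation matrix and applies the first-order partial correlation
`r_xy·z = (r_xy − r_xz r_yz)/√((1 − r_xz²)(1 − r_yz²))` controlling for
body size, with t tests on df = n − 3 and Fisher-z confidence intervals
(the noncentral-t alternative gives near-identical intervals at these n).

Because tissue masses compete for one body, allocation is also analysed as
an **Aitchison composition**: brain, fat, testes, hindlimb muscle and the
remaining mass (total body mass minus the four tissues) closed to
proportions. `clr()` gives centered log ratios (part-wise interpretable,
sum to zero); `ilr()` maps the 5-part composition isometrically to 4
unconstrained coordinates using a fixed Helmert-type balance basis. The
basis choice does not matter for any reported quantity: distances are
preserved and back-transformed coefficients are basis-independent.

`fit_mv_pgls()` fits the multivariate phylogenetic regression of the ilr
coordinates on brumation duration under a single profiled λ, computes
Pillai's trace from the hypothesis and error cross-products of the
phylogeny-whitened data, and obtains its p-value by permuting the whitened
residuals of the intercept-only model (default 999 permutations, seeded;
an F approximation is also reported). The effect size ξ² is defined here
as the permutation-corrected Pillai trace,
`ξ² = (V − mean(V_perm)) / (1 − mean(V_perm))` — the observed association
rescaled against its chance expectation; this is an interpretation, since
no closed-form definition is standard. The predictor's coefficient vector
is mapped back to the simplex with `ilr_inv()`: with no effect every part
receives 1/D = 0.20, so parts above/below 0.20 gain/lose allocation as
brumation lengthens. Zero parts are an error rather than silently imputed;
zero-replacement strategies are out of scope.

## Phylogenetic PCA and confirmatory path analysis

`fit_ppca()` eigendecomposes the evolutionary covariance (default) or
correlation of the log tissue masses, with scores taken about the GLS
phylogenetic mean (not the arithmetic mean). Covariance mode on log traits
under Brownian motion is the default because the analysis targets relative
allocation among jointly measured masses; loadings are sign-fixed so each
column's largest-magnitude entry is positive.

`path_model()`/`fit_path_model()` implement d-separation confirmatory path
analysis. Each candidate DAG implies one conditional-independence claim
per non-adjacent node pair — x ⊥ y given the union of both parents' sets —
tested by the PGLS t-test of x in the regression of the topologically
later variable on x plus the conditioning set. Claims combine into
Fisher's `C = −2Σ ln pᵢ` (χ², df = 2k), and models are ranked by
`CICc = C + 2qn/(n − 1 − q)`. The parameter count q is the number of edges
plus one free covariance per unordered pair of exogenous (parentless)
nodes; this convention is stated because no universal formula exists.
Body size enters every claim and edge regression as a covariate rather
than as a node subject to claims. Models within ΔCICc ≤ 2 of the best are
averaged; averaging is conditional (an edge is averaged over retained
models that contain it), with a CICc-weighted variant available. Two
candidate sets ship as editable plain-text configs: an 8-model climate set
(latitude → brumation → breeding season → aggregation variants) and a
28-model tissue set that reconstructs the published model families
(direct vs digestive-tract- and/or fat-mediated brumation effects, both
brain–testes directions); the tissue set is a labelled reconstruction, not
the original enumeration. Binary nodes (aggregation) are currently tested
with Gaussian PGLS, a known approximation.

## Directional tests of correlated evolution

For two binary traits (relatively large testes — the sign of the
phylogenetic log–log residual on SVL — and short breeding seasons — below
the mean duration), `fit_directional()` fits four continuous-time Markov
models over the joint states 00/01/10/11 with all rates different and dual
transitions forbidden: independent (4 rates), each unilateral dependence
(6), and mutual dependence (8). Likelihoods come from Felsenstein pruning
with per-branch matrix exponentials (scaling-and-squaring with a Padé
approximant, with an eigendecomposition fast path), flat root frequencies
by default (a stationary-distribution option exists), and bounded L-BFGS
optimization of log rates with seeded restarts; richer models are
additionally started from the optimum of the nested model, which keeps the
fitted log-likelihoods weakly ordered along the nesting. Models are
compared by AIC and Akaike weights.

A power caveat documented by our own simulations: dependence versus
independence is detected decisively (ΔAIC of tens at 150–300 tips under
strong rates), but *which* trait depends on the other — and mutual versus
unilateral dependence in particular — is weakly identified; the mutual
model's likelihood advantage over the best unilateral model rarely exceeds
its two-parameter AIC penalty at these sample sizes. Conclusions about
directionality should therefore lean on the decisive contrasts.

## The synthetic-data generator

`simulate_study()` generates every input the pipeline consumes, at the
study design's scale and nesting: 116 species on a pure-birth tree, 50
with paired pre-brumation masses, 43 with breeding metadata, 30 flagged as
field-validated for thresholds, daily temperatures 2012–2016 at sites
along a latitude/elevation gradient, and monthly climate normals. Within
it:

* Log SVL evolves as Brownian motion; each log tissue mass is
  `intercept + slope · log(SVL³)` plus a deviation mixing a Brownian and
  an independent component as `√λ·BM + √(1−λ)·iid` (exact on the
  ultrametric simulated trees). Default slopes encode the allometric
  structure of anuran tissue data — shallow brain scaling (0.49), steeper
  fat (1.10) and limb muscle (1.03), near-isometry elsewhere — with mild
  negative brain–fat, brain–testes and testes–muscle residual
  correlations.
* Daily temperature is a sinusoid (coldest at the turn of the year) plus
  AR(1) noise with coefficient 0.7: autocorrelated cold spells exercise
  the 5-day persistence rule the way weather does, unlike white noise.
  Site annual means are floored at 2 °C so the temperature CV (and its
  log) remains well-defined — the emulated sites are subtropical/montane
  with positive annual means.
* Binary trait pairs are simulated from the exact 4-state generator of the
  chosen Pagel model, root state drawn uniformly.

What the generator does **not** emulate: measurement error within species
(species means are taken as exact), sampling covariance between pre- and
post-brumation individuals, non-ultrametric trees, climate trends across
years, and any attempt to match the real deposited values. Passing tests
therefore demonstrate statistical correctness of the machinery under the
assumed generating processes, not agreement with the original data.

## Problem sizes and numerical choices

The shipped tests and examples run the estimators at deliberately chosen
sizes: oracle equivalences on ≥50 random instances each; λ and slope
recovery at 116–150 species with 40–50 bootstrap replicates; evolutionary
correlation at 300 species; MANOVA calibration with 200 null repeats of
199 permutations at 50 species; logistic calibration with 200 repeats at
64 species; directional tests at 150 tips. These sizes give stable
pass/fail behaviour for the properties being checked while keeping a full
run comfortably interactive. Other numerical conventions: covariances are
Cholesky-factorised with a 1e-10 ridge only inside the logistic working
covariance; p-values of exactly 0 entering Fisher's C are clamped to
1e-300 with a warning; permutation p-values use the add-one estimator
`(1 + #{V* ≥ V}) / (n_perm + 1)`; optimizer rate bounds are
[1e-8, 1e3] on the natural scale with non-finite objectives capped.

## Running the whole pipeline

```{r, eval = FALSE}
library(brumate)
study <- simulate_study(seed = 1)         # or read your own files
cfg <- pipeline_config(study = study, out_dir = "results", seed = 1)
res <- run_all(cfg)
```

The output directory receives one CSV per analysis plus `report.txt`
recording the sample size used at each stage. If a directory with an
externally obtained reference dataset is supplied via `benchmark_dir`,
headline statistics (brain allometric slope, PC1 variance share) are
recomputed on it for side-by-side display; otherwise that stage reports a
notice and is skipped — the reference deposit is never downloaded
automatically.

## Known limitations

* Phylogenetic logistic regression estimates α on a fixed grid and reports
  Wald z tests; no bootstrap is wired into it.
* Path-analysis claims on binary endpoints use Gaussian PGLS.
* The compositional MANOVA supports a single predictor (matching the
  analysis it implements) and no zero-replacement.
* The pPCA offers BM/λ-fixed structure but no λ-optimized variant.
* Directionality conclusions from `fit_directional()` face the power
  limits described above.
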