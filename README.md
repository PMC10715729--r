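# brumate

Phylogenetic comparative analysis of brumation (ectotherm winter dormancy)
and tissue allocation in anurans.

Frogs and toads stop activity when ambient temperature drops below a
species-specific threshold, and species differ enormously in how long that
dormancy lasts. Because a male's brain, body fat, testes and limb muscles
all draw on the same finite resources — and because a long dormancy
compresses the breeding season that follows it — brumation duration is a
natural axis along which to study resource-allocation trade-offs and their
consequences for brain and reproductive evolution. `brumate` packages the
full analysis chain for that question, for comparative biologists working
with species-level trait tables and a dated (or relative-time) phylogeny:

* **Dormancy estimation** — annual brumation days from daily mean
  temperature series and activity thresholds (5-day persistence rule,
  optional 2/4 °C burrow buffers, ≤27-day non-brumating classification),
  with repeatability (ICC) of the per-year estimates.
* **PGLS** with maximum-likelihood Pagel's λ: the residual covariance is
  V(λ), the Brownian shared-path-length matrix with off-diagonals scaled
  by λ ∈ [0,1]; coefficients solve the GLS normal equations via Cholesky,
  and standardized coefficients and λ̂ get percentile CIs from a seeded
  parametric bootstrap. Effect sizes via r = t/√(t² + df).
* **Allometry** against cubed snout–vent length (slope 1 = isometry),
  classified by whether the bootstrap CI excludes 1.
* **Phylogenetic logistic regression** (OU-correlation α, GEE/IRLS fit,
  Firth fallback under separation) for binary outcomes such as breeding
  aggregations.
* **Partial correlations** between tissues controlling for body size and
  phylogeny: r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²)) on the
  evolutionary correlation matrix.
* **Compositional analysis** of body-mass allocation (Aitchison closure,
  clr/ilr transforms) and a multivariate phylogenetic regression with
  permutation MANOVA (Pillai's trace, permutation-corrected effect size
  ξ², coefficients back-transformed to the simplex where 0.20 per part
  means "no effect").
* **Phylogenetic PCA** of log tissue masses about the GLS phylogenetic
  mean.
* **Confirmatory path analysis**: d-separation basis sets, Fisher's C,
  CICc = C + 2qn/(n−1−q) ranking, and coefficient averaging over models
  within ΔCICc ≤ 2. Candidate DAG sets are plain-text configs; an 8-model
  climate set and a 28-model tissue set ship with the package.
* **Directional tests of correlated evolution** between two binary traits
  (Pagel's method): independent / unilateral / mutual ARD Markov models on
  the four joint states, pruning likelihoods with matrix exponentials,
  compared by AIC weights.
* A **synthetic-data generator** that reproduces the statistical structure
  and nesting of such a study (116 species, 50 pre/post pairs, 43 with
  breeding data, 30 field-validated thresholds, five years of daily
  temperatures), so the entire pipeline is testable without any data
  download.

## Worked example

```r
library(brumate)

study <- simulate_study(seed = 42)   # full synthetic study bundle
tree <- study$tree; traits <- study$traits

# 1. brumation period of one species from its site's temperatures
th <- study$thresholds[1, ]
brumation_estimate(study$temperatures[[th$site]], th$entry_c,
                   th$emergence_c, years = 2012:2016)
#> $per_year_days
#> 2012 2013 2014 2015 2016
#>  116  141  151  152  127
#> $mean_days
#> [1] 137.4
#> $status
#> [1] "brumating"

# 2. brain allometry: shallow scaling, CI excludes 1
fit_allometry(traits$brain, traits$svl, tree, species = traits$species,
              n_boot = 100, seed = 1)
#> Allometric slope: 0.52 [ 0.488, 0.554 ] -> shallower

# 3. relative brain size vs brumation duration (size-controlled PGLS)
traits$log_brain <- log(traits$brain); traits$log_svl <- log(traits$svl)
days <- vapply(seq_len(nrow(study$thresholds)), function(i) {
  brumation_estimate(study$temperatures[[study$thresholds$site[i]]],
                     study$thresholds$entry_c[i],
                     study$thresholds$emergence_c[i],
                     years = 2012:2016)$mean_days
}, numeric(1))
traits$brumation_days <- days[match(traits$species, study$thresholds$species)]
fit_pgls(log_brain ~ brumation_days + log_svl, traits, tree,
         n_boot = 100, seed = 2)
#> PGLS fit: log_brain ~ brumation_days + log_svl
#> n = 116  df = 113  lambda = 0.898 [ 0.759, 0.96 ]
#>                Estimate std_beta        t       r      p
#> (Intercept)     -4.6826       NA -21.5845 -0.8971 0.0000
#> brumation_days   0.0000  -0.0014  -0.1180 -0.0111 0.9062
#> log_svl          1.5593   1.0248  31.4114  0.9472 0.0000
```

Reading the output: the species' mean dormancy is 137 days across
2012–2016, hence "brumating"; brain mass scales with the 0.52 power of
cubed SVL (clearly shallower than isometry); and relative brain size shows
no relationship with brumation here (partial r = −0.01, t₁₁₃ = −0.12) —
as it should, since the default generator encodes allometric and
phylogenetic structure but deliberately no brumation→brain effect, making
this a null-behaviour check of the machinery. λ̂ = 0.90 recovers the strong
phylogenetic signal the generator put into brain deviations.

The full pipeline (all ten analyses, one CSV each plus a text report):

```r
res <- run_all(pipeline_config(study = study, out_dir = "results", seed = 1))
```

or from a shell, `Rscript scripts/run_pipeline.R --simulate --out results`.

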