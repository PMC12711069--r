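# reefdd

Diversity dependence among morpho-functional groups of fossil reef corals.

Reef corals can be grouped by *morpho-functional (MF) group* — the set of
species sharing one combination of six binary colonial growth forms
(branching B, massive M, columnar C, laminar L, foliaceous F, encrusting E).
Because growth form governs a coral's ecosystem function, the species
diversity held within one MF group may promote or suppress origination and
extinction in co-existing groups. `reefdd` gives paleobiologists the full
analysis chain to test this on fossil occurrence data:

* **Curation** of Paleobiology-Database-style occurrence tables (geographic
  box, open-nomenclature filtering, offline synonym maps and drop lists,
  uniform age resampling into replicates, epoch binning).
* **MF groups** from binary growth-form scores, with dominance
  classification and log-calibrated redundancy categories.
* **Functional indices**: redundancy `FR = S/FG`, over-redundancy
  `FOR = Σ max(n_i − FR, 0) / S`, and a permutation null holding S and FG
  constant (9,999 uniform assignments rejected on empty groups).
* **A fossil birth–death engine**: reversible-jump MCMC over per-species
  origination/extinction times (Ts, Te), piecewise-constant rates λ(t), µ(t)
  with sampled shift counts, and Poisson preservation rates q under HPP /
  NHPP / TPP models with AIC-based model screening; replicate pooling and
  rate/diversity-through-time curves on a 0.1 Myr grid.
* **Covariate models** conditioned on the pooled (Ts, Te) draws: MTE
  (Dirichlet-multiplier trait/redundancy effects on extinction with
  Bayes-factor variable selection) and MBD (origination/extinction rates
  modulated by scaled environmental and group-diversity predictors,
  λ(t) = λ₀·exp(Σⱼ Gⱼ Cⱼ(t)), under a horseshoe prior with shrinkage
  weights ω ∈ [0, 1]).
* **Summaries**: an effect network keeping relationships with ω ≥ 0.6
  (promoting vs suppressing edges), report tables, and a YAML-driven
  pipeline with per-stage seeds and byte-reproducible outputs.

A forward Gillespie simulator with known truth (group structure,
diversity-dependence coefficients, covariate effects, preservation rates)
generates the package's test data, so every estimator is validated by
parameter recovery at desk scale.

## Worked example

A desk-scale end-to-end run on synthetic data (about a minute):

```r
library(reefdd)
res <- run_pipeline(list(seed = 5), out_dir = "reefdd-output")

res$groups
#>   label n_species n_occurrences occurrence_share    class
#> 1     M        40           321        0.7039474 dominant
#> 2     B        11            70        0.1535088 dominant
#> 3    ME         8            65        0.1425439    other

res$indices[, c("epoch","S","FG","FR","FOR","null_mean","null_sd","p_perm")]
#>         epoch  S FG   FR   FOR null_mean null_sd p_perm
#> 1   Oligocene 21  3  7.0 0.190    0.1223  0.0660  0.234
#> 2     Miocene 40  3 13.3 0.342    0.0878  0.0458  0.001
#> 3    Pliocene 21  2 10.5 0.452    0.0854  0.0631  0.001
#> 4 Pleistocene 19  1 19.0 0.000    0.0000  0.0000  1.000
```

Reading the output: the simulated fauna resolves into three MF groups
(massive-dominated, with 40 of 59 species and 70% of occurrences). In the
Miocene and Pliocene the observed over-redundancy (0.34, 0.45) far exceeds
its permutation null (0.09 ± 0.05, 0.09 ± 0.06; p ≈ 0.001): species are
packed into few groups much more unevenly than a random assignment would
produce. The MBD stage then asks whether any group's diversity (or the
environmental series) modulates origination or extinction; in this run all
shrinkage weights stay below the 0.5 noise line — correct, since the default
generator plants no diversity-dependence effects — so the ω ≥ 0.6 effect
network is empty:

```r
head(res$mbd$effects, 4)
#>     predictor   rate_type  median_G omega
#> 1           M origination -0.435677 0.354
#> 2           B origination  0.018074 0.218
#> 3          ME origination -0.136065 0.253
#> 4 temperature origination -0.518224 0.360
```

Single stages are plain functions: `compute_fr(111, 12)` returns `9.25`;
`null_model(111, 12, n_sims = 9999)$null_mean` is ≈ `0.13`;
`run_rjmcmc()` fits one fossil dataset; `mbd_fit()` / `mte_fit()` take any
pooled draw set.

## Layout

```
R/                   implementation (curation, groups, indices, fbd engine,
                     covariate models, summaries, pipeline, simulator)
tests/testthat/      unit, property and acceptance suites
scripts/acceptance.R headline-quantity reproduction
vignettes/methods.Rmd  model and design documentation
```
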