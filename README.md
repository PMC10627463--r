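# habnetsens

Sensitivity of habitat-network occurrence models to the maximum dispersal
distance.

## What this package is for

Habitat-network models predict the presence or absence (occurrence-state) of
a species in habitat patches: patches are the nodes of a graph, and an edge
connects two patches when the least-cost distance between them is below a
threshold set by the species' assumed maximum dispersal distance.  Because
field-derived maximum dispersal distances are unreliable — dispersal kernels
are leptokurtic, and rare long-distance dispersers are systematically
missed — the choice of that one parameter reshapes the entire network and
everything downstream of it.

`habnetsens` implements the full modelling chain as seeded, reusable stages
so that this sensitivity can be quantified: patch delineation from a
continuous suitability raster, network construction across a sweep of
dispersal distances, per-patch topological predictors, occurrence-state
assignment from opportunistic multi-species records, boosted regression
trees with stepwise tree-count selection, and collation of how network
structure, cross-validated AUC and predictor importance respond to the
distance threshold.  A synthetic-landscape generator with
connectivity-driven occupancy and imperfect visit-based detection makes the
whole analysis runnable and testable end to end with no external data.  It
is aimed at spatial ecologists building or auditing connectivity-based
occurrence models.

## The model in brief

Dispersal probability decays with cost distance as

    cost = log(prob) / log(p) * d0 ,        p = 0.5 by default,

so `d0` is the median dispersal distance.  Edges form where the probability
exceeds `prob_min = 0.0001`, i.e. below the cost threshold
`log(prob_min)/log(p) * d0 ≈ 13.29 d0`; `d0_for_max_distance()` inverts
this so a literature maximum dispersal distance can be plugged in directly
(1500 m → d0 = 113, 4411 m → 332).  Per patch, the occurrence model uses
seven predictors — degree, third-order neighborhood, unweighted betweenness,
strength (summed edge probability), habitat availability
`HA_i = a_i + Σ_j a_j p*_ij` with `p*_ij` the maximum-product path
probability, plus HSI and area — fitted to presence / target-group-absence
labels by stochastic gradient boosting (learning rate 0.001, tree depth 5,
bag fraction 0.75, stepwise tree selection by cross-validated deviance).

## Worked example

Generate a synthetic landscape, delineate patches, build the truth at 4 km,
sample records, and sweep four dispersal distances:

```r
library(habnetsens)

d0_for_max_distance(1500)                  # 113
cost_threshold(dispersal_params(d0 = 113)) # 1501.511

lc      <- landscape_config(seed = 7)
suit    <- generate_suitability(lc)
mask    <- generate_mask(lc)
patches <- delineate_patches(binarize(suit, 0.5), mask, suit)
patches
#> <patch_set> 295 patches on a 200 x 200 grid (cell 100 m, 8-connectivity)
#>   area: 10000 - 270000 m2; HSI: 0.500 - 0.904

net_true <- build_network(patches,
  interpatch_costs(patches, cost_cap = cost_threshold(dispersal_params(d0 = 301))),
  dispersal_params(d0 = d0_for_max_distance(4000)))
occ <- generate_true_occupancy(patches, net_true, occupancy_truth_config(seed = 7))
obs <- generate_observations(patches, occ, sampling_config(seed = 7))

design <- sweep_design("focal", fixed_distances = c(300, 2000, 4000, 10000))
cfg    <- brt_config(n_folds = 5, step_size = 50, max_trees = 400)
res    <- run_sweep(design, patches, obs, brt_config = cfg, n_replicates = 5,
                    intensity_threshold = 4, seed = 1)
res$results[, c("distance", "n_edges", "n_components", "mean_auc_cv",
                "imp_HSI", "imp_strength")]
#>   distance n_edges n_components mean_auc_cv imp_HSI imp_strength
#> 1      300      84          219       0.671   49.87         4.39
#> 2     2000    1498            1       0.814   10.96        47.98
#> 3     4000    4687            1       0.819    8.35        68.36
#> 4    10000   20882            1       0.800   15.00        48.08

regress_auc_on_distance(res, "focal")
#>   species    slope std_error p_value r_squared
#> 1   focal 8.55e-06  3.48e-06  0.0244     0.251
```

Reading the output: at 300 m the landscape fragments into 219 components,
topological predictors are nearly uninformative, and the model leans on
habitat quality (HSI influence ~50%) with mediocre discrimination
(AUC-cv 0.67).  At and beyond the true 2–4 km scale the network coalesces,
connectivity predictors take over (strength influence ~50–70%), and AUC-cv
rises to ~0.82 — the occupancy process here really is connectivity-driven,
and the model only sees that once the assumed dispersal distance is large
enough.  The regression summarizes the positive AUC–distance relation.

The same analysis runs from one YAML config through
`run_pipeline()` / `inst/scripts/run_pipeline.R`, writing rasters
(Esri ASCII grid), patch tables (CSV/GeoJSON), networks (GraphML/CSV),
per-stage results and a seeded manifest.

See `vignettes/habitat-network-sensitivity.Rmd` for the methods account:
kernel parametrization, cost conventions, the occurrence-state heuristic
and its manual override, the boosting contract, and what the synthetic
generator does and does not emulate.

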