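# edgegrowth

Quantifying how forest edges alter tree growth and stand structure in
temperate forest inventories.

Fragmentation puts a large share of temperate forest within ~30 m of a
non-forest edge, where light, temperature, water balance and nitrogen
inputs all differ from the forest interior. `edgegrowth` implements a
quasi-experimental pipeline for inventory data organized as plots of four
fixed-area subplots with land-use condition mapping and repeated tree
measurements (dbh ≥ 12.7 cm, two cycles 5–7 years apart):

1. **Edge classification** — subplots holding both a forest and a
   non-forest condition are edges, with the adjacent cover mapped to a
   binary anthropogenic/unknown type; fully forested subplots on fully
   forested plots are interior controls; edge-proximate subplots are
   excluded.
2. **Response computation and filtering** — per-subplot basal area
   BA = Σ π(dbh/200)² (m² ha⁻¹ of forested area), annualized basal area
   increment BAI (m² ha⁻¹ yr⁻¹, with ingrowth measured from the 12.7 cm
   threshold when no prior diameter was recorded), stem density and mean
   diameter; then an auditable filtering cascade (≥ 30 m² forested area,
   one subplot per plot, central-95% trims of BA and BAI) with an
   exclusion ledger.
3. **Matching** — greedy 1:1 nearest-neighbour Mahalanobis matching of
   interior subplots to edge subplots over four abiotic covariates, exact
   within forest type group, with standardized-mean-difference balance
   tables.
4. **Gamma GLM with inverse link** — `E[y] = 1/(Xβ)`; AIC model
   selection over a nested candidate set; marginal edge effects per
   forest type at within-type covariate means with delta-method CIs and
   Wald tests; two-part mortality models; Welch/Bonferroni
   density-diameter contrasts; residual semivariogram diagnostics.
5. **Scaling** — queen's-rule anthropogenic edge detection on 30 m
   land-cover grids, per-ecoregion edge fractions and forest-type
   composition, percent increase in zone-total BAI attributable to
   edges, and global-style edge/interior area accounting from canopy
   cover rasters (10%/30% thresholds, biome/continent strata, product
   agreement R²/RMSE).

A synthetic inventory and landscape generator (`generate_inventory()`,
`generate_landscape()`) reproduces the statistical structure the analysis
assumes — including confounded covariates, ingrowth, harvest and gross
dbh measurement errors — with known ground-truth effect sizes, so the
whole pipeline is testable without access to protected inventory records.

## Worked example

```r
library(edgegrowth)

cfg  <- edge_scenario(n_plots = 5000, seed = 1)  # published effect sizes
pipe <- run_edge_pipeline(cfg)
pipeline_effects(pipe)
#>   dataset       response  pct_diff pct_low pct_high
#>   all           bai          24.95   22.95    26.96
#>   all           ba           13.61   11.96    15.26
#>   anthropogenic bai          37.50   35.06    39.94
#>   anthropogenic ba           19.91   17.90    21.93
```

Each row is the overall (forest-type-weighted) marginal percent
difference of an edge dataset vs matched interior forest, with its 95%
confidence interval. The generator's true effects here are +24.1% (all
edges, BAI), +13.9% (all edges, BA), +36.3% (anthropogenic edges, BAI)
and +21.0% (anthropogenic edges, BA): every truth lies inside its
interval, i.e. the full classify → filter → match → fit → marginal-effect
chain recovers what was put in. Structural contrasts from the same run:

```r
pipe$density_tests
#> stems_ha:    all edges +55.9, anthropogenic +80.3 stems/ha (p << 0.001)
#> mean_dbh_cm: all edges +0.12, anthropogenic +0.24 cm       (p = 0.92, 0.21)
```

— more stems at edges, no meaningful diameter difference. See the
vignette (`vignettes/edge-effects-methods.Rmd`) for the model, the
generator's design and its limitations, and
`mortality_analysis()`, `harvest_robustness()`, `scale_zone_bai()` and
`biome_summary()` for the mortality, robustness and scaling analyses.

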