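# hvhforest

Testing the **Height Variation Hypothesis (HVH)** from canopy height model
(CHM) rasters: forests with a more heterogeneous vertical structure offer
more ecological niches — different light regimes and micro-habitats — and
should therefore host more tree species. If that holds, the *height
heterogeneity* (HH) of a CHM over a field plot is a remote-sensing proxy
for in-situ tree species diversity, and wall-to-wall CHM products (e.g.
spaceborne-LiDAR-derived maps at 10 m or 30 m) can be screened for
biodiversity without exhaustive ground campaigns.

The package is aimed at forest ecologists and remote-sensing analysts. It
implements the full analysis chain:

- **Height-heterogeneity indices** over the N pixels of a plot window, with
  uniform pixel abundances `p_i = 1/N`:
  - Rao's quadratic entropy `Q = (1/N²) Σ_{i,j} d(x_i, x_j)`, with
    `d = |x_i − x_j|` (Euclidean, default) or `d = ½(x_i − x_j)²`
    (half-squared, which reduces Q exactly to the population variance);
  - coefficient of variation `CV = SD / x̄`;
  - Shannon's `H_rs = −Σ p_i log p_i` and Simpson's `D = Σ p_i²` over
    discrete height classes (0.1 m rounding by default);
- **field diversity** from tree inventories (Shannon's H, species richness,
  stem density, DBH ≥ 5 cm census filter);
- **canopy cover** `CC = 100 · px2m / pxtot` (pixels strictly above 2 m);
- **CHM validation** against a reference (R², RMSE, MAE, bias over pooled
  plot pixels);
- **regression and repeated k-fold cross-validation** (k = 10, 3 repeats by
  default) of diversity on heterogeneity, single and multiple
  (HH + canopy cover + density);
- a **moving-window Rao's Q map** for wall-to-wall heterogeneity;
- a **synthetic forest scene simulator** whose `coupling` knob ties plot
  vertical structure to species diversity (1 = HVH holds by construction,
  0 = exact independence), so the entire workflow runs without external
  data.

Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`), readable by
QGIS/GDAL; plots and inventories as CSV.

## Worked example

```r
library(hvhforest)

# 20 one-hectare plots, structure tightly coupled to diversity
scene <- simulate_scene(scene_config(n_plots = 20, coupling = 1, seed = 42))
scene
#> scene_bundle: 20 plots of 100 m, truth CHM 240 x 240 @ 2.5 m
#>   14156 trees, 12 species; products: 10m, 30m; coupling = 1, seed = 42

# heterogeneity of the 10 m CHM per plot, field diversity per plot
truth10 <- aggregate_raster(scene$truth_chm, factor = 4, method = "mean")
het <- plot_heterogeneity(truth10, scene$plots, chm_source = "truth10m")
div <- diversity_table(scene$inventory)
m <- merge(het, div, by = "plot_id")

fit_linear(m$rao_q, m$shannon_h, xname = "rao_q", yname = "shannon_h")
#> hvh_fit: shannon_h ~ rao_q  (n = 20)
#>   R2 = 0.667, p = 1.13e-05, RMSE = 0.209, MAE = 0.165
#>   coefficients:
#> (Intercept)           x
#>      0.6216      0.2858

repeated_kfold_cv(m$rao_q, m$shannon_h, k = 5, repeats = 3, seed = 42)
#> repeated k-fold CV: k = 5, repeats = 3, seed = 42 (15 folds)
#>   fold means : R2 = 0.629, RMSE = 0.216, MAE = 0.176
#>   pooled     : R2 = 0.616, RMSE = 0.225, MAE = 0.176

validate_chm(scene$product_chms[["10m"]], truth10, scene$plots)
#> CHM validation (pixel, n = 2000): R2 = 0.826, RMSE = 3.12 m, MAE = 2.5 m, bias = +0.982 m
```

Reading: one unit of Rao's Q (mean absolute pairwise height difference, in
metres) buys ≈ 0.29 units of field Shannon diversity here; the positive,
highly significant slope is the HVH signature, and the held-out R² ≈ 0.62
shows it generalizes across folds. The validation line reflects the
simulated product errors (≈ 3 m RMSE, ≈ +1 m bias).

The full pipeline — validation, diversity, cover, heterogeneity, all 16
single regressions, cross-validated single/multiple models, the
inter-index R² matrix, and an optional Rao's Q map — runs from one
configuration:

```r
simulate_scene(scene_config(seed = 1), out_dir = "scene")
run_hvh(run_config(out_dir = "run1", scene_dir = "scene", cv_seed = 1))
```

A command-line wrapper with subcommands (`simulate`, `diversity`, `cover`,
`heterogeneity`, `validate`, `regress`, `cv`, `rao-map`, `run`) ships at
`inst/cli/hvh.R`.

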