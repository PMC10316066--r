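---
title: "Height heterogeneity as a proxy for tree species diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height heterogeneity as a proxy for tree species diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvhforest)
```

## The model

The Height Variation Hypothesis (HVH) posits that vertical structural
heterogeneity of a forest canopy creates niches — gradients of light,
micro-climate and habitat — that allow more tree species to coexist. The
testable consequence is a positive association between a *height
heterogeneity* (HH) statistic computed from a canopy height model (CHM)
over a field plot and the plot's in-situ species diversity.

A CHM is a single-band raster of canopy top height (metres). A field plot
is a square (1 ha, 100 m × 100 m by convention); its *window* is the set of
N CHM pixels whose cell centres fall inside the square. Four HH indices are
computed per window, all with uniform pixel abundances $p_i = 1/N$:

* **Rao's quadratic entropy**
  $Q = \frac{1}{N^2}\sum_{i,j} d(x_i, x_j)$, summed over all ordered pairs
  including $i = j$ (with $d_{ii} = 0$). The single-band Euclidean distance
  $d = |x_i - x_j|$ makes $Q$ the mean absolute pairwise height difference
  (metres). With the half-squared distance $d = \tfrac12 (x_i - x_j)^2$,
  $Q$ collapses exactly to the population variance of the window — a useful
  analytic identity that the test suite pins to $10^{-10}$.
* **Coefficient of variation** $CV = SD/\bar{x}$, dimensionless. Sample SD
  (divisor $n-1$) by default; the population form is an option. The
  convention is irrelevant for correlation-based inference but is stated
  because the two differ at small N.
* **Shannon's H** and **Simpson's D** over *height classes*: heights are
  rounded to a configurable precision (default 1 decimal, i.e. 0.1 m bins)
  and $H_{rs} = -\sum p_i \log p_i$, $D = \sum p_i^2$ are computed over the
  class abundances. These two indices see only the abundance profile, not
  the height values — swapping which height owns which class leaves them
  unchanged. That blindness is exactly why they are expected to
  underperform Rao's Q and CV as HH measures, and the package keeps them to
  make that comparison reproducible.

Field diversity per plot is Shannon's $H = -\sum p_i \log p_i$ over species
abundances (natural log; the base is configurable and only rescales) and
species richness $q$; the census filter keeps stems with DBH ≥ 5 cm
(inclusive). Canopy cover is $CC = 100\,\mathrm{px2m}/\mathrm{pxtot}$ with
a strict `> 2 m` pixel test, computed on the finest CHM available. Stem
density is the tree count per plot.

Inference follows the standard workflow: (1) validate the CHM product
against a reference over the plots (R², RMSE
$=\sqrt{\frac1n\sum (X-Y)^2}$, MAE $=\frac1n\sum |X-Y|$, bias); (2) regress
diversity on each HH index (OLS; R² = squared Pearson correlation, p from
the slope t-test); (3) cross-validate the best combination with repeated
k-fold (k = 10, 3 repeats by default), single and multiple
(HH + canopy cover + density); (4) map heterogeneity wall-to-wall with a
moving-window Rao's Q.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| plot side | 100 | m | the 1 ha field-plot convention |
| window membership | centre in closed square, min-edge in / max-edge out | — | unambiguous, no double counting between adjacent plots |
| canopy-cover threshold | 2 (strict >) | m | the conventional canopy/non-canopy cut |
| DBH census floor | 5 (inclusive ≥) | cm | standard census protocol |
| height-class rounding | 1 decimal | m | "unique pixel values" is ill-defined on float rasters; 0.1 m bins make the abundance indices stable and the choice explicit |
| CV standard deviation | sample (n−1) | — | matches common statistical software; population form available |
| k-fold settings | k = 10, 3 repeats | — | the standard repeated-CV protocol for ~130 plots |
| nodata warning | > 50 % of window | — | flags unusable plots without silently dropping them |

## Numerical choices

* **Rao's Q algorithm.** The Euclidean mode uses the sorted-prefix identity
  $\sum_{i<j} |x_i - x_j| = \sum_k (2k - 1 - N)\, x_{(k)}$ (O(N log N));
  the half-squared mode uses the variance identity (O(N)). The O(N²)
  double loop is retained in the test suite as an independent oracle; the
  two agree to ≤ 10⁻¹⁰ relative error on windows up to N = 10 000.
* **Moving-window edges.** Border cells where the window is incomplete are
  nodata — every mapped value is a full-window statistic, directly
  comparable across the map. Partial windows would mix neighbourhood sizes.
  Within a window, nodata pixels are dropped; fewer than 2 valid pixels
  yields nodata.
* **Boundary ties.** A cell centre exactly on the plot's minimum edge is
  included, on the maximum edge excluded, on both axes; comparisons carry a
  relative tolerance of 10⁻⁹ cell sizes so exact-edge geometry does not
  flip on float round-off.
* **Cross-validation R² conventions.** Per-fold R² is the squared Pearson
  correlation between observed and predicted held-out values — the
  resampling convention of the common workflow. That statistic has a
  positive small-sample bias of order $1/(n_{test}-1)$ per fold, so it can
  exceed the training R² when the signal is weak; the variance-explained
  convention $1 - SSE/SST$ is therefore reported alongside
  (`mean_r2_sst`, `pooled_r2_sst`) and is the one that provably sits below
  the training R² on average (the optimism property, asserted statistically
  in the tests). Both are written to every report; headline tables use the
  correlation convention.
* **Degenerate inputs.** Constant windows: $Q = 0$, $CV = 0$,
  $H_{rs} = 0$, $D = 1$ exactly. A zero-mean window makes CV undefined —
  an error, not an infinity; in batch tables it degrades to `NA` for CV
  only. Empty windows, all-nodata plots and plots outside the grid are
  collected in a rejects report rather than dropped.
* **Raster format.** Grids are serialized as ESRI ASCII (plain text) with
  17 significant digits, so a write→read round trip is bit-exact; the CRS
  identifier travels in a `.prj` sidecar. Only square cells are supported.

## The scene simulator

Field campaigns behind HVH studies are rarely deposited, so the package
ships a generator whose defaults mirror the study conditions the analysis
is meant for: 130 plots of 1 ha, a 2.5 m "truth" CHM, degraded products at
10 m and 30 m with +1 m bias and 3 m Gaussian noise (the few-metre error
magnitudes reported for satellite CHM products), ~700 stems/ha (inside the
656–995 trees/plot range typical of temperate inventory plots), a pool of
12 species, and up to 4 height strata with mean top heights 6/14/22/30 m.

Each plot draws a latent structural complexity $c \sim U(0,1)$ that sets
its number of occupied strata $L = 1 + \mathrm{round}(c\,(L_{max}-1))$.
With probability `coupling` the species count is tied to the same latent
variable ($q = 1 + \mathrm{Binomial}(q_{pool}-1, c)$) and species evenness
rises with $c$; otherwise both are drawn independently. This mixture gives
an exact independent null at `coupling = 0` and a monotone
structure–diversity dependence at `coupling = 1` — a parameter-recovery
surface: the analysis should find a positive, significant Rao-vs-Shannon
slope in the coupled arm and nothing in the null arm, and the 10 m product
should explain diversity at least as well as the 30 m product. Crowns are
flat-topped disks (radius $0.15\,h + 0.5$ m) rasterized by the cell-centre
max rule over 0 m bare ground (so canopy-cover logic is exercised); no
allometric realism is claimed. Every plot owns a private RNG stream derived
from (scene seed, plot index), so regeneration is order-independent and a
scene manifest reproduces the bundle bit-identically.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: spatial autocorrelation of structure across
plot boundaries, topography (slope-induced CHM error), crown shape and
mortality realism, sensor-specific error structure (the product noise is
i.i.d. Gaussian, real CHM products have spatially correlated,
height-dependent error), understory strata invisible to a CHM, and
imperfect tree geolocation. Results on synthetic scenes demonstrate that
the estimators and the pipeline recover a known coupling; they do not
certify effect sizes in any real forest.

## Problem sizes

The test suite runs the oracle comparison on 200 windows up to N = 10 000,
the parameter-recovery sweep on 20 seeds × two coupling arms × 130 plots,
and the reproducibility check on a full 130-plot pipeline run; the
acceptance script uses one 130-plot scene plus ten scenes per coupling arm.
These sizes make the statistical checks stable while a full run stays in
the minutes range on a single CPU.

## Known limitations

* Planar (projected, metric) coordinates only; no reprojection, no
  geodesic handling, no multi-band rasters or multi-metric Rao's Q.
* The regression stage is plain OLS: no spatial autocorrelation between
  plots, no mixed effects, no variable selection. With overlapping plots
  (possible in dense campaigns) the independence assumption is optimistic.
* Height-class rounding for the abundance indices is a declared choice
  (0.1 m); on rasters stored at coarse precision the "natural" class width
  may differ, and the two abundance indices react strongly to it.
* The moving-window map is O(cells × window²·log window); fine for scenes
  of tens of hectares at 10 m, not tuned for country-scale mosaics.
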