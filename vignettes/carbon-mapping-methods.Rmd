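---
title: "Methods: LiDAR-assisted carbon mapping with carbonscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LiDAR-assisted carbon mapping with carbonscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonscape)
```

# The problem

National forest-carbon accounting (for REDD+ and similar schemes) needs
per-hectare estimates of aboveground carbon density (ACD, Mg C ha^-1^)
with explicit uncertainty, over areas far larger than any field-plot
network can cover. The approach implemented here chains three estimation
tiers, each calibrating the next:

1. **Field plots** give ACD from tree lists through allometry.
2. **Airborne LiDAR** gives canopy height over sampling transects; a
   calibrated power law converts mean top-of-canopy height (TCH) to ACD at
   1-ha resolution.
3. **Satellite covariates** (terrain, climate, fractional vegetation
   cover) extend the LiDAR-scale ACD to full landscape coverage, by
   covariate stratification and by random-forest regression.

Per-pixel uncertainty is propagated through the last two tiers and
validated by comparing the upscaled map against LiDAR-scale estimates
inside set-aside regions.

# Plot-level allometry

`plot_acd()` computes, for each plot,

$$\mathrm{ACD} = \frac{c_f}{A} \sum_{i:\,D_i \ge 10\,\mathrm{cm}}
  \mathrm{AGB}(D_i, H_i, \rho_i) \times 10^{-3},$$

with area $A$ in ha, carbon fraction $c_f = 0.48$ of dry biomass, and the
moist-forest allometry $\mathrm{AGB} = 0.0509\,\rho D^2 H$ (kg; $D$ cm,
$H$ m, $\rho$ g cm^-3^) as the default `form`. Dry
($0.112\,(\rho D^2 H)^{0.916}$) and wet ($0.0776\,(\rho D^2 H)^{0.940}$)
variants are selectable per plot network because the appropriate variant
is an ecotype-level choice that the data rarely record; we deliberately
expose it as configuration rather than guessing from covariates.

Wood density resolves through a cascade — species table, then genus table,
then the Central American regional default of 0.56 g cm^-3^ — mirroring
how Neotropical inventories handle incomplete floristic determination.
Stems below the 10 cm diameter cutoff never contribute; the cutoff is the
conventional inventory census limit and also the lower limit of what the
allometries were built on.

Heights missing from the stem records come from a height–diameter model.
The default form is log-log linear, $\ln H = c_0 + c_1 \ln D$, fitted by
least squares (`fit_height_diameter()`). Where no local height
measurements exist but LiDAR does, `fit_hd_lidar_constrained()` fits the
same form through per-plot (maximum diameter, maximum LiDAR height) pairs.
Constraining heights by what the LiDAR actually observed caps the
systematic over-prediction that imported height models produce in short
ecosystems. With a single plot the exponent is held at a supplied regional
value and only the intercept is solved — the model is otherwise
underdetermined; this is the package's choice of regularisation, flagged
by `provenance = "lidar-constrained"`.

# LiDAR metrics

The canopy height model is `DSM - DTM` with negative differences clamped
to zero (`compute_chm()`; the clamp count is retained as an attribute
because a high count indicates mis-registered elevation models rather
than vegetation).

`plot_tch()` averages every CHM pixel whose **centre** lies inside the
plot footprint. Centres exactly on a boundary follow a half-open rule
(bottom/left edges count as inside): the choice is arbitrary but must be
deterministic so abutting footprints partition pixels without double
counting. `aggregate_to_hectare()` block-averages fine pixels to the
1-ha analysis grid; blocks with under 50% valid pixels become nodata.
That threshold is this package's convention for partially cloud-masked
hectares — there is no community standard — and it is configurable.

# TCH-to-ACD calibration

`fit_power_law_ml()` fits

$$\mathrm{ACD}_i \sim \mathcal{N}\!\left(a\,\mathrm{TCH}_i^{\,b},\;
 \left(\sigma_0 (a\,\mathrm{TCH}_i^{\,b})^{k}\right)^2\right)$$

by maximum likelihood over $(a, b, \sigma_0, k)$, initialised from
ordinary least squares on $(\ln \mathrm{TCH}, \ln \mathrm{ACD})$. The
mean-dependent (heteroskedastic) error standard deviation
$\sigma_0 \mu^k$ nests constant error ($k = 0$) and proportional error
($k = 1$), and $k$ is estimated rather than fixed: tall, high-carbon
plots scatter more in absolute terms, and a constant-variance fit would
let them dominate. Fitting on the untransformed scale, rather than
regressing logs, avoids back-transformation bias and — because the
Gaussian density is defined at zero — permits ACD = 0 observations
(grasslands), which a lognormal error model cannot accommodate. That is
the main reason a Gaussian with mean-dependent spread was chosen over a
lognormal.

Numerical choices: the optimiser is L-BFGS-B on
$(\ln a, \ln b, \ln \sigma_0, k)$ with $k \in [0, 3]$, a $10^4$
iteration budget and a tight convergence factor; the objective is clamped
to a large finite value where the likelihood under- or overflows, and a
profiled grid over $k$ with Nelder–Mead on the remaining three parameters
is the fallback if the primary optimiser reports non-convergence. Exactly
noise-free data (residual RMSE below $10^{-9}$ of the data scale after
initialisation) short-circuits to the OLS solution, since the ML variance
estimate degenerates to zero there. A floor of $10^{-8}$ on each
$\sigma_i$ keeps the likelihood finite for interior zero-mean cells.

The calibration report carries $n$, original-scale RMSE, bias, and
adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-3)$ with $p = 2$ mean-model
parameters. For held-out plots, `validation_stats()` reports the adjusted
$R^2$ of **observed regressed on predicted** (plus RMSE and bias of
predicted minus observed). Regressing in the other direction gives a
different number; we state our choice rather than leaving it ambiguous.

# Satellite covariates

- `composite_best_pixel()`: per location, candidate observations within
  70% of the mean brightness (mean reflectance across bands) are
  retained, and the retained candidate with the **median NDVI** is
  selected; for even counts the lower-middle order statistic is taken,
  for determinism. The brightness rule is read literally as
  $|b - \bar b| \le 0.70\,\bar b$; a stricter ±30% reading is selectable
  (`mode = "plusminus"`) because the phrasing admits both.
- `cross_sensor_calibrate()`: per-band linear gain/offset by least
  squares on co-occurring pixels (at least 100 required), then gap
  backfill with transformed coarse-sensor values; the filled fraction is
  reported.
- `slope_aspect()`: Horn 3×3 finite differences; aspect is the bearing of
  steepest **descent**, degrees clockwise from north in [0, 360); cells
  with gradient magnitude below $10^{-8}$ are flat and get nodata aspect.
  A west-dipping plane (elevation increasing eastward) therefore has
  aspect 270°. Both a native-resolution and a block-averaged
  coarse-resolution variant are computed (`terrain_two_scales()`) since
  the coarse aspect can be the more predictive covariate.
- `median_smooth()`: per-cell median over a 5×5 window (truncated at
  edges), used to stabilise coarse, noisy climate surfaces.
- `seasonality_index()`: count of months with rainfall strictly below
  100 mm; a month at exactly 100 mm is not dry.

Spectral unmixing into PV/NPV/bare fractions is out of scope: it is the
province of existing dedicated tools, so the covariate stack accepts
fraction rasters as inputs (the simulator generates them directly).

# Upscaling

**Stratification** (`build_strata()`, `stratified_acd_map()`): the
landscape is partitioned into unique joint covariate-bin classes; each
class with LiDAR coverage of at least 1% of its area receives the
**median** ACD of its sampled cells; classes below the threshold fall
back to bins of PV fraction alone, the covariate most strongly related to
carbon. Default bin steps are 250 m elevation, 5° slope, 250 mm rainfall,
integer seasonality and 10% cover fractions — coarse enough to be
interpretable, and fully configurable since any particular national
product's bin ledger is a design choice of that product. On a desk-scale
synthetic landscape these defaults still produce thousands of classes,
most of them small; the 1% rule then routes much of the map through the
PV fallback. That behaviour is faithful to the method: stratification's
weakness on finely structured landscapes is exactly what the ensemble
comparison is designed to expose.

**Random-forest regression** (`train_ensemble()`,
`predict_ensemble()`): a regression forest (500 trees, minimum node size
5 by default) of LiDAR ACD on the eight covariates **plus raw row/col
position**, trained on an ordered systematic sample of every
`stride`-th sampled cell (default 10). Position features exploit the
systematic transect layout and damp large-scale spatial autocorrelation
of errors; raw indices are used because any smooth monotone transform is
equivalent for tree splits. Predictions can optionally overwrite directly
sampled cells with their LiDAR ACD (`overwrite_lidar`), since the direct
estimate is known with more confidence there; both behaviours are
supported because published maps are ambiguous on this point.

# Uncertainty

`fit_rmse_polynomial()` bins residuals by predicted ACD (default 10
Mg C ha^-1^ bins, sparse bins merged into neighbours below 5 residuals),
computes per-bin RMSE and fits a cubic through (bin centre, RMSE) weighted
by bin count, clamped at zero. `quantile_residual_bands()` characterises
the same heteroskedasticity non-parametrically by linear quantile
regression (pinball loss minimised by Nelder–Mead from a least-squares
start) at the 5th, 50th and 95th percentiles.

`propagate_error_map()` assigns

$$\varepsilon =
\begin{cases}
\varepsilon_{\mathrm{LiDAR}}(\mathrm{ACD}) & \text{on directly sampled cells}\\
\sqrt{\varepsilon_{\mathrm{LiDAR}}^2 + \varepsilon_{\mathrm{model}}^2} & \text{elsewhere,}
\end{cases}$$

treating the LiDAR-calibration and upscaling errors as independent. The
default LiDAR-tier error is proportional, $0.10 \times \mathrm{ACD}$,
consistent with the ~10% RMSE that 1-ha LiDAR calibration achieves; a
fitted heteroskedastic function from plot-validation residuals can be
substituted (`lidar_error_fn`), and neither form is asserted as uniquely
correct.

`ecoregion_bias_report()` computes, per set-aside region, the mean bias
(upscaled minus LiDAR-scale), RMSE and distribution summaries of both
maps — the zonal validation used to decide between the two upscalers.

# The synthetic landscape

`generate_landscape()` builds study systems with known truth:

- **Covariates**: an east–west elevation ridge plus smoothed Gaussian
  random fields (white noise convolved with a separable Gaussian kernel,
  reflected at edges); rainfall increasing and seasonality decreasing
  with elevation; PV from a logistic transform of a smooth field with the
  remainder split between NPV and bare so the three fractions sum to one
  exactly.
- **True ACD**: $\max(0,\ \beta_0 + \sum_j \beta_j x_j)$ times unit-mean
  lognormal noise with coefficient of variation `noise_cv` (default
  0.15, the plot-to-LiDAR error scale at 1 ha). Multiplicative unit-mean
  noise keeps the field non-negative, makes error proportional to the
  mean — matching the calibration's heteroskedastic error model — and
  leaves the expected landscape mean equal to the noise-free surface, so
  parameter recovery is well-posed. Default effects put ACD roughly in
  0–175 Mg C ha^-1^ with a landscape mean near 60, a realistic humid
  neotropical range.
- **CHM**: each 1-ha cell's fine pixels are
  $(\mathrm{ACD}/a)^{1/b}$ plus *exactly zero-mean*, amplitude-bounded
  (15% of cell TCH) within-cell texture, so the 1-ha mean TCH inverts the
  generating power law to the cell's true ACD exactly. The texture model
  is a free choice — no study describes sub-hectare canopy texture in a
  way that constrains it — and by construction it cannot affect 1-ha mean
  TCH. Generating coefficients default to $a = 0.359$, $b = 1.7676$.
- **Transects**: parallel one-cell strips every 25 columns (~4%
  coverage, the national-LiDAR share the design emulates), on a
  north–south azimuth.
- **Plots**: square footprints placed uniformly at random, filled with
  stems (truncated power-law diameters ≥ 10 cm, heights from the
  generating height–diameter curve, taxa from a fixed synthetic
  wood-density table) until the plot's allometric carbon closes on the
  cell's true ACD; the final stem's diameter is solved exactly, so
  re-analysis through `plot_acd()` recovers the local truth to well
  within 10% (the shortfall is at most one sub-cutoff stem).

What the simulator does **not** emulate: cloud masking beyond a binary
mask, realistic floristics, sensor noise in the covariates, spatial
autocorrelation of the ACD noise, geolocation error between plots and
LiDAR, and allometric model error. Because plot carbon closes exactly on
cell truth and the CHM inverts it exactly, the synthetic plot-to-LiDAR
calibration is nearly noise-free — synthetic calibration $R^2$ is
therefore much higher than any field campaign would achieve, and passing
tests demonstrate correctness of the machinery, not field-attainable
accuracy. Statistical behaviour of the calibration under realistic noise
is instead tested by simulating TCH–ACD pairs directly with 15%
multiplicative noise.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → inventory → calibrate → stratify →
ensemble → errors → validate from one configuration (R object or YAML).
All randomness flows from the single global seed through fixed per-stage
offsets, so identical config + seed reproduces every artifact
bit-identically; the run manifest records each artifact with its MD5
checksum and stage timing. Rasters are written as ESRI ASCII grids and
footprints/regions as GeoJSON — plain-text formats any GIS reads.

Problem sizes used in the shipped tests and in `scripts/acceptance.R` —
landscapes up to 100×100 ha cells, 319-plot networks, 200-replicate
calibration recovery, 300-tree forests — were chosen so the complete
analysis re-runs in minutes on a laptop while keeping Monte-Carlo error
well inside the stated tolerances.

# Known limitations

- Stratification bin defaults produce many sparse classes on small
  landscapes (see above); users mapping real regions should set bins from
  the covariate distributions at hand.
- The quantile regression is a generic optimiser on the pinball loss, not
  an interior-point LP; for the two-parameter fits used here it is
  accurate and fast, but it does not scale to many covariates.
- Spatial autocorrelation of mapping errors is not modelled; propagated
  uncertainties are per-pixel and should not be summed naively over
  regions.
- No reprojection: all inputs must share one planar metric CRS.
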