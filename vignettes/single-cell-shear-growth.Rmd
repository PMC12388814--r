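---
title: "Measuring single-cell algal growth under hydraulic shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell algal growth under hydraulic shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(algrow)
library(dplyr)
```

## The measurement problem

Hydraulic shear modulates phytoplankton growth, but most evidence comes from
bulk cultures, where washout, aggregation and population heterogeneity
confound the signal. An alternative is to attach individual cells (here the
elongated green alga *Scenedesmus quadricauda*) to the inner face of a
parallel-plate flow chamber, push medium over them at a controlled
volumetric flow rate, and photograph the field of view every few minutes.
Each cell then yields a volume-versus-time curve from attachment to its
first division, and comparing curves across flow rates gives a single-cell
dose–response to shear.

`algrow` implements the complete computational side of such a platform:

1. **synthesis** — a generator of artificial micrograph time-lapses with
   exact ground truth, so every downstream stage can be validated without
   physical hardware;
2. **segmentation** — a shallow neural pixel classifier producing
   black-and-white cell masks, followed by connected-component extraction;
3. **measurement** — pixel-to-micrometre calibration and a 2D→3D volume
   rule;
4. **growth analysis** — tracking, exponential smoothing, cubic
   growth-curve fitting, division detection;
5. **reporting** — per-flow-rate aggregation, optimum finding, and a
   flow-rate → energy-dissipation-rate lookup.

## The growth model

Per-frame volumes fluctuate because of image noise, so each series is first
smoothed with single exponential smoothing,

$$S_t = \alpha Y_t + (1-\alpha) S_{t-1}, \qquad S_1 = Y_1, \quad 0<\alpha<1,$$

with $\alpha = 0.1$ by default: single-cell volume fluctuation is mild
relative to the growth signal, so heavy smoothing is appropriate. The
initialisation $S_1 = Y_1$ is the standard convention and makes a constant
series an exact fixed point. Note the lag this smoother introduces: in
steady state it delays a ramp by roughly $(1-\alpha)/\alpha$ frames, which
matters when reading instantaneous values (see *Division metrics* below).

The smoothed curve is then fitted by ordinary least squares with the cubic
growth law

$$V(t) = a\,t^3 + b\,t^2 + c\,t + d,$$

$V$ in $\mu m^3$, $t$ in minutes from the cell's attachment. The intercept
$d$ is the modelled initial volume; the linear term $c\,t$ represents
external (environmental) forcing, whose effect on biomass is approximately
linear; and the higher-order terms capture internal kinetics (enzymatic
reactions), which dominate late growth. `fit_cubic()` rescales the time
axis internally before solving, so exact cubic inputs are recovered to
near machine precision even on grids spanning thousands of minutes:

```{r cubic}
t <- seq(0, 8000, by = 5)
v <- 1.6e-10 * t^3 + 1.0e-3 * t^2 + 0.8e-2 * t + 25
fit <- fit_cubic(t, v)
fit
```

$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean. A
zero-variance target makes that ratio undefined; the fit reports
$R^2 = 1$ by convention and flags it (`zero_variance`), since a constant
series is fitted perfectly by $V = d$.

### Division metrics

A division ends a track. The tracker recognises it when a cell is replaced
by at least two markedly smaller objects inside its matching gate; a
fallback detector (for single-object series) triggers at the first drop of
at least 30% from the running maximum. The *volume at division* is the
volume immediately before that moment, and the *growth period* is
attachment → division, reported in minutes and days (min/1440). By default
the division volume is read from the smoothed series, matching the curves
the analysis presents; a `volume_source = "raw"` option exists because the
smoother's lag systematically underestimates the instantaneous value on a
rising curve — by about $(1-\alpha)/\alpha \cdot c \cdot \Delta t$, which
for $\alpha = 0.1$ is substantial. Quantitative comparisons against
generating ground truth therefore use the raw reading; cross-condition
*comparisons* are unaffected, because the lag offset is common to cells
growing at the same rate.

The *lag phase* is operationalised as the time until the smoothed volume
first strictly exceeds $(1 + r)$ times its initial value, $r = 0.10$ by
default.

## The pixel classifier

Segmentation follows the platform's original design: a 3-layer
backpropagation network (input, one hidden layer, single output) maps each
pixel's colour to a cell probability, thresholded at 0.5 into a
black-and-white mask. Published details pin the training protocol — a
random 70/15/15 train/validation/test split, Levenberg–Marquardt
optimisation, and convergence at a training MSE of $10^{-6}$ — but leave
the exact input topology ambiguous, so the default feature set is the
three 8-bit channel values scaled to $[0,1]$ (a single-channel luminance
option is provided), standardised with training-split statistics. The
hidden width (default 8) is unstated in the source design and
configurable.

The trainer is full-batch Levenberg–Marquardt on the MSE: with parameter
count $P$ (41 at the defaults) it solves
$(J^\top J + \mu I)\,\delta = -J^\top r$ each epoch, shrinking $\mu$
tenfold on improvement and growing it tenfold otherwise. Training stops at
MSE $\le$ target or at `max_epochs`, whichever comes first; the validation
split only monitors early stopping (six consecutive non-improvements, best
weights restored), and the test split is never used in fitting. For the
well-separated intensities typical of stained or fluorescent micrographs
the target MSE is reached within ~10 epochs.

Masks are labelled with **8-connectivity** (diagonally touching pixels are
one object) and components below `min_area` (default 5 px²) are discarded
as speckle; both conventions are package choices.

## Geometry: from mask to volume

A stage-micrometer calibration converts pixels to micrometres (default
$0.30 \pm 0.001\ \mu m/px$). A single focal plane cannot give cell depth,
so a 2D→3D rule is required and is configurable:

* **prolate spheroid** (default, suits elongated *Scenedesmus*):
  $V = \tfrac{4}{3}\pi (L/2)(W/2)^2$ with $L, W$ the calibrated ellipse
  axes;
* **equivalent sphere**: $V = \tfrac{4}{3}\pi r^3$,
  $r = \sqrt{\text{area}/\pi}$.

The two agree exactly for circular projections. Which rule the original
platform used is not recoverable from its published record; the synthetic
renderer always inverts whichever rule is configured, so the
generate→measure round trip is exact by construction up to rasterisation.

Two numerical choices keep that rasterisation error small at realistic
cell sizes (a 27 µm³ cell is only ~17 px long at 0.30 µm/px):

* the renderer uses **coverage rasterisation** — a pixel belongs to the
  cell if at least half its footprint lies inside the ellipse, judged on a
  4×4 subsample grid — which keeps discretised areas close to analytic
  ones;
* `extract_cells()` takes ellipse **orientation and aspect from second
  central moments** (with 1/12 added to the covariance diagonal for the
  unit-pixel footprint) but **pins the ellipse size to the component's
  pixel area**, a first-order statistic far less sensitive to boundary
  discretisation than the moments.

With both in place, volumes measured from noise-free renders stay within
~3% of the generating values for cells from ~15 µm³ upward; the residual
error grows for smaller cells and for the degenerate case of exactly
pixel-aligned, axis-aligned ellipses.

## The synthetic scene generator

`scene_spec()` describes cells (position, orientation, cubic growth
coefficients, optional division or loss time, relative area noise) on a
textured background; foreground/background are Gaussian per-channel 8-bit
intensity models required to be separable (≥ 4 sd apart in one channel).
Frames are rendered at a fixed cadence (default 5 min, the platform's
camera interval). At a division the parent is replaced by two daughters,
each holding 45% of the parent volume, placed just beyond touching along
the parent's major axis — this guarantees the split signature the tracker
keys on. Daughters are only weakly attached after division and are flushed
away after `daughter_residence` (default 60) minutes, mirroring the
routine loss of post-division cells in flow chambers; this also keeps
presentation rules based on cultivation length focused on cells with full
growth curves. Every random element (pixel noise, area noise) derives from
a per-frame child seed computed from the scene seed and the frame time, so
any frame is reproducible in isolation and identical scenes render
bit-identically.

What the generator does **not** emulate: optics (point-spread functions,
illumination gradients, defocus), cell motility, colony/coenobium
formation, and overlapping cells. Tests passing on synthetic scenes
therefore validate the algorithmic chain — not robustness to real-world
optical artefacts, which would require retraining the classifier on real
labelled pixels.

### The shear dose–response cohort

`shear_scene()` encodes a dose–response with its optimum at
270 µL min⁻¹, the threshold shear the platform identified: a bump
$u(f) = \exp(-((f-270)/70)^2)$ scales both the linear growth coefficient,
$c = c_0 (0.3 + 2.7u)$, and the division-size multiple $k = 2 + u$ (a
cell divides when $V$ reaches $k\,d$, i.e. at $t = d(k-1)/c$). Hence
within a condition a larger initial volume yields a larger volume at
division, and across conditions the maximum division volume peaks — and
the growth period dips — exactly at 270 µL min⁻¹. Cells start at 20, 30
and 45 µm³ with $c_0 = 0.06\ \mu m^3\,min^{-1}$, spanning division volumes
up to ~135 µm³ and growth periods up to ~1.8 days within a 0–2600 min
window. The cohort runs at a 20-min cadence — coarser than the camera's
5 min — chosen so a 13-condition study (the full experimental grid
`study_flow_rates()`: 0 plus 30–420 µL min⁻¹) remains a desk-scale
computation while every division still falls inside the window.

```{r cohort-sketch, eval = FALSE}
cohort <- run_shear_cohort(seed = 1)
find_optimal_flow(cohort$summaries, "max_division_volume")  # 270
find_optimal_flow(cohort$summaries, "min_growth_period")    # 270
plot_growth_periods(cohort$divisions)
```

## Reporting conventions

* **Presentation rule**: per experiment only the `k = 3` tracks with the
  longest cultivation period (end − attachment) are kept, matching how
  flow-chamber studies report the few cells that stay stably attached;
  ties break by larger final volume, then smaller id.
* **Matched initial volume**: cross-condition growth-rate comparisons
  filter tracks to a first volume within `tol` of 27 µm³.
* **Aggregation**: arithmetic mean and *sample* sd per coefficient and
  per $R^2$; sd is reported only for $n \ge 2$. Summaries are invariant to
  cell order.
* **Optimum search**: the division-volume metric uses the per-condition
  maximum (the headline number such studies quote), the growth-period
  metric the per-condition median — robust to the censored and lost
  tracks flow chambers produce. Ties return all tied flow rates.
* **Energy dissipation**: only one interior anchor
  (270 µL min⁻¹ → 5.62×10⁻⁵ m² s⁻³) and the study range
  6.2×10⁻⁶–7.5×10⁻⁵ m² s⁻³ are published for this chamber; the default
  `epsilon_map()` assigns the range endpoints to the lowest/highest pumped
  flows (30 and 420 µL min⁻¹) and interpolates linearly. That endpoint
  assignment is an explicit assumption — the underlying CFD relation is
  not public — and the map is overridable with user anchors.
  Extrapolation outside the anchor span is an error rather than a guess.

## Parameter reference

| Parameter | Default | Units | Where |
|---|---|---|---|
| `ratio` | 0.30 | µm/px | `calibration()` |
| `alpha` | 0.1 | — | `exp_smooth()` |
| `threshold` | 0.5 | probability | `classify_image()` |
| `hidden_size` | 8 | nodes | `train_pixel_classifier()` |
| `mse_target` | 1e-6 | — | `train_pixel_classifier()` |
| `min_area` | 5 | px² | `extract_cells()` |
| `max_displacement` | 15 | px | `track_cells()` |
| `division_area_ratio` | 0.8 | — | `track_cells()` |
| `drop_fraction` | 0.30 | — | `detect_division()` |
| `rise_fraction` | 0.10 | — | `lag_phase()` |
| `aspect` | 0.6 | — | `scene_spec()` |
| `interval` | 5 | min | `generate_timelapse()` |

## Known limitations

* Pure greedy nearest-centroid tracking presumes essentially stationary,
  well-separated cells; crossing or densely packed cells would need a
  global assignment method.
* The 2D→3D volume rule is a modelling convention; absolute volumes carry
  its bias even when relative comparisons are sound.
* Very small cells (< ~15 µm³) approach the rasterisation floor of a
  binary mask at 0.30 µm/px; their single-frame volumes can err by more
  than 3% even noise-free.
* The classifier is a per-pixel colour model: it has no spatial context
  and will not separate touching cells (no watershed/declumping) nor cope
  with illumination gradients without retraining.
* Division timing is quantised to the frame interval; sub-interval timing
  and multi-generation lineages are out of scope.
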