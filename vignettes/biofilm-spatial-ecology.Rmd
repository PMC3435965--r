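---
title: "Quantifying the spatial ecology of biofilm colonization at single-cell resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial ecology of biofilm colonization at single-cell resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(biofilmspat)
```

## The scientific question

When bacteria colonize a surface, the spatial arrangement of individual
cells records the interactions that produced it. Under the null model of
*complete spatial randomness* (CSR — a homogeneous Poisson process) no
interaction shaped the pattern; aggregated (clustered) patterns imply
positive, cooperative interactions — typically mediated by diffusible
signals — while regular, self-avoiding patterns imply inhibition. This
package implements the analysis chain that turns a calibrated micrograph of
surface-attached cells into that inference: per-cell coordinates and
features, a battery of CSR tests, geostatistical modelling of how strongly
and over what distance per-cell properties autocorrelate, and, for
dual-reporter (signal source / signal sensor) images, direct measurement of
cell-to-cell *calling distances* and per-cell gene-expression intensity.

All distances are micrometers, areas µm², densities cells/mm², and image
intensities 8-bit. Centroids are georeferenced to a Cartesian frame whose
origin is the lower-left corner of the image, with pixel centers at
half-integer offsets: a pixel in image row $r$, column $c$ (1-based, from
the top) has center $x = (c - \tfrac12)\,\mathrm{cal}$,
$y = (H - r + \tfrac12)\,\mathrm{cal}$ for an $H$-row image at
$\mathrm{cal}$ µm/px.

## From image to object table

`segment_binary()` thresholds a grayscale micrograph (Otsu by default; ties
across a flat plateau of the between-class variance resolve to the plateau
midpoint) and labels connected foreground components. Connectivity defaults
to 8 (bacterial cells are compact); components below `min_pixels = 5` are
discarded as segmentation specks — the debris filter any practitioner
applies even though it rarely appears in print. `segment_color()` handles
two-channel reporter images with a dominance rule: a pixel is *red* when
$R - \max(G, B) \ge$ `margin` (default 30 of 255), and analogously green.
The rule is deliberately simple; it reproduces the function of proprietary
color segmentation on well-separated fluorophores, which is the regime the
synthetic scenes emulate.

`extract_objects()` reduces each labeled object to an `ObjectRecord`:
centroid (arithmetic mean of member pixel centers), pixel count, area
(`pixel_count * calibration^2`, exact by construction), and mean 8-bit
luminosity in the stated channel.

## The CSR test battery

Given $n$ cell centroids in a $W \times H$ window (intensity
$\lambda = n/A$), `neighbor_table()` computes exact first and second
nearest-neighbor distances (`nnd1`, `nnd2`) and the per-cell *cluster
index* $1/\mathrm{nnd1}$ (µm⁻¹), a local sensor of crowding. Stored
distances are raw; coincident centroids are clamped to half a pixel so the
cluster index stays finite (with a warning).

The battery (`csr_tests()`) follows the classical decision rules —
aggregation is indicated by:

| statistic | definition | CSR reference | aggregated side |
|---|---|---|---|
| Holgate | $A = \overline{\mathrm{nnd1}^2/\mathrm{nnd2}^2}$ | 0.5 | $A > 0.5$ |
| Russ | $\tfrac12\sum_{k=1,2}\overline{\mathrm{nnd}_k}/E_{CSR}[\mathrm{nnd}_k]$ | 1 | $< 1$ |
| Clark & Evans | $R = \overline{\mathrm{nnd1}} / (0.5/\sqrt\lambda)$ | 1 | $R < 1$ |
| Hopkins & Skellam | $h = \sum x_i^2 / \sum r_i^2$ | 1 | $h > 1$ |

with $E_{CSR}[\mathrm{nnd}_1] = 0.5/\sqrt\lambda$ and
$E_{CSR}[\mathrm{nnd}_2] = 0.75/\sqrt\lambda$; the Hopkins–Skellam $x_i$
are distances from $m$ uniform sampling locations to their nearest cell and
the $r_i$ nearest-neighbor distances of $m$ sampled cells
($m = \min(\lfloor n/2\rfloor, 100)$ by default). The *verdict* field is
the threshold direction gated by significance at $\alpha$ (default 0.05,
two-sided): `"aggregated"`, `"uniform"`, or `"random"` when not
significant.

The Russ index deserves a note: its upstream formula is not published, so
the package constructs it from exactly the features its source names (first
and second NND) normalized by their CSR expectations, which makes its CSR
reference exactly 1 and preserves the printed `< 1 =` aggregated rule.

`edf_curve()` gives the cumulative empirical distribution function of
`nnd1` against the CSR reference $G_0(r) = 1 - e^{-\lambda \pi r^2}$ with a
pointwise 95% envelope and a global p-value from the maximum vertical
deviation, both from 99 conditional CSR simulations (two-sided rank test).
Aggregated patterns ascend above the reference at small $r$.

### Edge handling and inference

Raw nearest-neighbor distances are biased upward in a bounded window.
`clark_evans()` therefore defaults to the Donnelly perimeter adjustment and
offers toroidal distances (`edge_correction = "torus"`), which the
simulation batteries use. For Holgate and Hopkins–Skellam the analytic
references ($z = (A - 0.5)\sqrt{12n}$; $F_{2m,2m}$) treat per-point
quantities with shared neighbor structure as independent; at $n = 200$,
$m = 100$ this inflates their size to roughly 0.08–0.10. Both tests
therefore offer `p_method = "monte_carlo"`: a two-sided rank test against
99 conditional CSR simulations — the same inference already used for the
Russ index and the EDF envelope — which is exact by construction and
absorbs edge effects. The analytic forms remain the default for
compatibility with their textbook definitions; the simulation batteries use
the Monte-Carlo option.

### Fractal dimension

`fractal_dimension()` measures landscape complexity by box counting: the
slope of $\log N(\varepsilon)$ versus $\log(1/\varepsilon)$ over a
power-of-2 ladder of box sizes from 2 px to a quarter of the smaller image
dimension, by least squares. A filled frame gives 2, a one-pixel curve 1, a
single pixel 0; aggregated biofilm landscapes fall strictly between 1 and
2, and values above 1.000 are read as the self-similar complexity of
aggregated colonization.

## Geostatistics of a per-cell Z-variate

Any continuously distributed per-cell quantity (here typically the cluster
index) can be treated as a regionalized *Z-variate*. `empirical_variogram()`
computes the isotropic semivariance
$\gamma(h) = \frac{1}{2N(h)}\sum_{(i,j) \in h} (z_i - z_j)^2$ over
`n_lags = 12` equal-width bins up to half the window diagonal, using every
pair exactly (no subsampling — at the image scale this is cheap and
deterministic, so no simulation approximations are needed).
`fit_variogram()` fits spherical, exponential, gaussian and linear models
by least squares weighted by pair counts and keeps the family with the
smallest weighted RSS. The *effective range* — the separation at which the
model reaches 95% of its sill, i.e. the radius over which cells influence
their neighbors' Z-variate — is $a\ln 20 \approx 3a$ (exponential),
$a\sqrt{\ln 20}$ (gaussian), or $\approx 0.812\,a$ (spherical, the root of
$1.5x - 0.5x^3 = 0.95$).

Two numerical guards matter in practice. First, a three-parameter WLS fit
to a dozen noisy lags of structureless data will always find a tiny
spurious sill, so a fit is flagged "no structure" (effective range 0)
unless the partial sill exceeds 10% of the total sill *and* the weighted
$R^2$ against the flat variogram exceeds 0.3. Second, a single bounded
window carries few independent patches of the field, so single-realization
range estimates fluctuate wildly; `pool_variograms()` implements the
standard remedy of pooling replicate variograms (pair-count-weighted) before
fitting. In the package's validation, 20 pooled replicate fields (n = 200 in
100 × 100 µm) recover a true exponential effective range of 30 µm to well
within 25%.

`morans_i()` reports the classical index with inverse-distance (optionally
bandwidth-cut) or binary weights, its null expectation $-1/(n-1)$, and a
z-score under randomization. Both the raw index and the z-score are
reported deliberately: the raw index is bounded near ±1, so
"autocorrelation intensity" numbers well above 1 reported by some
geostatistics packages are comparable only on the z-score scale.

`ordinary_kriging()` interpolates the Z-variate on a regular grid
(spacing = window/100, local neighborhoods of the k = 16 nearest cells),
solving the standard ordinary-kriging system per node; with a zero nugget
the surface is exact at the data. Duplicate cell locations would make the
system singular and are jittered by half a pixel with a warning.
`isopleth_contours()` draws marching-squares contours (default: interior
quintiles of the predicted surface), and `autoplot()` renders the
weather-map-style figure.

## Dual-reporter communication analysis

`calling_distances()` pairs every sensor (green) cell with its nearest
source (red) cell. The default distance is centroid-to-centroid at single
pixel resolution; `mode = "boundary"` measures minimum pixel-to-pixel
separation between the segmented cell bodies, because "shortest linear
distance" is ambiguous for extended cells. An optional ROI mask excludes
cells (e.g. those attached to root hairs) before matching.
`calling_summary()` reports the 1-µm-binned frequency distribution, its
modal bin and maximum. `expression_histogram()` bins per-cell mean
luminosity (default 16-level bins over 0–255) and reports occupied bins and
modal structure (local maxima after 3-bin smoothing).

## What the synthetic generators emulate

The generators provide ground truth for every stage and are all
seed-deterministic.

* `gen_poisson()` — CSR, conditional on n by default so simulation
  batteries have fixed sample size.
* `gen_thomas()` — aggregation: Poisson parents (intensity κ per µm²;
  parents simulated in a 4σ-buffered window for stationarity), Poisson(µ)
  offspring displaced by an isotropic Gaussian (sd σ). An optional
  hard-core radius `r_min` thins offspring so no two centroids come closer
  than a cell width. This matters for the cluster index: real cells are
  extended objects, so `nnd1` is bounded below by the cell diameter; a pure
  point process allows arbitrarily close pairs whose `1/nnd1` explodes,
  which buries the spatial autocorrelation of the cluster index under
  heavy-tailed within-cluster noise. With `r_min` set to one cell width the
  cluster-index variogram behaves like the field data it emulates — its
  effective range tracks the cluster radius σ (about 4.6 µm at σ = 2 µm,
  growing monotonically with σ in the validation suite).
* `gen_hardcore()` — regularity by sequential inhibition with radius
  `r_min`.
* `gen_spatial_field()` — a Gaussian random field with known variogram
  (Cholesky factorization), for variogram/kriging validation.
* `render_cells()` — anti-aliasing-free disks; overlapping disks merge, and
  the truth table records which rendered component each generated cell
  landed in, so intended vs merged counts are comparable. Disk-shaped cells
  only: at the magnifications emulated, cocci and short rods are
  near-circular, and rod rendering is deferred.
* `gen_communication_scene()` — red source disks and green sensor disks
  whose luminosity follows $L(d) = \mathrm{round}(L_{max} e^{-d/d_0})$,
  with sensors beyond `d_thresh` inactive at a dim baseline. Defaults:
  200 × 200 µm field at 0.2 µm/px (a typical confocal montage field),
  cell radius 1 µm (short *Pseudomonas*-like rods), $L_{max} = 255$,
  $d_0 = 20$ µm (spreads the 8-bit dynamic range over the observed
  distance scale), `d_thresh` = 63 µm (the upper end of reported in-situ
  calling distances), baseline 40 (dim but above the color-segmentation
  margin, so inactive sensors remain detectable). Positions are drawn with
  a hard core of two radii plus one pixel and an inset of one radius from
  the field edge, so cells never overlap or clip — the regime in which
  segmentation can recover every cell individually and end-to-end recovery
  can be required to be exact to a pixel.

What the generators deliberately do **not** emulate: optics (point-spread
function, noise, uneven illumination), cell shape variation, 3-D structure,
and within-cell intensity gradients. Tests passing on these scenes
therefore validate the measurement chain and the statistics, not robustness
to imaging artifacts — on real micrographs, segmentation quality is the
user's responsibility.

## Validation problem sizes

The simulation batteries shipped with the package use: 200 CSR replicates
of n = 200 in 100 × 100 µm for the index calibration (Holgate 0.5 ± 0.02,
Clark & Evans 1 ± 0.05, Hopkins–Skellam 1 ± 0.10); 100 Thomas replicates
(κ = 10 clusters/mm², µ = 20, σ = 2 µm, 1 mm² window) for aggregation
detection; 500 CSR replicates for test size; 20 pooled replicate fields for
variogram recovery; and 100 source + 150 sensor cells for the end-to-end
communication pipeline. These sizes put Monte-Carlo error comfortably below
the tolerances being checked while keeping a full run in minutes on one
core.

One honest caveat from that validation: the event-based Holgate ratio
statistic has almost no power against Thomas clustering (its expectation
under dense Gaussian clusters stays near 0.5 because the pattern is locally
Poisson inside a cluster). It reliably crosses its 0.5 threshold only for
patterns with strong between-cluster isolation structure; on Thomas scenes
the other three indices carry the detection. This mirrors how small its
printed exceedances over 0.5 tend to be on real biofilm data.

## A worked run

```{r}
p <- gen_thomas(kappa = 1e-5, mu = 20, sigma = 2,
                window = c(1000, 1000), seed = 42)
nb <- neighbor_table(p)
summary(nb$nnd1)
csr_tests(p, seed = 1)
```

```{r}
geo <- dplyr::mutate(p, z = nb$cluster_index)
vm <- fit_variogram(empirical_variogram(geo))
glance(vm)
morans_i(geo)
```

```{r, fig.width=6, fig.height=5}
sc <- gen_communication_scene(100, 150, seed = 8)
img <- sc$image
sources <- extract_objects(segment_color(img, "red"), img, "red")
sensors <- extract_objects(segment_color(img, "green"), img, "green")
rec <- calling_distances(sources, sensors, calibration = 0.2)
calling_summary(rec)
autoplot(calling_summary(rec))
```

## Known limitations

* 2-D only: X|Y projections, no confocal stacks or 3-D distances.
* Isotropic variograms only; no co-kriging or anisotropy.
* Ripley's K / pair-correlation functions are out of scope; the battery is
  deliberately the nearest-neighbor index family.
* The color-segmentation dominance rule assumes well-separated fluorophores;
  spectral overlap requires external unmixing first.
* The Holgate index's low power against diffuse clustering (above) is a
  property of the statistic, not of the implementation.
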