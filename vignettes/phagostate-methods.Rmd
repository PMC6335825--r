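---
title: "Quantifying phagocytic state: models, conventions and design choices"
author: "phagostate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phagocytic state: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagostate)
```

# The scientific problem

Brain myeloid cells (microglia, infiltrating macrophages) change the
intracellular distribution of their lysosomes as phagocytosis progresses:
during active target internalization lysosomes cluster against the plasma
membrane, where they fuse with phagosomes; during terminal digestion and
autophagy they disperse toward the cell interior. With a membrane marker
(e.g. CD11b) defining the cell outline and a lysosomal marker (e.g. CD68) or
fluorescent beads carrying the cargo signal, superresolved dual-channel
images let this redistribution be quantified per cell. `phagostate`
implements that quantification as a tested, reusable pipeline, and ships a
ground-truthed simulator so every stage can be validated without microscope
data.

The pipeline computes four families of per-cell measurements:

1. **GLCM texture.** The gray-level co-occurrence matrix $p(i,j)$ is the
   normalized count of ordered 8-bit gray-level pairs observed at a fixed
   pixel offset (default $(dx, dy) = (1, 0)$: step size 1 pixel, direction
   0°) with both endpoints inside the traced outline. From it,
   $\mathrm{ASM} = \sum_{ij} p(i,j)^2$,
   $\mathrm{IDM} = \sum_{ij} p(i,j) / (1 + (i-j)^2)$, and
   $\mathrm{entropy} = -\sum_{ij} p(i,j)\,\ln p(i,j)$ (with $0 \ln 0 = 0$).
   Clustered signal means a pixel's neighbour tends to share its gray
   level: ASM and IDM rise, entropy falls.
2. **Membrane-distance shells.** The traced outline is rasterized, the
   inward Euclidean distance transform computed from its background-facing
   edge, and the mask partitioned into bands $(0,100]$, $(100,300]$,
   $(300,500]$, $(500,700]$ and $(700,\infty)$ nm. The fraction of
   integrated density (sum of gray values) in each band localizes the
   lysosomal signal relative to the membrane.
3. **Shape descriptors.** Circularity $4\pi A / P^2$ and solidity
   $A / A_{\mathrm{hull}}$ control for the possibility that texture
   differences merely reflect cell morphology.
4. **Bead uptake.** Beads are segmented by thresholding, labeled with
   8-connectivity, and counted by the centroid rule inside the cytoplasm
   and inside the 700 nm membrane band; time-lapse counts assemble into an
   uptake curve.

# The synthetic cell model

`generateCell()` draws one cell from a forward model whose defaults are the
acquisition conditions the pipeline targets: square 1024 px rasters at
0.030 µm/pixel, 16-bit camera with signal kept inside its 0–16000 linear
range. For live-cell bead imaging the natural settings are 0.036 µm/pixel,
14-bit, 0–4000 range (`pixelSizeUm`, `bitDepth`, `spotAmplitude`).

* **Membrane contour.** By default a smoothed random star-convex contour: a
  periodic radial spline through 12 knots with ±25 % radial jitter around
  0.30 × image size, rotated by a random phase. Star-convex randomness
  avoids the circular-symmetry artifacts a disk would induce in shell
  tests; an explicit polygon can be supplied instead. The rendered membrane
  channel is a bright ~2 px band along the contour.
* **Spot placement.** `nSpots` lysosomes/beads are placed by a two-component
  mixture: a fraction $\varphi$ (`clusteringFraction`) is drawn uniformly
  from the region with inward membrane distance ≤ `proximalBandNm`
  (default 700 nm) by rejection sampling; the remainder is uniform over the
  whole interior. The expected fraction of spots within the band is
  therefore $\varphi + (1-\varphi)\,a$, where $a$ is the band's area
  fraction — the identity the parameter-recovery tests check.
* **Spot rendering.** Each spot is an isotropic 2D Gaussian with
  $\sigma = 60$ nm (a 100–200 nm object imaged at ≈130 nm resolution),
  integrated analytically over each pixel rather than point-sampled, so
  integrated-density fractions do not depend on sub-pixel phase. Real
  lysosomal intensity distributions are unknown; the simulator uses a
  single nominal amplitude with ±20 % uniform jitter, a deliberate,
  flagged simplification.
* **Noise.** Poisson shot noise on the rendered signal plus additive
  Gaussian camera noise (offset 100, sd 20 gray values by default) on the
  whole frame, rounded and clipped — never wrapped — to the bit depth. The
  offset-to-sd ratio is chosen so clipping at zero is vanishingly rare, as
  it is in a correctly exposed camera; a large sd relative to the offset
  would pile clipped pixels at gray level 0 and distort the histogram-mode
  background estimator.
* **Determinism.** All randomness derives from `seed`; identical specs
  give bit-identical rasters and ground truth. The default-contour draws
  are consumed from the stream even when a polygon is supplied, so spot
  placement is invariant to how the contour was provided.

## The uptake time course

`generateTimelapse()` models saturating internalization: the expected
count at time $t$ (minutes after bead exposure) is
$C\,(1 - e^{-r t / C})$ with rate $r$ (beads/min) and capacity $C$. Frames
start at `firstFrameMin` (default 20 — beads are typically added ~20 min
before the first acquisition) and advance by `frameIntervalMin` (default
30). Realized counts use a latent-arrival construction: each of the $C$
latent beads holds a fixed uniform draw and becomes (and stays)
internalized once the saturating probability exceeds it. This makes counts
exactly monotone within a realization and capacity-bounded, with the
closed-form mean above; the marginal law is binomial rather than Poisson,
a modelling choice we prefer because persistence and the capacity bound
hold by construction instead of by truncation. With $C = 120$ and
$r = 2.285$/min the means at 20′ and 170′ are ≈38 and ≈115 beads,
magnitudes chosen to mirror a realistic LPS-stimulated microglia culture;
rate 0 models the unstimulated control. Internalized beads keep their
positions across frames; each frame receives fresh camera noise.

## What the simulator does and does not emulate

The simulator reproduces the statistical structure the analysis relies on:
membrane-proximal vs. interior-uniform positioning, sub-resolution spots,
Poisson–Gaussian camera statistics, stated bit depths and pixel sizes, and
saturating uptake. It does not attempt nuclei, multi-cell fields, 3D
stacks, structured-illumination stripe artifacts, PSF anisotropy, spatially
varying background, or lysosomes of heterogeneous size and brightness.
Passing tests therefore demonstrate correctness of the measurement code
and recoverability of planted spatial structure — not robustness to every
feature of real micrographs (uneven illumination and segmentation errors
chief among them).

# Analysis conventions and numerical choices

* **Raster geometry.** Rasters are matrices indexed [row, col] = [y, x];
  pixel $(r, c)$ has its centre at $(c - 0.5,\ r - 0.5)$. A pixel belongs
  to a polygon mask iff its centre is inside under the even-odd rule, so
  an axis-aligned square with integer corners $(10,10)$–$(20,20)$
  rasterizes to exactly 100 pixels.
* **8-bit conversion.** $v \mapsto \lfloor 255\,(\mathrm{clip}(v, lo, hi) -
  lo)/(hi - lo)\rfloor$ with the window defaulting to the acquisition
  range (0–16000 or 0–4000), not the full bit range; $hi$ maps to 255.
* **Background.** A single level estimated as the histogram mode (default)
  or a percentile, over pixels outside the ROI when a mask is available;
  ties break toward the lower gray value; results are floored at zero.
* **GLCM.** Directed (not symmetrized) with the single offset (1, 0) by
  default; symmetrization is available but off. Only pairs with both
  endpoints in the mask count, which keeps background outside the outline
  from inflating homogeneity. The matrix stays 256 × 256 (no re-binning).
  Entropy uses the natural logarithm; the base affects scale, never
  ordering.
* **Shells.** Distance is measured from the ROI's outer (background-facing)
  boundary; boundary pixels take $d$ = half a pixel, a symmetric
  convention given that sub-pixel exactness is unattainable on a raster.
  Band edges 100/300/500/700 nm are read as cumulative distances (band
  thicknesses 100/200/200/200 nm) plus the > 700 nm remainder. Band $k$ is
  closed on its outer edge: $e_{k-1} < d \le e_k$.
* **Density fractions** are computed on raw background-subtracted
  intensities; being ratios, they are invariant to any affine rescaling,
  so computing them before or after 8-bit conversion changes nothing
  material.
* **Perimeter.** The obvious crack-length estimator (unit steps with
  $\sqrt2$ diagonals) overestimates a digital disk's perimeter by ≈5 %,
  which would push disk circularity down to ≈0.90. We instead trace the
  Moore 8-chain through boundary pixel centres and apply
  Vossepoel–Smeulders corrected weights (0.980 per axial step, 1.406 per
  diagonal, −0.091 per corner), adding $\pi$ for the half-pixel outward
  offset between the centre polygon and the true crack boundary (exact for
  convex shapes). A digital disk of radius 50 px then measures
  circularity 0.998; a 100 × 25 px rectangle 0.528 against the analytic
  0.503.
* **Solidity.** The convex hull is taken over boundary-pixel corners, so
  the hull always contains the mask and solidity never exceeds 1.
* **Bead counting.** 8-connectivity (via a 4-connected pass plus
  union-find merging of diagonal contacts); touching beads merge — an
  acknowledged undercount, as declumping is out of scope. Membership is by
  intensity-weighted centroid; a centroid exactly on a band edge belongs
  to the band. A bead whose centroid falls within half a pixel of the
  outline can rasterize just outside the ROI mask and is then excluded by
  the centroid rule — the deliberate resolution of an ambiguous case.
* **Statistics.** Two-group comparisons use the Welch t test by default
  (group variances in this kind of data are rarely equal; the pooled
  Student test is available via `varEqual`). Band-fraction profiles use a
  two-way group × band ANOVA with Šidák-adjusted post hoc group contrasts
  within each band; the post hoc adjustment is parameterized rather than
  fixed. No mixed models: per-animal nesting is reported by aggregating
  records, not modelled.

# Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixelSizeUm` | 0.030 (tissue), 0.036 (live) | µm/px | acquisition pixel size; converts EDT pixels to nm |
| `window` | (0, 16000) / (0, 4000) | gray | camera linear range used at acquisition |
| `edgesNm` | 100, 300, 500, 700 | nm | cumulative shell edges from the membrane |
| `offset` | (1, 0) | px | GLCM step (1 px, 0°) |
| `clusteringFraction` | — | 0–1 | simulator mixture weight (φ); the recoverable parameter |
| `proximalBandNm` | 700 | nm | proximal placement band |
| `spotSigmaNm` | 60 | nm | rendered spot width under ≈130 nm resolution |
| `uptakeRate`, `capacity` | 2.285, 120 | beads/min, beads | saturating uptake curve |

# Problem sizes used in validation

The test-suite and acceptance computations use: full 1024 px study
conditions for the paired clustering contrast (20 seed pairs) and for
parameter recovery (2000 spots); 512 px rasters for the nine simulated
time lapses (a 18 µm live-cell field comfortably holding one microglia);
96–320 px rasters for oracle comparisons and unit fixtures, where the
properties under test are scale-free. Shell assignments are checked
exactly against a brute-force boundary-distance oracle on masks up to
128²; GLCMs against full pair enumeration on 8 × 8 images.

# Known limitations

* Texture contrasts between moderately different clustering regimes (e.g.
  φ = 0.70 vs 0.45) are small relative to per-cell variability at n = 20;
  the within-700 nm density fraction is the far more powerful readout, and
  the paired φ = 1 vs φ = 0 contrast is what the directional acceptance
  checks use.
* Otsu thresholding on a bead-free (control) frame bisects the noise; for
  control counting use a fixed threshold above the noise ceiling, as any
  practical assay does.
* The manual outline is trusted: no automatic membrane segmentation, no
  correction for tracing error.
* 2D only; a 3D cell sectioned at one plane under- or over-represents
  membrane-proximal volume depending on the section.
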