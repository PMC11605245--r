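---
title: "Quadrant darkfield: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant darkfield: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdf)
```

## The physical picture

Darkfield microscopy illuminates the sample from outside the objective's
acceptance cone, so only light that the sample redirects into the objective
forms the image. Two very different processes redirect that light:

* **Large refracting structures** — the edge of a cell or a bead — act as
  local lenses. By Snell's law the refracted ray leaves in a direction set
  by the local surface normal, so under illumination from one azimuthal
  sector the edge signal appears only on the side of the object facing away
  from that sector.
* **Small puncta** — organelles in the 100 nm to 1 µm range such as
  melanosomes — scatter in the Mie regime with a broad cone and little
  azimuthal preference. Their signal is nearly the same whichever sector
  the light comes from.

Quadrant darkfield (QDF) exploits this asymmetry. Four darkfield images are
captured under illumination from the four quadrants of an LED annulus
(top-left, top-right, bottom-left, bottom-right). Pixel-wise:

$$DF = TL + TR + BL + BR$$
$$E = |TL - BR| + |BL - TR|$$
$$QDF = c \cdot DF - E$$

Directional edge light arrives under only one of each diagonally opposed
illumination pair, so it survives the absolute differences and populates
the edge image $E$; broadly scattered puncta light is common to both
members of a pair and cancels out of $E$. Subtracting $E$ from a scaled
darkfield therefore removes edges and keeps puncta. The scaling factor $c$
is system-specific, typically 0.8–1.0: residual diffraction from the far
side of an object puts a little edge energy into quadrants where the
simple refraction picture predicts none, making the darkfield edge signal
slightly exceed $E$.

## Calibrating c

`calibrate_c()` fits $c$ by least squares over a set of edge pixels,
minimizing $\sum (c\,DF - E)^2$, giving the closed form
$c = \sum DF\,E \,/\, \sum DF^2$. The pixel set matters: the package
defaults to pixels where $E$ exceeds its 95th percentile among
positive-$E$ pixels, and accepts an explicit mask (the phantom ground
truth in tests). This least-squares definition is this package's own
choice of operationalization; published descriptions of the method state
only that $c$ is determined experimentally by matching edge intensities.

Negative values of $QDF$ arise wherever $E > c\,DF$ (noise, imperfect
calibration). The package keeps signed images internally — they are
diagnostic — and clips at zero only where the value is interpreted as
puncta signal: per-cell totals (`per_cell_signals()`) and display.

## The phantom simulator

Real acquisitions of the kind the method was developed on are not
reproducible at a desk, so every downstream stage is exercised on a
parametric forward model (`scene()`, `render_quadrants()`):

* Each object deposits its total `amplitude` (counts) over a Gaussian
  profile — cross-section σ equal to the edge `width` for boundaries, spot
  σ for puncta — normalized after truncation so the deposited photon
  budget is exact.
* A single anisotropy parameter $g \in [0,1]$ interpolates linearly
  between isotropic ($g=0$: a quarter of the light to each quadrant image)
  and fully directional ($g=1$: all light to the image whose illumination
  quadrant opposes the local outward normal). This deliberately replaces
  the full Mie phase function: one parameter is enough to span the two
  regimes the reconstruction distinguishes, and the reconstruction itself
  never sees the phase function, only the four integrals.
* The convention is fixed once: a pixel whose outward normal points toward
  the top-left receives its directional light under bottom-right
  illumination. Pixels whose normal lies exactly on an image axis split
  evenly between the two adjacent quadrants — this keeps the diagonal
  pairs balanced, so the $E$ and $QDF$ identities are unaffected by the
  tie-break.
* An optional `leak` parameter redistributes a fraction of the directional
  light isotropically, modelling the weak symmetric diffraction from the
  object's far edge. Effective directionality is $g(1-\mathrm{leak})$; on
  edge pixels this makes $E = g(1-\mathrm{leak}) \cdot DF$ exactly, which
  is what gives phantoms a known effective $c$ for calibration tests.
* Background (flat plus an optional polynomial surface up to order 8),
  seeded Gaussian read noise, clipping to the camera range and integer
  quantization are applied last. Shot noise and fixed-pattern noise are
  deliberately out of scope; additive Gaussian noise plus quantization is
  the simplest model consistent with a CMOS camera at high gain.

What the simulator does **not** emulate — coherent diffraction, defocus,
the true Mie angular spectrum, vignetting — bounds what passing tests
mean: they validate the reconstruction arithmetic, the calibration, the
quantification chain and the statistics under the stated forward model,
not the optics of any particular microscope.

### Study phantoms

Three phantom suites mirror the method's canonical experiments
(`demo_datasets()`):

* **Beads** (20 µm at 0.5 µm/px → radius 20 px): a clean bead whose ring
  should vanish in QDF, and an "imperfect" bead with an internal isotropic
  punctum that must survive.
* **Shape change**: one cell interpolating a shape parameter $s$ from 0.1
  (flat) to 0.9 (rounded) over 5 frames. Radius shrinks as
  $R_0(1-0.4s)$, edge brightness grows as $A_0(1+1.5s)$ (rounded edges
  refract more), puncta amplitudes are constant and their positions
  contract with the cell. Edge and puncta budgets (12 000 vs 15 000
  counts at $s=0$) are comparable, as in cells; the rendered sequence
  moves total darkfield by ~50% while total QDF stays within a few
  percent — the shape-invariance property.
* **Two populations** (200 cells each in the standard comparison): radii
  lognormal (meanlog log 15 px, sdlog 0.15), per-cell puncta counts
  Poisson with mean density × area at densities 0.01 vs 0.03 puncta/px²
  (a 3× pigmentation-like contrast), punctum amplitude 300 counts,
  per-cell edge brightness lognormal with mean 4×10⁴ counts and sdlog
  0.8. The wide edge dispersion is the point: per-cell darkfield totals
  are dominated by edge brightness, whose biological variability swamps a
  3× puncta difference (the expected two-sample t statistic is near 1),
  while QDF totals isolate the puncta and separate the populations by
  orders of magnitude in p-value. Population quantification subtracts an
  empty-reference stack first; without it the flat background times cell
  area dominates every per-cell total.

## Preprocessing

The conditioning chain follows standard darkfield practice: optional bit
rescaling (divide by 16 and round to nearest, ties away from zero — the
documented camera convention; base R's `round()` would round ties to
even), empty-reference subtraction (floating point, negatives preserved),
and masked polynomial background removal. The background model is a full
bivariate basis of total degree ≤ 8 (45 terms) over coordinates
normalized to $[-1,1]^2$ for conditioning, solved by QR least squares on
non-object pixels only; the surface is then evaluated everywhere and
subtracted. Beyond 10⁵ background pixels the fit uses a deterministic
uniform subsample — it is vastly over-determined and the surface smooth.
Whether the polynomial removal applies to the quadrant images, the edge
image, or both is left configurable (`preprocess_stack()` applies it per
quadrant by default); the literature describes masking both without fixing
a dataflow.

## Segmentation, tracking, quantification

Cells are segmented from the quantitative phase image: Gaussian smoothing
(σ = 2 px), foreground mask at 0.2 rad, intensity watershed
(`EBImage::watershed`) to split touching cells, minimum area 50 px. All
parameters are exposed; these defaults suit the phantom geometry and are
stated here as package defaults, not universal constants.

Dry mass uses the standard QPI relation
$m = \sum \varphi \cdot \frac{\lambda}{2\pi} \cdot A_{px} / \alpha$ with
the cell-average specific refractive increment
$\alpha = 1.8\times10^{-4}\,\mathrm{m^3/kg}$; mass per area serves as the
shape proxy in the signal-versus-shape analysis.

Tracking links centroids frame to frame by minimum total squared
displacement with a maximum displacement gate (default 20 px) and
short-gap memory (default 1 frame). Candidate sets up to 9×9 are solved
exactly by branch-and-bound (maximize links, then minimize cost); larger
sets fall back to greedy nearest-neighbour. On the phantom scale every
frame is solved exactly.

Debris filtering only flags records (area bounds, track length, mean
phase/DF/QDF minima) — nothing is deleted, mirroring the practice of
reviewing rather than silently discarding segmentations.

The puncta SNR estimator thresholds each QDF image at 4× the 99th
percentile of the background (all pixels outside 3-px-dilated labels,
excluding a 5-px border), takes the mean above-threshold QDF per cell as
signal and the background standard deviation as noise. A zero-variance
background is an error, not a zero.

## Statistics

The shape-dependence test regresses signal per mass on mass per area and
compares against the constant-y (zero-slope) null with
$F = (SS_{flat}-SS_{fit})/(SS_{fit}/(n-2))$ on $(1, n-2)$ degrees of
freedom. Descriptions of this test sometimes say "a flat line parallel to
the y-axis", which literally denotes a vertical line; the conventional
null is the horizontal constant-y line and that is what is implemented.
Fits delegate to `lm()`; the test suite checks them against from-scratch
normal-equation oracles at 10⁻¹⁰.

The Kullback–Leibler divergence between two per-cell signal distributions
histograms both samples on shared edges spanning the pooled 1st–99th
percentile range (32 bins; outliers clamp into the end bins), then mixes
a uniform weight of 10⁻³ into the frequencies before computing
$D_{KL}(P\|Q)=\sum p_i \log_2 (p_i/q_i)$ (bits). Smoothing in frequency
space, rather than adding pseudo-counts, guarantees exactly zero
divergence for identical binned distributions regardless of sample sizes
while still keeping empty bins finite. The two-sample t-test is the
pooled-variance classic (Welch by flag), with degenerate zero-variance
inputs resolved explicitly.

## Digital baseline

The comparison baseline blurs the darkfield image (σ = 2 px), detects
edges with Sobel or Canny (thresholds parameterized as fractions of the
99th-percentile gradient magnitude for cross-image comparability; Canny
includes non-maximum suppression and hysteresis), dilates the mask with a
disc and zeroes the masked pixels. The sweep scores every
threshold × dilation point by the fraction of true edge signal that
survives and the fraction of true puncta signal retained. On phantoms
whose puncta are at least as bright per pixel as the edge ring — the
regime reported for cells — no grid point reaches QDF's edge suppression
without also destroying puncta, because any gradient threshold low enough
to catch the whole ring fires on the much sharper puncta first.

## Problem sizes and numerics

The test suite and acceptance script run phantoms at 64–160 px canvases,
5-frame sequences, and 200-cell populations; these sizes make every
property measurable in seconds while keeping the Poisson/lognormal
sampling regimes honest. All image arithmetic is double precision
regardless of input bit depth; quadrant stacks round-trip TIFF as 16-bit
integer samples, and real-valued reconstructions are stored as 32-bit
TIFF scaled into [0, 1] with a JSON sidecar recording offset and scale
(the portable way to keep negative values exact through `tiff`). All
randomness flows from explicit integer seeds; rendering the same scene
twice is bit-identical.

## Known limitations

* The anisotropy model is phenomenological; it cannot predict how $c$
  depends on wavelength, NA or particle size distribution — only that a
  stable effective $c$ exists, which is what the reconstruction needs.
* Segmentation defaults assume isolated-to-moderately-touching rounded
  cells; dense monolayers would need tuned seeds and thresholds.
* Tracking has no division/lineage handling; a dividing cell starts a new
  track.
* Per-punctum detection is out of scope: the method quantifies total
  puncta signal per cell, not counts.
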