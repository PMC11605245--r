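# qdf — quadrant darkfield reconstruction and puncta quantification

Label-free darkfield microscopy sees two things at once: bright rings from
the refracting edges of cells, and the speckle of small intracellular
puncta (melanosomes and other sub-micron organelles). The edge signal
dominates and tracks cell *shape*, so total darkfield intensity is a poor
readout of organelle *content*. Quadrant darkfield (QDF) separates the two
computationally: four darkfield images are captured under illumination
from the four quadrants of an LED annulus, and combined pixel-wise as

```
DF  = TL + TR + BL + BR
E   = |TL − BR| + |BL − TR|
QDF = c·DF − E
```

Edge light is refracted directionally (Snell's law), so it reaches the
camera under only one of each diagonally opposed illumination pair and
survives in the edge image `E`; puncta scatter broadly (Mie regime), are
seen equally by all four quadrants, and cancel out of `E`. Subtracting `E`
from the scaled darkfield leaves the puncta. The scaling factor `c`
(typically 0.8–1.0) absorbs residual symmetric diffraction and is
calibrated by least squares on edge pixels.

The package is aimed at quantitative microscopists: it implements the
reconstruction and `c` calibration, the preprocessing chain (bit
rescaling, empty-reference subtraction, masked order-8 polynomial
background removal), watershed single-cell segmentation from quantitative
phase images with dry-mass conversion (`m = Σφ·(λ/2π)·A_px/α`,
α = 1.8×10⁻⁴ m³/kg), centroid tracking with gap memory, debris filtering,
a puncta SNR estimator, Sobel/Canny digital-edge baselines, and the
distribution statistics used to compare cell populations (linear fit with
flat-line F-test, Pearson correlation, Kullback–Leibler divergence,
two-sample t-test). A parametric phantom simulator with per-object
scattering anisotropy provides ground truth for every stage; see the
methods vignette (`vignettes/qdf-methods.Rmd`) for the model and design
choices.

## Worked example

Simulate an "imperfect" 20 µm bead — a strongly directional edge ring
(`g = 0.9`) enclosing an isotropic punctum — subtract an empty reference,
calibrate `c`, and reconstruct:

```r
library(qdf)

sc <- scene(
  canvas_shape = c(96, 96),
  boundaries   = boundary_circle(48, 48, radius = 20, amplitude = 5e4,
                                 g = 0.9, is_cell = FALSE),
  puncta       = punctum(44, 52, amplitude = 5e3, radius = 1.5),
  background_level = 30, noise_sigma = 2, seed = 1
)
r   <- render_quadrants(sc)
ref <- render_quadrants(scene(c(96, 96), background_level = 30,
                              noise_sigma = 2, seed = 99))$stack
st  <- preprocess_stack(r$stack, reference = ref, poly_order = NULL)

(c_hat <- calibrate_c(st, r$truth$edge_mask))
#> c = 0.9263  (residual edge energy 2.5%, 1396 px)

(rec <- compute_qdf(st, c = as.numeric(c_hat)))
#> <qdf_reconstruction> 96x96 px, c = 0.9263
#>   DF range [-21, 349], QDF range [-34.45, 322.3]

edge <- r$truth$edge_mask; punc <- r$truth$puncta_mask
cat(sprintf("edge residual: %.1f%%   punctum retention: %.1f%%\n",
    100 * mean(pmax(rec$qdf[edge], 0)) / mean(rec$df[edge]),
    100 * mean(rec$qdf[punc]) / (as.numeric(c_hat) * mean(rec$df[punc]))))
#> edge residual: 4.9%   punctum retention: 88.1%
```

The calibrated `c` recovers the phantom's effective directionality; after
subtraction the bead ring keeps under 5% of its darkfield intensity while
the internal punctum keeps ~88% of its scaled darkfield signal —
`autoplot(rec)` shows the ring vanish between the DF and QDF panels. Note
the calibration is run *after* reference subtraction: a flat background
offset biases the least-squares `c` badly.

From here, `segment_cells()` + `per_cell_signals()` turn phase and QDF
images into a per-cell tibble, `track_cells()` links frames,
`fit_vs_flat()` / `kl_divergence()` / `two_sample_t()` compare
populations, and `run_pipeline()` does all of it over an on-disk dataset
(see `demo_datasets()` for ready-made bead, shape-change and
two-population phantom suites). A thin command-line front end over these
functions ships in `inst/cli/qdf.R`.

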