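---
title: "Quantifying membrane nanoclustering: anisotropy, FCS and GP methods in ndimg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane nanoclustering: anisotropy, FCS and GP methods in ndimg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndimg)
```

## The measurement problem

GPI-anchored proteins (GPI-APs) form nanoscale clusters in the outer
leaflet of the plasma membrane. The clusters are far below the optical
diffraction limit, but they leave a photophysical signature: when
identical fluorophores sit within Förster distance of each other, energy
migrates between them (homoFRET), the emission dipole decorrelates from
the excitation dipole, and the steady-state fluorescence emission
anisotropy drops. `ndimg` implements the image-analysis chain that turns
dual-channel polarized TIRF movies into that signature — plus the
companion measurements a nanoclustering study leans on: fluorescence
correlation spectroscopy (FCS) of cortical-actin probes, Laurdan
generalized polarization (GP) maps of membrane order, segmentation of
adhesion-associated protein clusters, and their spatial correlation with
anisotropy.

Because raw microscope data for such studies are rarely portable, the
package ships a synthetic-scene generator (`make_polarized_scene()` and
friends) that is the *exact forward model* of each analysis: every
generator inverts the formula its analysis applies, carries a
`SceneTruth` record, and is deterministic under a seed. All tests and the
acceptance script run against these scenes.

## Emission anisotropy from polarized channel pairs

The microscope records the parallel (`Ipa`) and perpendicular (`Ipe`)
emission components. After background subtraction (buffer image,
negatives clipped) and affine registration of `Ipe` onto `Ipa`, the
per-pixel anisotropy is

$$ r = \frac{I_{pa} - G\,I_{pe}}{I_{pa} + 2\,G\,I_{pe}} $$

where the G-factor $G$ is the pixelwise detection-sensitivity ratio of
the two channels, measured on an isotropic fluorescein solution
(`compute_gfactor()`, `g = Ipa/Ipe`). For nonnegative channels $r$ is
confined to $[-0.5, 1]$, with $r = 0$ when the corrected channels are
equal and $r = 1$ when the perpendicular channel vanishes.

Decisions a user should know about:

* **Registration** (`estimate_registration()`): translation + rotation +
  isotropic scale, seeded by regularized phase correlation and refined by
  Nelder–Mead on the normalized cross-correlation. The similarity is
  scored on an interior window (default margin 8 px) because resampled
  border pixels carry fill values; the optimizer parameters are expressed
  in pixels/degrees/percent so simplex steps are commensurate. If
  alignment does not improve the similarity, the identity transform is
  returned with a warning flag. A precomputed transform can be passed to
  `apply_registration()` directly (bilinear interpolation, zero fill,
  border pixels excluded via the support mask).
* **ROI statistics** (`roi_anisotropy()`): ROIs are the ~2×2 µm squares
  drawn on intensity-flat membrane. Each ROI's anisotropy is computed
  from its *summed* channel intensities (photon-weighted), which is how
  extracted ROI intensities combine; the mean-of-pixel-r alternative is
  available via `method = "pixelmean"` for sensitivity analysis. On
  uniform regions the two coincide exactly.
* **Thresholding and smoothing**: the total intensity is
  $I_{pa} + 2GI_{pe}$; pixels at or below the threshold are masked. The
  2-D averaging filter (window 3 or 5) exists for map rendering only —
  ROI statistics always read the unsmoothed field. The threshold is
  applied after G-factor correction.
* **Coordinates** are 1-based with inclusive rectangles, the R and
  EBImage convention (rather than 0-based half-open indexing), so region
  objects compose naturally with matrix subscripting.
* **Pixel size** defaults to 0.0977 µm/px (a 512×512 EMCCD field of
  ~50×50 µm at 100× magnification).

## Photobleaching homoFRET analysis

In a nanocluster-rich membrane, photobleaching removes energy-transfer
partners, so anisotropy rises approximately linearly as intensity falls;
the extrapolated anisotropy at complete bleaching is the monomer value.
`bleach_analysis()` normalizes each ROI's total intensity to its first
(un-bleached) frame, pools `(I/I0, r)` pairs across ROIs, bins them in
`I/I0` (10 equal bins by default), fits
$r = a\,(1 - I/I_0) + r_{start}$ to the bin means over
`I/I0` in `[0.2, 1]` by ordinary least squares, and reports the
asymptote $a + r_{start}$. The fit window and bin count are parameters;
the linear form mirrors the observed linear rise, and extrapolation
beyond the last measured bin is deliberate (complete bleaching is never
reached in practice). With the generator's defaults (start 0.19, monomer
0.23, 30 frames at 10% bleaching per frame, Poisson + 2 ADU read noise)
the asymptote is recovered within ±0.01.

```{r bleach-example}
ser <- make_bleach_series(poisson = TRUE, read_noise_sd = 2, seed = 1)
rois <- lapply(seq(0, 9), function(j)
  region_rect(1 + (j %% 3) * 21, 1 + (j %/% 3) * 16, 16, 16))
bleach_analysis(ser, regions = rois)
```

## Spreading kinetics, trace alignment, kymographs

During integrin-driven spreading, nanocluster formation (an anisotropy
drop) precedes the peak of cell expansion. `spreading_kinetics()`
segments the cell per frame (threshold + largest connected component,
optional edge erosion — whole-cell anisotropy is insensitive to eroding
up to 20 px on uniform cells), and emits area, whole-cell photon-weighted
anisotropy, and their between-frame differences. The anisotropy change is
also normalized by the trace's anisotropy range (`d_r_norm`) so cells
with different dynamic ranges can be pooled; the raw difference is kept
alongside, since no canonical normalization exists for this quantity.

Two estimators summarize a trace: the area-change peak is the maximum of
the 3-point-median-smoothed `d_area` (ties to the earliest frame), and
the anisotropy-drop time is the weighted centroid of negative `d_r`
within a window around the smoothed minimum — a centroid, because the
drop spreads over several frames and a bare argmin is degenerate under
noise. `align_traces()` shifts traces so their area-change peaks sit at
$t = 0$ and averages them in time bins (mean ± SEM). The generator's
spreading movie uses a logistic area curve (15 s frames) with the
anisotropy-drop midpoint 150 s before the growth peak; both times are
recovered within one frame under the default noise.

`kymograph()` samples a 3-pixel-wide line per frame (width-averaged,
photon-weighted anisotropy) and stacks position × time.

## FCS: triplet × two-component diffusion model

Intensity traces from a confocal spot are correlated into
$G(\tau) = \langle \delta I(t)\,\delta I(t+\tau) \rangle / \langle I \rangle^2$
by a multi-tau correlator (`autocorrelate()`; 16 linear lags, then
octave-wise coarsening by 2 — the hardware-correlator scheme; lags up to
a tenth of the trace). The model (`fcs_model()`) is

$$ G(\tau) = \frac{1}{N}\,G_T(\tau)\,G_D(\tau),\qquad
   G_T = 1 + \frac{T}{1-T} e^{-\tau/\tau_T} $$

$$ G_D = f\,\Big(1+\frac{\tau}{\tau_{D1}}\Big)^{-1}
         \Big(1+\frac{\tau}{S^2 \tau_{D1}}\Big)^{-1/2}
       + (1-f)\Big(1+\frac{\tau}{\tau_{D2}}\Big)^{-1} $$

with $N$ the mean particle number, $T$/$\tau_T$ the dark-state fraction
and lifetime, $f$ the fast (free, 3-D) fraction with diffusion time
$\tau_{D1}$, $\tau_{D2}$ the slow (filament-bound, 2-D) time, and $S$
the structure factor of the detection volume, fixed at 0.2 by default —
freeing it in fits of synthetic curves generated at the default recovers
≈0.2, which is why fixing it is safe. Component identity is enforced by
default bounds ($\tau_{D1}$ 0.3–3 ms, $\tau_{D2}$ 10–200 ms, both
relaxable) and by the post-fit ordering convention
$\tau_{D1} < \tau_{D2}$.

`fit_acf()` runs Levenberg–Marquardt on log/logit-transformed parameters
(five orders of magnitude separate $N$ from $\tau_T$; raw-scale LM stalls
at box bounds) with a small deterministic multi-start over the
fast-component window, keeping the lowest-RSS solution. Weights are
$1/\mathrm{sd}$ when per-lag SDs exist, else uniform on the log-spaced
grid. Fits run per trace or on averaged curves — both are just
`ACFCurve` objects. `qc_trace()` discards traces with linear drift
(> 10% of the mean over the trace) or bursts (rolling 100 ms mean more
than 5 SD high); thresholds are parameters since no canonical values
exist.

The correlator's independent oracle is a two-state telegraph emitter
(`make_blinking_trace()`) whose normalized ACF is
$(k_{off}/k_{on}) e^{-(k_{on}+k_{off})\tau}$ in closed form.

## Laurdan generalized polarization

Membrane order is read out ratiometrically from two spectral channels of
the solvatochromic probe Laurdan (ordered ~435 nm, disordered ~504 nm):

$$ GP = \frac{I_{Ch1} - G\,I_{Ch2}}{I_{Ch1} + G\,I_{Ch2}} $$

The channel G-factor comes from a reference solution of known GP
(conventionally 0.207 for Laurdan in DMSO):

$$ G = \frac{GP_{ref} + GP_{ref}GP_{mes} - GP_{mes} - 1}
            {GP_{mes} + GP_{ref}GP_{mes} - GP_{ref} - 1} $$

which factorizes as $(1-GP_{ref})(1+GP_{mes}) \big/
\big((1-GP_{mes})(1+GP_{ref})\big)$ — an exact closed-form inverse, so
recomputing the reference GP with the calibrated G returns $GP_{ref}$ to
machine precision for any channel imbalance. When the reference is an
image, `gp_mes` is taken as the intensity-weighted (summed-channel) GP.
ROI GP follows the same photon-weighted convention as ROI anisotropy.

## Blob segmentation and spatial correlation

Adhesion/cluster segmenters in this field are often lab-internal
routines; `segment_blobs()` specifies the procedure transparently:
Gaussian smoothing (σ = 1 px), global Otsu (or user) threshold, optional
intersection with an Otsu-thresholded Sobel gradient-magnitude mask,
hole filling, connected components, minimum size 4 px. All parameters
are exposed, and Otsu makes labels invariant to intensity scaling.
`adhesion_areas()` reports per-blob areas in µm²;
`anisotropy_in_masks()` extracts photon-weighted anisotropy inside each
blob and in the pooled outside region.

For ligands immobilized on chromium line grids (~100 nm lines, 2 µm
apart) under a supported lipid bilayer, the bilayer is excluded on the
lines, so the marker intensity dips there. `pattern_rois()` detects dip
columns (column means below median − 2·MAD, grouped), placing 1×4 µm
rectangles on the lines and 2×2 µm squares at inter-line midpoints;
detection assumes axis-aligned patterns and otherwise requires an
explicit `pattern_layout()`. `aligned_line_profiles()` normalizes each
~1 µm marker line profile to its own maximum, aligns profiles at the
marker peak, and bins partner intensity and anisotropy on the signed
distance axis (the flank-binning by marker level that inspired it is
under-specified; distance binning is what an aligned profile needs and
the bin width is a parameter). `cluster_average_image()` averages
cluster-centred crops after mirroring them so the pattern always lies
left; anisotropy is computed channel-first on the averaged crops, then
3-pixel mean filtered.

## What the generators emulate — and what they do not

The generators reproduce the *statistical structure the analyses
assume*: channel formation by exact inversion of the anisotropy/GP
formulas, detection-ratio imbalance, affine channel misalignment,
additive background, Poisson photon noise and Gaussian read noise
(default σ = 2 ADU), linear bleach laws, logistic spreading, telegraph
blinking, heteroscedastic ACF noise. They deliberately do *not* simulate
the homoFRET photophysics itself — clusters are assigned a depolarized
anisotropy ($r_{clust} < r_{mono}$) rather than modelled photon-by-photon
— nor realistic cell morphologies, scattering halos, or detector
artifacts beyond the above. Passing tests therefore demonstrate that the
*analysis chain* is correct and unbiased under its stated noise model,
not that any biological claim holds on real data.

## Numerical choices and degenerate inputs

* Background subtraction clips negatives (keeps $r$ physical); it is
  idempotent once applied.
* G-factor reference pixels below 1% of the median `Ipe` are imputed
  with the median G and flagged.
* Intensity-bin edges: a value on an interior right edge joins the lower
  bin; the lowest edge is inclusive. Empty bins report count 0, mean NA.
* Empty ROIs are skipped with a message, never abort a batch; an empty
  segmentation is a valid result, an empty *cell* mask is an error with
  threshold diagnostics.
* Degenerate registration inputs (constant images, no similarity
  improvement) return a flagged identity rather than failing.
* All problem sizes in tests and the acceptance script (64–200 px
  scenes, 10–50 seeds, 10–20 s traces) were chosen so the full suite
  runs in well under a minute while keeping Monte-Carlo error far below
  each tolerance.

## Known limitations

* Registration assumes a similarity transform (no shear/anisotropic
  scale); full-affine channel distortions would need an external
  transform supplied to `apply_registration()`.
* The multi-tau correlator averages within octaves; for very short
  traces the late-lag estimates are noisy, and the package does not
  implement symmetric-normalization bias corrections.
* Pattern detection requires axis-aligned line grids.
* FRAP analysis, conversion of diffusion times to filament lengths, and
  hypothesis testing across experimental conditions are out of scope;
  standard R tests (`kruskal.test`, `wilcox.test`) apply directly to the
  ROI tables the package emits.
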