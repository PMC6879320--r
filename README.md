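# ndimg

Quantitative imaging of membrane-protein nanoclustering. `ndimg` is an R
package for laboratories that use emission-anisotropy TIRF microscopy
(EA-TIRFM) to detect nanoscale clustering of GPI-anchored proteins and
related membrane components, together with the companion measurements
such studies rely on: FCS of cortical-actin dynamics, Laurdan membrane
order, and spatial correlation of anisotropy with adhesion-protein
clusters.

## What it computes

**Emission anisotropy.** Nanoclusters placed within Förster distance
exchange energy between identical fluorophores (homoFRET), which
depolarizes emission. From registered, background-subtracted polarized
channel pairs the package computes the per-pixel anisotropy

    r = (Ipa − G·Ipe) / (Ipa + 2·G·Ipe)

with the G-factor `G = Ipa/Ipe` calibrated on an isotropic dye image.
Lower `r` means more clustering. ROI statistics use photon-weighted
(summed-intensity) anisotropy over ~2×2 µm regions, with
intensity-binned summaries.

**Photobleaching homoFRET curves.** Bleaching removes FRET partners, so
`r` rises linearly as intensity falls; `bleach_analysis()` fits
`r = a·(1 − I/I0) + r_start` to intensity-binned data and extrapolates
the monomer anisotropy at `I/I0 → 0`.

**Spreading kinetics.** Whole-cell anisotropy and area per frame,
between-frame changes, alignment of multiple cells at their peak area
change, and position×time kymographs along 3-pixel lines.

**FCS.** A multi-tau correlator and the triplet × two-component
diffusion model `G(τ) = (1/N)·G_T(τ)·G_D(τ)` with a 3-D free component
(diffusion time τD1, structure factor S = 0.2) and a 2-D bound component
(τD2), fitted by constrained Levenberg–Marquardt with trace QC.

**Laurdan GP.** Per-pixel generalized polarization
`GP = (ICh1 − G·ICh2)/(ICh1 + G·ICh2)` with the closed-form G-factor
calibration against the conventional reference GP of 0.207.

**Spatial statistics.** Blob segmentation (vinculin clusters, paxillin
adhesions) with per-blob areas, anisotropy inside/outside cluster masks,
nanopattern ROI placement from intensity dips, peak-aligned line
profiles, and cluster-centred average images.

**Synthetic scenes.** Every analysis has an exact forward model
(`make_polarized_scene()`, `make_bleach_series()`, `make_fcs_curve()`,
`make_blinking_trace()`, `make_gp_scene()`, `make_pattern_scene()`,
`make_spreading_movie()`) carrying full ground truth and deterministic
under a seed, so the whole pipeline is testable without microscope data.

## Worked example

Simulate a photobleaching series of a mixed monomer/nanocluster
membrane (anisotropy 0.19 at full intensity, monomer limit 0.23), then
recover the monomer anisotropy by extrapolation:

```r
library(ndimg)

ser  <- make_bleach_series(poisson = TRUE, read_noise_sd = 2, seed = 1)
rois <- lapply(seq(0, 9), function(j)
  region_rect(1 + (j %% 3) * 21, 1 + (j %/% 3) * 16, 16, 16))
bleach_analysis(ser, regions = rois)
#> BleachCurve: slope 0.0386, r(I/I0=1) = 0.1902, asymptote r(I/I0->0) = 0.2288
```

The fitted start (0.1902) matches the simulated unbleached mixture and
the asymptote (0.2288) recovers the monomer anisotropy of 0.23 within
the method's ±0.01 tolerance — on real data this convergence is the
signature that homoFRET, not dye photophysics, caused the low starting
anisotropy.

Fit the FCS model to a noisy synthetic curve (truth: N = 2, T = 0.15,
τT = 50 µs, f = 0.7, τD1 = 1 ms, τD2 = 50 ms, S fixed at 0.2):

```r
curve <- make_fcs_curve(fcs_params(), noise_sd = 0.01, seed = 1)
fit_acf(curve)
#> FCSFit (converged): N = 2.05, T = 0.172, tauT = 5.02e-05 s, f = 0.693,
#>   tauD1 = 0.00106 s, tauD2 = 0.0502 s, S = 0.200, RSS = 0.000652
```

All parameters are recovered within a few percent; `tauD2` is the
actin-bound diffusion time a dynamic-actin study reads out.

A thin command-line wrapper lives at `inst/cli/ndi.R`
(`Rscript ndi.R run --config pipeline.yaml`); `write_defaults()` dumps
every tunable default as YAML.

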