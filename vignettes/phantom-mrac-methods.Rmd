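---
title: "Simulating phantom-specific MRI-based attenuation correction for PET/MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phantom-specific MRI-based attenuation correction for PET/MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phantomAC)
```

## The problem

Quantitative PET requires attenuation correction (AC): every line of
response must be compensated for the photon attenuation
$\exp(-\int \mu \, dl)$ along it, with $\mu$ the linear attenuation
coefficient at 511 keV. On PET/MRI systems the $\mu$-map is derived from MR
images, but conventional phantom housings (PMMA and similar) give no MR
signal, so MR-based AC ignores them and PET values inside the phantom are
biased low. A phantom printed from an MRI-visible polymer changes this: the
housing appears in standard two-point Dixon images (at roughly one third of
the water signal) and can be segmented into its own $\mu$ class.

`phantomAC` implements that whole experiment as a reproducible simulation:

1. a parametric digital model of the cylindrical resolution phantom
   (`default_phantom_spec()`, `rasterize()`);
2. a two-point Dixon MR simulator and a co-registered synthetic CT
   (`simulate_dixon()`, `simulate_ct()`);
3. the threshold/morphology segmentation and the four competing AC maps
   (`total_phantom_mask()`, `water_mask()`, `build_phantom_mrac()`,
   `build_standard_mrac()`, `build_nowall_mrac()`, `ct_to_mu()`);
4. an attenuated parallel-beam forward model and OSEM reconstruction
   (`make_projector()`, `forward_project()`, `osem_reconstruct()`);
5. the ROI bias evaluation against the CT-AC reconstruction
   (`percent_difference()`, `make_roi()`, `roi_stats()`).

`run_experiment()` chains all stages under one seed-bearing configuration.

## Phantom geometry

The phantom is a water-fillable cylinder (252 mm outer diameter, 6 mm
polymer shell, 10 mm top and 5 mm bottom lid) whose inner compartment is
240 mm wide and 185 mm long. A Jaszczak-style array of solid polymer rods
(diameters 5, 10, 13, 17, 22, 28 mm; 50 mm long) stands on the bottom lid,
one 60° sector per diameter with rods spaced one diameter edge-to-edge.
The published dimension set is slightly over-determined — a 19 cm outer
length cannot contain an 18.5 cm compartment between 10 + 5 mm lids — and
since the water compartment and the lids are what drive PET quantification,
those are kept exact and the outer length is the derived 200 mm.

Rod positions are not printed anywhere, so the sector layout is generated
by `jaszczak_rod_layout()` and fully exposed in `phantom_spec()`: any other
layout can be supplied as a `data.frame(x, y, diameter)`.

Voxelization is anti-aliased: each voxel is probed on a `subsampling`^3
sub-grid (default 3, a compromise between anti-aliasing and speed), the
majority label is stored, and the exact material/water volume fractions are
kept for partial-volume simulation. Coordinates are right-handed, z along
the cylinder axis, z = 0 at the outer bottom face, everything in mm, voxel
boxes half-open.

## Dixon simulation

Per voxel the complex gradient-echo signal at echo time $TE$ is

$$ S(TE) = B(x)\,\bigl(w\,W e^{i 2\pi f_w TE} + p\,P e^{i 2\pi f_p TE}\bigr), $$

with $w, p$ the water/polymer volume fractions, $W$ the water amplitude,
$P = W/3$ the polymer amplitude, and $f$ the chemical-shift frequencies of
water (4.8 ppm) and the polymer's main resonance (3.5 ppm) at the true
field of a "3 T" system (2.894 T, ~123.2 MHz). At the product echo times
(1.23/2.46 ms) the 1.3 ppm water–polymer pair is far from its opposed/
in-phase condition (that would need 3.39/6.78 ms), so pure polymer ends up
in the Dixon *water* image — exactly the failure that makes the vendor map
treat the whole phantom as soft tissue — while partial-volume voxels at the
material/water border dephase and produce the "fat" contrast the
segmentation exploits. The two-point magnitude recombination used is
`water = (IP + OP)/2`, `fat = |IP − OP|/2`; the vendor's actual algorithm
is proprietary, and the polymer relaxation times (T1 = 194 ms, T2 = 32 ms)
are folded into the amplitude ratio rather than simulated dynamically.

Additional image structure, all tunable in `dixon_sim_params()`:

* **Intensity scale.** Scanner units are arbitrary; `water_signal = 1000`
  puts polymer (~333) between the published segmentation thresholds
  (object > 100, water > 400), reproducing the separability the method
  relies on.
* **Bias field.** A radial receive/excitation profile
  $B(r) = 1 - (1-b_{\min})(1 - (r/R)^2)$ with $b_{\min} = 0.7$ at the
  centre emulates the reported global signal drop toward the middle of a
  25 cm water load at 3 T; the magnitude is not printed, 30% is a typical
  standing-wave depth for this geometry. Even at $b_{\min}$ the water stays
  above the 400 threshold, as it must for the published thresholds to work.
* **Point-spread function.** The product Dixon volumes are low-resolution,
  apodised and interpolated; this is modelled as a Gaussian PSF applied to
  the complex signal (in-plane FWHM in pixels, plus a slice-profile FWHM
  along the slice normal — slices overlap, which is why extent errors are
  worst across slices). The default (4 px / 4 slices) is calibrated once so
  the threshold-100 object mask overestimates the true extent by about one
  voxel — the behaviour the segmentation's 1-voxel erosion is documented to
  compensate — and the same setting reproduces the reported ~1-pixel inward
  overestimation of the material extent.
* **Noise.** Complex Gaussian noise per echo (Rician magnitudes), default
  SNR 40 in water; noise levels are not printed. Bias evaluation runs
  noiseless (`noiseless = TRUE` in the experiment config) so results are
  deterministic.
* **Tissue swaps.** Random spherical patches inside the material exchange
  the fat/water channel values, emulating the tissue-swap-like artifacts
  observed in the housing. Because both segmentation thresholds act on the
  opposed-phase/fat pair in a way those swaps cannot cross, they do not
  propagate into the phantom MR-AC — an invariant the tests assert.
* The Dixon slice normal is perpendicular to the phantom axis (the MR-AC
  sequence is acquired coronally), so the slice-select axis of the Dixon
  grid is x; the grid spacing is the printed 2.6 × 2.6 mm² in-plane with
  3.1 mm slices.

The synthetic CT mixes −1000 HU (air), 0 HU (water) and the material value
by volume fraction; the material default is the HU whose bilinear mapping
yields 0.1037 cm⁻¹, so a noise-free CT-AC reproduces the published
coefficients exactly away from borders.

What the simulator does *not* model: k-space sampling and Gibbs ringing,
eddy-current phase errors, actual B0 inhomogeneity (swaps are imposed, not
emergent), CT beam hardening, and the vendor's proprietary fat–water
decomposition. Tests passing on this generator therefore validate the
segmentation and reconstruction logic under controlled conditions; they do
not certify behaviour on arbitrary real scans.

## Segmentation and the four AC maps

Following the published recipe, on the Dixon grid:

* **Total phantom**: opposed-phase > 100 a.u. → morphological closing →
  largest connected component → isotropic 1-voxel erosion.
* **Water**: fat image smoothed in-plane (Gaussian, σ = 0.5 px), values
  < 10 zeroed, subtracted four times from the opposed-phase image, then
  > 400 a.u. and closing.
* **Material**: total minus water.

Structuring elements are not printed; the defaults are a 6-connected
radius-1 cross for closing/erosion (applied `radius` times) and
26-connectivity for components, all exposed in `segmentation_params()`.
The closing radius default is 1: it fills isolated sub-threshold voxels (its
documented purpose) while leaving multi-pixel holes open. A radius of 2
would swallow the 5–13 mm rods into the water mask, contradicting the
reported rod visibility in the AC maps.

Masks are built on the Dixon grid, moved to the reconstruction grid by
nearest-neighbour resampling (which preserves binary labels), and the μ
values are assigned there: water 0.096 cm⁻¹, material 0.1037 cm⁻¹
(phantom MR-AC); material zeroed (NoWall); whole object dilated by one
voxel and set to 0.1 cm⁻¹ (standard MR-AC emulation — on the 2.09 mm
reconstruction grid that dilation is the reported ~2 mm extent
overestimation). The CT map uses the standard 120 kVp bilinear scaling,
9.6×10⁻⁵ cm⁻¹/HU below 47 HU and 5.1×10⁻⁵ cm⁻¹/HU above, the high-segment
intercept fixed by continuity; 0 HU ↦ 0.096 cm⁻¹.

## Forward model and reconstruction

The acquisition is modelled slice-wise in 2-D parallel-beam geometry: the
bias under study is an attenuation line-integral effect, and a 2-D model
preserves it (including the long tangential chords through the shell that
drive the near-wall bias) at desktop cost. A sparse system matrix over
48 uniform view angles is built once per grid by Joseph-style ray sampling
(half-pixel steps, bilinear interpolation; weights carry path length in
mm); the noiseless sinogram is the activity ray transform times
$\exp(-\int\mu_{\text{true}}\,dl)$ with the ground-truth μ-map from the
anti-aliased label fractions, and Poisson sampling is available (seeded)
for robustness experiments. What the model omits — oblique 3-D lines of
response, scatter and randoms and their corrections, detector
normalisation — is the main reason the simulated NoWall/standard biases
sit a few points below the measured ones; sign, ordering and approximate
magnitude are preserved.

Reconstruction is OSEM with the chosen AC map's attenuation factors
multiplicative in the system model: 3 iterations, 24 angular subsets
(stride partition; 48 angles ⇒ 2 per subset), uniform positive
initialisation on voxels seen by at least one ray, and a 5-mm FWHM Gaussian
post-filter — the published protocol. With neither randoms nor scatter
simulated, the "ordinary Poisson" variant reduces to plain OSEM. Ratios are
guarded by a relative floor (`epsilon`, 10⁻¹²·max(y)); voxels with zero
sensitivity stay zero; nonnegativity is preserved by construction. On
noiseless data the Poisson log-likelihood is non-decreasing over full
iterations (provably for one subset, empirically for 24 — asserted in the
tests).

The default reconstruction grid is the clinical 344 × 344 matrix at
2.09 mm with 3.1 mm slices: the reported ROIs are defined in pixels of that
grid, so matching it keeps the "5 pixel" bands at their ~10 mm physical
width. A coarser grid (e.g. 172 × 172 at 4.18 mm) runs the whole pipeline
in under a minute for exploration, at the price of wider bands and a
blunter near-wall dip.

## Evaluation protocol

Voxel-wise %-difference images `100·(test − ref)/ref` are computed against
the CT-AC reconstruction on the water support: CT-AC μ within
[0.090, 0.100) cm⁻¹, inside the largest connected phantom component, eroded
by one voxel to drop border partial-volume voxels (reference voxels ≤ 0 are
excluded and tallied). ROIs: the whole water compartment; single axial
slices through the middle of the rod-free region (homogeneous) and of the
rod array (heterogeneous), chosen from the label volume; and 5-pixel bands
of water adjacent to the material (8-connected in-plane dilation of the
CT-derived material support). `roi_stats()` reports mean ± SD; the SD is
the population SD (divide by n) by default with a `sample_sd` switch, since
the published tables do not state which was used. Line profiles
(`line_profile()`, trilinear interpolation) are provided for visual
inspection of the AC maps and reconstructions; rod-resolution scoring is
deliberately not automated.

## Numerical and design notes

* Problem sizes: the default end-to-end run rasterizes the Dixon grid
  (90 × 108 × 86 at 3.1/2.6/2.6 mm, chosen to hold the phantom with at
  least three voxels of air margin so morphology never touches the array
  border) and the 344 × 344 × 68 reconstruction grid, and takes roughly
  8 minutes on one CPU; unit tests use a geometrically similar ~100 mm
  phantom.
* Determinism: one master seed drives the Dixon noise/swaps, CT noise and
  Poisson sampling (derived per-stage seeds); repeated runs are
  bit-identical, and the written CSV/NIfTI artifacts carry the config's
  MD5.
* Ties in the majority-vote rasterizer resolve background > material >
  water, which keeps 90° rotations of a centred, rod-free phantom
  voxel-exact.
* Degenerate inputs error early with stage names (`empty phantom mask`,
  `grid too small`, `invalid subset partition`, `empty ROI`).

## Known limitations

* 2-D slice-wise transport without scatter: absolute NoWall/standard biases
  are reproduced only approximately (see above); the phantom MR-AC bias,
  which is a *difference* of nearly identical maps, is insensitive to this.
* The Gaussian PSF + slice-profile model is a stand-in for the true system
  response; its width is calibrated to the reported segmentation behaviour
  rather than measured.
* Real-data use assumes co-registered, axis-aligned NIfTI volumes; no
  registration is provided.
* The segmentation thresholds are the published ones and are meaningful
  only on the simulator's intensity scale (or after rescaling real data
  accordingly), mirroring the original method's phantom-specific tuning.
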