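---
title: "Spectral photon-counting CT: simulation, correction and reconstruction with pcctk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral photon-counting CT: simulation, correction and reconstruction with pcctk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pcctk)
```

# The system being modelled

pcctk implements the processing chain of a dual-threshold photon-counting
cone-beam micro-CT: a microfocus 80 kV source (0.5 mm Al filtration), a
counting detector with two energy thresholds at 15 and 30 keV, and a
circular orbit with source-to-isocenter distance 140 mm and
source-to-detector distance 325 mm. Each acquisition yields a *Total*
(15--80 keV) and a *High* (30--80 keV) count frame per view; the *Low* bin
(15--30 keV) is derived by subtraction, `Low = Total - High`. Each pixel
carries a 12-bit counter, so recorded counts saturate at 4096. A full-scale
frame is 2063 channels by 505 effective rows (513 physical rows with four
cropped from each edge); an orbit has 1440 views at 0.25 degrees.

Since real scans of this class run to hundreds of gigabytes, the package
pairs every processing stage with a physics-based simulator that emits
scans in the instrument's exact file and folder conventions, so the chain
can be exercised end to end on a laptop and validated against known ground
truth.

# The simulator

**Spectrum.** An analytic thin-target bremsstrahlung shape, fluence
proportional to `(kvp - E)` below the tube voltage, hardened by
Beer--Lambert attenuation through the aluminium filter. Characteristic
lines are omitted: no stage of the chain depends on line structure. The
photon budget (total fluence per pixel per view) is a free parameter,
default 3000, which keeps flat fields inside the detector's usable
`[1, 4000]`-count window; the true instrument budget is set by exposure and
tube current and is not recoverable without the hardware.

**Materials.** Mass-attenuation tables live on a 1 keV grid over 10--120
keV and are queried by cubic interpolation (exact at the nodes, no
extrapolation). The bundled tables come from a two-component analytic
model -- a photoelectric term falling as `E^-3` plus a Compton term
following the Klein--Nishina total cross-section shape -- pinned per
material at 20 and 60 keV near tabulated values for water, PMMA, aluminium
and hydroxyapatite. Walnut shell and pulp are synthetic stand-ins (no
reference data exists for them), given a deliberate spectral contrast
(shell more photoelectric) so that the shell/pulp decomposition matrix has
condition number around 11: ill-conditioned enough to need denoising, well
short of degenerate. All bundled tables are shipped as plain TSV
(`inst/extdata/*_synthetic.tsv`); measured tables in the same format can be
dropped in.

**Phantoms.** Four builders, all pure functions of `(kind, params, seed)`:
a walnut-like specimen (triaxial ellipsoidal shell, default outer diameter
36 mm and thickness 2 mm, enclosing irregular pulp lobes and air cavities
generated from seeded blob noise), a uniform water cylinder for HU
calibration, a PMMA holder with three hydroxyapatite rods (50/100/200
mg/cm^3, modelled as HAP loading in a water-equivalent matrix), and
PMMA/aluminium slab stacks.

**Forward projection and detection.** Rays are traced source-to-pixel with
an exact Siddon traversal, giving per-material intersection lengths.
Expected counts follow the polychromatic Beer--Lambert sum over the
spectrum restricted to the bin threshold; recorded counts are Poisson
draws clipped to the counter ceiling. The slab calibration series uses
analytic slab paths (`thickness / cos` of the ray obliquity), since the
physical slabs cover the whole beam.

**Detector defects.** The gain map is a smooth low-order polynomial field
times per-tile offsets times per-pixel log-normal jitter. Two further
mechanisms matter, because a multiplicative gain identical at flat-field
and scan time cancels *exactly* in air correction and would leave the
correction chain nothing to do:

* *threshold dispersion* -- per-pixel offsets on the energy thresholds
  (default sd 0.4 keV, with tile structure). The resulting count error
  depends on how much the object hardens the spectrum, so it survives
  flat-fielding as a signal-dependent non-uniformity. This is the error
  the polynomial calibration exists for.
* *gain drift* -- a small multiplicative change between flat acquisition
  and object scan (default log-sd 0.01). It survives flat-fielding as a
  static additive offset in the log projections, which backprojects into
  concentric rings. This is the error the ring correction exists for.

Stuck pixels (readings pinned near 0 or near the ceiling) complete the
defect model. Charge sharing, pile-up and focal-spot blur are not
modelled.

# The correction chain

Order of operations: bin subtraction (counts) -> air correction ->
polynomial non-uniformity correction -> bad-pixel interpolation -> ring
correction, each bin treated independently from air correction onward.

**Air correction** converts counts to log projections,
`P = -ln(I_obj / I_air)`, with numerator and denominator clamped at one
count so zero readings stay finite. The low bin is clipped at zero counts
before the log (counts are physical), with a clip counter kept as
telemetry.

**Non-uniformity calibration** follows the two-stage
calibrate-then-correct design. Calibration scans are flat attenuators:
every combination of PMMA (0, 5, 10, 15, 20, 30, 40 mm) and aluminium (0,
0.5, 1, 1.5, 2, 3, 4, 5 mm), 56 scans, each an average of 600 frames. For
each scan and bin, a full 2-D second-order polynomial surface (six terms,
coordinates normalized to [0,1]) is least-squares fitted over the frame;
the residual from that surface is the pixel's uniformity error. Each
pixel then gets a 5-coefficient polynomial in its own multi-energy
signals, `e = c0 + c1 S_T + c2 S_H + c3 S_T^2 + c4 S_H^2` (S_T, S_H the
air-corrected Total/High log signals), fitted across the slab scans by
least squares. The 5-term basis matches the released coefficient-table
shape (rows x channels x 5); the instrument's exact basis is not public,
so this is a documented compatible stand-in. Correction subtracts the
predicted error from every frame, using each frame's own Total/High pair
as predictors. Note the correction must be applied once: the predictors
are barely changed by the subtraction, so a second application of the same
table would subtract the error again; the meaningful idempotence (tested)
is that recalibrating on corrected frames finds essentially nothing.

**Bad pixels** are the union of a prior table and any pixel reading below
5 or above 4090 counts in any frame (strict inequalities). They are
replaced by 1-D linear interpolation along the detector row, nearest good
value at row edges.

**Ring correction** estimates the static log-domain error: split the
views into M contiguous-angle subsets (default 8); average each subset;
2-D median filter the subset mean (default window 3 rows x 9 channels --
narrow across rows, wide along channels, since rings are
channel-structured); per-subset error = mean - smoothed; pixel-wise median
across subsets (rejects residual object structure, and makes the estimate
independent of subset order); subtract a wide Gaussian (default sigma 10
pixels) of that map as the background bias so only the high-frequency
ring-forming component is removed; optionally restrict to a channel
window. Published ring-correction methods of this family state no kernel
values; these defaults are this package's own and are all configurable.

# Reconstruction and Hounsfield calibration

FDK filtered backprojection for the circular orbit: detector coordinates
rescaled to the virtual detector through the isocenter, cosine (fan +
cone) pre-weighting, per-row ramp filtering via FFT with zero-padding to
the next power of two past twice the channel count (the band-limited
Ram--Lak impulse response transformed exactly, optionally apodized by a
Hann window -- the default), then distance-weighted voxel-driven
backprojection with bilinear detector interpolation, scaled by the angular
step and the full-scan 1/2 factor. Short scans are rejected. Output is
linear attenuation per mm; the absolute scale was verified against an
analytic cylinder line-integral oracle (agreement within 0.1% at desk
scale, tested at 3%).

The mid-detector row is assumed to hold the central ray: the instrument's
geometric calibration procedure is not public, so no tilt/offset model is
fitted.

**TV denoising** is the Rudin--Osher--Fatemi model, `min 1/2||x - x0||^2 +
w TV(x)` with isotropic 3-D TV, solved by Chambolle's dual projection
(step 1/12 for the 3-D gradient operator), fixed iteration count, default
100 iterations. The weight is `lam` in per-mille of the volume's robust
dynamic range (0.1--99.9 percentile spread), so `lam = 20` -- the
reference pipeline's value -- acts comparably on attenuation and HU
volumes; the reference implementation's internal normalization for that
value is not published, so this scale is this package's own, documented
choice.

**HU calibration** scans a water cylinder through the same chain and takes
`scale = 1000 / mean(mu)` over an interior ROI, per bin; conversion is
`HU = mu * scale - 1000` (water 0, vacuum -1000). The evaluation ROI used
in the shipped metrics is deliberately *wider* (radius 14 mm) than the
calibration ROI (radius 10 mm), and both are restricted to the axial range
the cone beam samples (80% of the axial FOV), so the reported water HU
mean measures residual non-uniformity rather than the calibration
identity.

# Spectral processing

Decomposition works in water-normalized attenuation, `NA = HU + 1000`
(the scale where the mixture algebra is exact): the Low/High NA pair of
each voxel is a 2x2 linear map of the two basis-material densities, and
decomposition is the per-voxel inverse, reported in mg/cm^3 with negative
excursions kept (clipping would bias recovery statistics; their fraction
is reported). The Low/High pair is used because those bins do not overlap
spectrally.

The shell/pulp matrix is calibrated the way the real calibration table is
described: from the average CT values of the segmented components of a
reconstructed specimen. Critically, the calibration specimen is a
*separate* walnut (different seed) from the volume being decomposed --
calibrating from the same volume would make region-mean recovery an
algebraic identity -- and bulk cylinders of shell material are *not* used,
because 36 mm of bulk material hardens the low bin by roughly 80 HU
relative to the 2 mm shell in situ, which propagates to ~40% density
error through the ill-conditioned inverse. Matched calibration geometry
keeps the spectral shift comparable and brings recovery to within ~1% at
desk scale.

Virtual monoenergetic images use the water/HAP basis: `mu_E =
mu/rho_water(E) rho_water + mu/rho_HAP(E) rho_HAP` with cubic-interpolated
tables, converted to HU against water's linear attenuation *at the same
energy*, so pure water reads 0 HU at every synthesis energy (the
alternative -- a fixed reference bin -- would make water drift with E;
the per-energy reference is the documented choice).

# Problem sizes and study conditions

The full-scale geometry (2063 x 505, 1440 views, 1000 x 1000 x 300
volumes) is available behind the `scale = "full"` profile. The shipped
tests and the acceptance script run the desk profile: 256 x 64 detector
(0.75 mm pitch), 180 views over 360 degrees, 96^3 phantom grids at 0.5 mm
-- the sizes at which every stage's property can be measured in minutes on
one CPU. Unit tests use a further-reduced micro profile (32 x 16, 24--36
views, 32^3); at that grid the 2 mm shell is under one reconstructed
voxel thick, so quantitative density recovery there is asserted on the
resolved pulp only, with the shell checked at desk scale.

The ring-efficacy experiment isolates its mechanism: gain drift only, no
threshold dispersion, no noise, ring correction alone, and the ring-power
metric (variance of the high-pass component of the angular-mean radial
profile, with a quadratic-preserving Savitzky--Golay radial smoother)
evaluated inside the flat interior of the cylinder -- the phantom's sharp
edge contributes identically to corrected and uncorrected slices and
would otherwise dominate the ratio.

# What the synthetic data does and does not show

The simulator reproduces the features the correction chain is built for:
polychromatic beam hardening, bin nesting, Poisson counting statistics,
saturation, tile-structured response errors, signal-dependent
non-uniformity, static ring-forming offsets, stuck pixels, and the exact
file conventions. It does not model charge sharing, pulse pile-up,
scatter, detector lag, focal-spot blur, or anatomically realistic
specimens. Passing tests therefore demonstrate the correctness of the
processing chain under the stated error model, not instrument-grade
image quality on real scans; in particular, spectral distortions from
charge sharing would degrade real decomposition accuracy beyond what the
synthetic recovery numbers suggest.

# Numerical choices

* Air-correction clamp: one count (keeps `P` finite and the inverse
  identity exact on clamped values).
* Surface and per-pixel fits: QR least squares; rank-deficient per-pixel
  designs fall back to the pseudoinverse, and calibration refuses series
  with fewer than six scans or a rank-deficient mean design.
* Threshold dispersion uses fractional weighting of the boundary 1 keV
  energy bin, so counts are continuous in the threshold offset.
* FDK ramp filter: spatial-domain Ram--Lak kernel transformed by FFT
  (exact DC handling); Hann applied multiplicatively in frequency.
* TV solver: fixed 1/12 dual step (the 3-D gradient operator norm bound);
  no stopping tolerance, so results are bit-reproducible.
* All randomness flows from a single seed through documented sub-seeding
  (`derive_seed`), keeping every derived stream below 2^31.
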