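---
title: "Optimizing volume-rendered DBT visualization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing volume-rendered DBT visualization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Digital breast tomosynthesis (DBT) reconstructions are strongly anisotropic:
around 0.085 mm within a slice and 1.0 mm between slices. Rendering such a
stack as a 3D volume exposes the coarse z-direction badly — bright structures
smear into long streaks along z — and the quality of the rendered image then
depends critically on two choices made before and during ray casting: the
interpolation used to bring the grid to isotropic spacing, and the distance
between consecutive samples accumulated along each ray. `dbtvr` implements
the full measurement pipeline for studying those two parameters on a disk
phantom: synthetic phantom generation, z-only resampling with a family of
interpolation kernels, orthographic composite ray casting, and the three
image-quality figures of merit (FWHM, CNR, profile smoothness), plus the
sweep and selection machinery that turns the measurements into a recommended
configuration.

This vignette records the model, its assumptions, the tunable parameters and
their defaults, and the design decisions taken where the procedure was
genuinely open.

## The synthetic phantom

The physical object emulated by `phantom_spec()` / `generate_phantom()` is an
acrylic slab with one column of aluminium disks of diameters 5.0, 3.0, 1.0,
0.5, 2.0 and 4.0 mm, each 1.0 mm thick, with the disk axis along z. Real
scans of such a phantom are not publicly available, so the generator is a
first-class, tested module rather than a data loader. Three stages produce a
volume:

1. **Voxelization** by voxel-center membership: a voxel takes the disk
   intensity exactly when its center lies inside a disk cylinder. No
   antialiasing — the rule is simple enough to test geometrically.
2. **z-spread**: 1-D Gaussian convolution along z only (unit-sum discrete
   kernel truncated at 4 sigma, reflective borders). Real DBT out-of-plane
   blur comes from limited-angle reconstruction, which we deliberately do not
   simulate; a Gaussian reproduces the one property the metrics need, namely
   that 1 mm structures measure far wider than 1 mm along z.
3. **Noise**: additive i.i.d. Gaussian noise, drawn from a private RNG stream
   seeded by the mandatory `seed` field, so identical specs give
   byte-identical volumes and the caller's RNG state is untouched.

Defaults, chosen once as the study conditions:

* grid 384 x 128 x 40 voxels at 0.085 x 0.085 x 1.0 mm. The x extent must
  hold the whole disk column (28 mm of disks and 2.5 mm gaps) with the CNR
  background regions clear of neighbouring disks; y only carries the
  90-degree rays; z matches the slab thickness of a typical compressed
  breast. About 2M voxels — small enough that the complete pipeline runs in
  seconds per configuration on one core, large enough that profiles and ROIs
  have realistic pixel counts.
* intensities: background 0.2, disks 1.0, in arbitrary reconstruction units.
  No reconstructed-unit values are published for acrylic vs aluminium, so the
  scale is arbitrary and config-exposed; every metric is either
  scale-invariant (CNR) or reported in units the transfer function controls.
* `z_spread_sigma = 4` mm, which puts the measured FWHM of the 5 mm disk near
  9.4 mm — the "much wider than the physical 1 mm" regime reported for real
  reconstructions (where a default rendering measures about 12 mm).
* `noise_sigma = 0.015`. The unit-sum z-spread dilutes the 1-mm disk by
  roughly 10x, leaving an effective disk amplitude of about 0.08, so this
  noise level gives a volume-level signal-to-noise ratio of about 5,
  consistent with the modest contrast-to-noise (about 6) published for
  default renderings of the physical phantom.
* disk centers at z = 26 mm, in one column along x with 2.5 mm edge-to-edge
  gaps. Putting the disks at z = 26 mm places the rising edge of the blurred
  profile inside the fixed smoothness window of (16, 24) mm — a region of
  high intensity variation, as the smoothness metric requires.

What the generator does **not** emulate: limited-angle reconstruction
artifacts (streaks, inter-slice ripple, structured noise), breast texture,
the second disk column of the physical phantom, and scanner-specific
intensity scales. Consequences for interpreting results are discussed at the
end.

## z-resampling and the kernel family

`resample_z()` converts 0.085 x 0.085 x 1.0 mm to 0.085^3 mm by interpolating
along z only. Output slices sit on the source's world grid starting at the
first slice (origin preserved, `floor((nz-1) sz / sz') + 1` slices), so disks
keep their world coordinates for the metrics. Out-of-range source indices are
clamped to the edge slices: the resampler never invents data beyond the
measured support.

`kernel_spec()` covers nearest-neighbour (ties toward the lower index),
linear, Catmull-Rom cubic, and windowed sinc with seven windows (Lanczos,
Kaiser, cosine, Hann, Hamming, Blackman, Nuttall). Two parameters shape the
windowed-sinc family:

* **window half-width** `W` (1..16 source samples): half the kernel support;
* **z blur factor** `B` (>= 1): argument scaling `x -> x/B` with support
  widened to `W*B`, i.e. a low-pass filter applied while interpolating.

The windows are the standard signal-processing closed forms (for
`u = (x/B)/W` in [-1, 1]): Lanczos `sinc(u)`, cosine `cos(pi u / 2)`, Hann
`0.5 + 0.5 cos(pi u)`, Hamming `0.54 + 0.46 cos(pi u)`, Blackman
`0.42 + 0.5 cos(pi u) + 0.08 cos(2 pi u)`, 4-term Nuttall, and Kaiser
`I0(a sqrt(1 - u^2)) / I0(a)` with `a = 3` by default (the "shape adjustment
off" setting of common rendering toolkits; the parameter is exposed).
Whether the cubic of the original library is Catmull-Rom or a B-spline
variant is not documented anywhere we could find; Catmull-Rom was chosen as
the common default in rendering toolkits and is documented as such.

Numerical choices: discrete taps are renormalized to unit sum for every
fractional offset, which pins the resampler's DC gain at exactly 1 and
prevents ripple from sinc truncation; taps whose weight is floating-point
residue of a sinc zero (|w| below 1e-14 of the largest tap) are dropped so
that interpolating kernels degenerate cleanly to a single unit tap at
integer positions.

## Rendering

`render()` is an orthographic composite ray caster for the two azimuths the
study needs: 0 degrees (rays along +z, image spans xy, the view parallel to
the detector) and 90 degrees (rays along +y, image spans xz, the view where
z-quality is visible). General rotating cameras reduce, for these two
angles, to axis-aligned ray marching, which is exact and cheap to test
against brute force. Rays start half a sampling distance inside the entry
face and step every `d` mm over the half-open center-to-center span of the
volume. Because each ray passes exactly through in-plane voxel centers,
trilinear sampling reduces to 1-D linear interpolation along the ray axis,
and the whole march vectorizes in lockstep across rays (all rays share their
sample depths), which is why the renderer needs no compiled code.

Samples map through a transfer function — piecewise-linear opacity and gray
ramps, by default linear 0 -> 1 over the volume's [min, max] — and are
composited front to back:

```
alpha_corr = 1 - (1 - alpha)^(d / unit_distance)
I <- I + (1 - A) * alpha_corr * gray
A <- A + (1 - A) * alpha_corr
```

with early termination once `A` reaches 0.999 (configurable). The opacity
correction is essential: it keeps the accumulated opacity of a homogeneous
ray independent of `d`, so a sampling-distance sweep measures sampling
fidelity rather than a trivial opacity change.

Two theoretical quantities frame the sweep: `nyquist_bound()` (the distance
between accumulations must not exceed twice the smallest voxel spacing;
0.170 mm for a 0.085 mm grid) and `auto_sampling_distance()`, the empirical
power law `3580.5 n^-0.621` relating voxel count to the automatic mode of a
standard toolkit (about 0.185 mm at 8M voxels, matching the 0.195 mm
automatic value in the study grid).

The transfer function is the study's largest unknowable: the original work
does not report its opacity/gray ramps or unit distance, which is the
fundamental reason its absolute CNR/FWHM/smoothness values cannot be
reproduced by anyone without the original scan and settings. We therefore
hold one tf fixed across every configuration compared (built once from the
input volume's range). For the sweep defaults the opacity unit distance is
10 mm: the optical mean free path then matches the object depth (about 11 mm
of y for the 90-degree view, 40 mm of z for the 0-degree view), so the disks
are within view depth at both azimuths. With a much shorter unit distance
the background alone saturates the 0-degree rays before they reach the
disks — the measurement degenerates to imaging noise.

## Metrics

All three figures of merit act on the 5 mm disk in the 90-degree image:

* **FWHM** (`fit_fwhm`): a Gaussian `b + A exp(-(z-mu)^2 / 2 sigma^2)` is
  fitted (Levenberg-Marquardt, moment-based initialization, bounded
  restarts) to the z profile through the disk center, and `2 sqrt(2 ln 2)
  sigma` is reported. A background offset `b` is included — rendered
  profiles do not decay to zero — and makes the estimate invariant to
  intensity offset and scale. Lower FWHM = better z definition.
* **CNR** (`cnr`): `(mu_disk - mu_BG) / sigma_BG` with `mu_BG` the mean of
  two background ROI means and `sigma_BG` the mean of their sample standard
  deviations (n-1 denominator, matching the spreadsheet function family the
  field uses for this analysis). Default geometry, since none is published:
  11 x 11 px ROIs, backgrounds flanking the disk along x at +/-1.5 disk
  radii.
* **Smoothness** (`smoothness`): the reciprocal of STEYX — the standard
  error `sqrt(SSE / (n-2))` of the ordinary least-squares line of intensity
  on z — over the window (16, 24) mm. Perfectly collinear points mean
  infinite smoothness and are reported as a structured condition, not a
  crash; sweeps map them to `Inf`.

Profiles average a band of image columns around the disk's x center
(half-width 2 px in the metrics module; the sweep uses 5 px, about 1 mm of
the 5 mm disk, trading a little spatial specificity for a quieter Gaussian
fit). Whether the original analysis used one column or a band is not
reported.

## The sweep and the selection rules

`run_sweep()` crosses kernels with sampling distances: resample once per
kernel, render per distance, measure per image; wall times are recorded
(monotonic clock) but never used in automated selection, because they are
hardware-dependent — the published time-based tie-breaks survive only as a
reported column. The default grids are the study's: 3 plain interpolators +
7 windows x W in {1,3,5,8,13,16} at B=1 + 7 windows x B in
{1,1.5,2,2.5,3,4} at W=3 (87 cells), and 12 distances from 0.010 to 1.0 mm.
The interpolation study runs at the renderer-default d = 1.0 mm.

`select_parameters()` encodes the published reasoning as explicit rules:

* `chosen_whw`: smallest W whose mean smoothness is within `eps_s` (default
  2%, the published "no significant increase" is not quantified) of the
  maximum over W — the start of the smoothness plateau;
* `chosen_bf`: smallest B whose marginal relative FWHM decrease to the next
  B falls below 5% — the point where extra blurring stops buying definition;
* `chosen_window`: windows ranked by smoothness under the chosen W and under
  the chosen B; the selection is the best *common* performer (minimax rank,
  ties by rank sum then alphabetically).

A monotone smoothness curve with no plateau selects the largest swept W and
is flagged. The published window ordering itself (Kaiser/Nuttall/Hamming at
W=5, Blackman/Lanczos/Hann/Hamming at B=2) is a property of the original
scan and is not asserted on synthetic data; the rule, not the ordering, is
the reproducible object.

`percent_change()` is the summary arithmetic `100 (after - before) /
before`, applied both to synthetic results and to the published
default-vs-optimized table shipped in `reference_comparison()` (the original
scan is not deposited, so those printed values are fixed inputs, the only
part of the original results that is exactly recomputable).

## What the synthetic phantom can and cannot show

The package's acceptance checks fall in two groups. Identities and oracle
checks — percent-change arithmetic, the Nyquist bound, unit DC gain and the
interpolating property over the whole kernel grid, brute-force compositing
agreement, metric closed forms, and recovery of the generator's z-spread
(measured profile FWHM within 3% of a numerical box-Gaussian convolution
oracle) — hold exactly or to tight tolerances.

Direction-of-change claims from the original study transfer only partially,
and the reasons are informative:

* **Smoothness improvements reproduce.** Optimized rendering (Hamming
  windowed sinc with B=2, d = 0.025 mm) is far smoother than the default
  (no interpolation, d = 1.0 mm), and B=2 beats B=1; low-pass interpolation
  suppresses the noise that the smoothness score measures. CNR improves
  several-fold, as published.
* **FWHM-based claims largely do not.** With an opacity-corrected
  orthographic compositor, the 90-degree profile is almost independent of
  sampling distance (the rays integrate along y only; the image z-grid is
  fixed by the volume), so the measured FWHM neither falls as d shrinks nor
  improves under the optimized configuration: there is no reconstruction
  artifact in the generator for interpolation to remove — the blurred disk
  is equally blurred in every pipeline. The published FWHM gains ride on
  artifact cleanup in structured reconstruction data, which the Gaussian
  z-spread + white-noise phantom deliberately does not contain.
* **The cubic > linear smoothness ordering inverts on white noise.**
  Catmull-Rom transmits slightly more white-noise variance than linear
  interpolation, while its real advantage — tracking structured
  mid-frequency content — has nothing to act on here: after a 4 mm Gaussian
  spread the signal is deep inside every kernel's passband.
  Nearest-neighbour is robustly the roughest, as published.

These mismatches are properties of the synthetic data model, not of the
pipeline; the corresponding acceptance tests assert the published directions
unchanged and are expected to fail on synthetic input, precisely to keep
this limitation visible. A phantom with structured, z-correlated
reconstruction noise would be needed to carry the FWHM claims, and
simulating reconstruction is out of scope by design.

## Problem sizes and runtime

The study conditions (384 x 128 x 40 phantom, 459-slice isotropic volume,
176k rays at 90 degrees) were sized so that one resample costs a few
seconds, the most expensive render (d = 0.025 mm) about six, and the
complete acceptance computation well under a minute — the whole default
analysis runs on one core in minutes. The sinusoid-reconstruction,
compositing-oracle and metric tests use much smaller grids (16^3 volumes,
single-column profiles) where brute-force references are exact and fast.

## Known limitations

* Only axis-aligned 0/90-degree orthographic views; no perspective cameras,
  shading, or maximum-intensity projection.
* The transfer function of the original study is unknown; all absolute
  metric values depend on it, and only directions and identities are
  comparable.
* The phantom's degradation model is a separable Gaussian z-spread plus
  white noise; reconstruction artifacts, breast texture and the second disk
  column are not modeled.
* MetaImage support covers uncompressed volumes only; NIfTI headers store
  geometry as 32-bit floats, so spacing/origin round-trip exactly through
  MetaImage and the raw+JSON sidecar, and to float precision through NIfTI.
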