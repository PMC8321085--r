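# dbtvr — volume-rendering optimization for digital breast tomosynthesis

Digital breast tomosynthesis (DBT) reconstructions have voxels of about
0.085 × 0.085 × 1.0 mm³: sharp within slices, coarse between them. Rendered
as a 3D volume, the coarse z direction smears bright structures into long
streaks, and the usefulness of the rendering then hinges on two parameters
chosen before and during ray casting:

* the **interpolation kernel** used to resample the grid to isotropic
  0.085³ mm³ spacing (z-only), and
* the **sampling distance** *d* between consecutive accumulations along each
  cast ray.

`dbtvr` is an analysis package for studying exactly that trade-off on a disk
phantom. It is aimed at medical-imaging researchers who want a fully
scriptable, dependency-light reimplementation of the classic phantom
pipeline: synthetic phantom → z-resampling → composite ray casting →
image-quality metrics → parameter selection.

## The model in brief

**Resampling.** z-only interpolation with nearest, linear, Catmull-Rom cubic
or windowed-sinc kernels: `k(x) = sinc(x/B) · w((x/B)/W)` with window `w` one
of Lanczos, Kaiser, cosine, Hann, Hamming, Blackman, Nuttall; `W` ∈ [1, 16]
is the window half-width (support in source samples) and `B` ≥ 1 the z blur
factor (argument scaling that low-pass filters while interpolating). Discrete
taps are renormalized to unit sum, so the resampler has exactly unit DC gain.

**Rendering.** Orthographic composite ray casting at azimuth 0° (rays along
z, detector-parallel view) and 90° (rays along y, the view that exposes
z-quality). Per sample, opacity is corrected for the sampling distance,
`α' = 1 − (1 − α)^(d/u)` with unit distance `u`, then composited front to
back: `I += (1 − A) α' g`, `A += (1 − A) α'`. The sampling theorem bounds
useful distances by `2 × min voxel spacing` = 0.170 mm for the DBT grid
(`nyquist_bound()`), and `auto_sampling_distance(n) = 3580.5 · n^−0.621`
reproduces the automatic mode of a standard toolkit.

**Metrics**, measured on the 5 mm disk of the phantom at 90°:

* FWHM of a Gaussian `b + A·exp(−(z−μ)²/2σ²)` fitted to the disk's z
  profile: `FWHM = 2√(2 ln 2)·σ` (lower = better z definition);
* `CNR = (μ_disk − μ_BG) / σ_BG`, two flanking background ROIs, sample SDs;
* smoothness `= 1 / STEYX` over z ∈ (16, 24) mm, where STEYX =
  `√(SSE/(n−2))` of the least-squares line of intensity on z.

## Worked example

The whole study is scripted under `analysis/` (01 phantom, 02 interpolation
sweep, 03 sampling-distance sweep, 04 final comparison). The final
comparison alone:

```r
library(dbtvr)

vol <- generate_phantom(phantom_spec(seed = 1))   # 384 x 128 x 40 DBT-like phantom
cfg <- sweep_config(vol,
                    kernels = list(kernel_spec("windowed_sinc", window = "hamming",
                                               W = 3, B = 2)),
                    sampling_distances = c(1.0, 0.025),
                    include_original = TRUE,
                    azimuths = c(90, 0))
records <- run_sweep(cfg)
print(comparison_table(records, optimized_kernel = "hamming_W3_B2",
                       optimized_d = 0.025), digits = 4)
```

prints (seed 1):

```
         metric default optimized pct_change
1         cnr_0   8.260     8.276     0.1936
2        fwhm_0   5.759     5.766     0.1191
3        cnr_90  11.163    85.642   667.1835
4       fwhm_90   7.916     8.019     1.3012
5 smoothness_90  53.317    71.354    33.8280
```

Read: switching from the renderer defaults (no interpolation, d = 1.0 mm) to
Hamming windowed-sinc resampling with z blur factor 2 and d = 0.025 mm
raises the 90° contrast-to-noise ratio about 7-fold and the profile
smoothness by a third on the synthetic phantom — the same direction and
similar magnitude as the published physical-phantom result for CNR
(`reference_comparison()`: 6.23 → 39.39, +532%). The FWHM column is flat
here by construction: the synthetic phantom's blur is in the volume itself,
so there is no reconstruction artifact for interpolation to remove — see the
methods vignette (`vignettes/dbt-volume-rendering.Rmd`) for what the
synthetic phantom can and cannot show.

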