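# cnparcel

Microstructural parcellation of the caudate nucleus (CN) from diffusion
MRI, with a polarized-light-imaging (PLI) module for histological
validation and a ground-truth phantom that makes every stage testable
without any data download.

## The scientific problem

The caudate nucleus is an arc-shaped gray-matter nucleus whose internal
fiber architecture is not uniform: along most of its body the dominant
diffusion direction runs *tangentially* (along the nucleus' long axis),
but in the middle portion myelinated radial fiber bundles (Wilson's
pencils, running toward the globus pallidus through the internal capsule)
dominate, and near the head a narrow tangential zone interrupts them
again. These transitions define a reproducible tri-partition of the CN
into posterior, middle and anterior subregions — a parcellation based on
tissue microstructure rather than cortical connectivity.

`cnparcel` implements that analysis as a tested pipeline:

1. **Tensor fitting** — per-voxel diffusion tensor by log-linear least
   squares of ln S = ln S₀ − b gᵀDg, with FA, principal eigenvector and
   direction-coded RGB maps (red = left–right, green =
   posterior–anterior, blue = inferior–superior).
2. **Longitudinal axis** — a cubic smoothing spline through all CN
   voxels, parameterised by the angle about the anterior commissure and
   sampled equidistantly at 45 points.
3. **Radiality index** — for each axis sample, the mean acute angle
   arccos(|v·t|) between the voxelwise principal direction v and the
   local spline tangent t (0° = tangential, 90° = radial), plotted
   against arc length.
4. **Boundary detection** — the group-mean profile's 45° crossing in the
   central CN, and the local minimum (maximally tangential point) near
   the head; per-subject refinement searches within 10 mm of arc for the
   angle closest to 45° and the lowest angle, respectively.
5. **Segmentation** — every voxel labeled posterior / middle / anterior
   by its projected arc length relative to the two boundaries.
6. **Tractography** — deterministic streamline tracking (500 seeds, 2 mm
   curvature radius, 30 mm minimum length, 0.05 amplitude cutoff) with
   declarative inclusion/exclusion bundle rules and per-subregion
   endpoint target maps.
7. **PLI** — forward simulation of polarizer rotation series
   (crossed: I = I₀ sin²(2(ρ−φ)) sin²(δ/2); quarter-wave:
   I = I₀/2 (1 + sin(2(ρ−φ)) sin δ), retardance δ = δ_max cos²α) and the
   inverse per-pixel sinusoid fit recovering in-plane direction φ,
   inclination α and maximum-intensity maps.
8. **Phantom** — a multi-tensor DWI phantom (curved tube, tangential +
   radial compartments, Rician noise, 60 directions at b = 1000 s/mm²)
   with planted boundaries for parameter-recovery testing.

## Worked example

```r
library(cnparcel)

truth <- make_cn_phantom()                       # 25 mm arc radius, 120 deg
dwi   <- simulate_dwi(truth, noise_sigma = 1/20, rng_seed = 7)   # SNR 20
field <- fit_tensors(dwi, truth$mask)
axis  <- fit_longitudinal_spline(truth$mask, truth$affine, truth$ac_point)
prof  <- radiality_profile(field, axis)
bounds <- detect_group_boundaries(prof)
labels <- segment_cn(truth$mask, axis, bounds, truth$affine)
```

This prints (via the objects' `print` methods):

```
Curved-nucleus phantom: 2499 voxels, arc length 52.4 mm, planted boundaries at 23.56 / 39.27 mm
Tensor field: 2499 voxels; mean FA 0.592
Longitudinal spline: 45 samples over 52.5 mm of arc
group boundaries: 45-degree crossing at 23.99 mm; local minimum at 39.37 mm
```

The detected boundaries (23.99 / 39.37 mm of arc) recover the planted
ones (23.56 / 39.27 mm) well within one sample spacing (52.4/44 ≈ 1.2 mm)
at SNR 20. `table(labels[labels > 0])` gives the subregion voxel counts
(1155 posterior / 726 middle / 618 anterior here). The full pipeline —
including tractography, bundle classification and endpoint maps — runs
via `run_pipeline(pipeline_config(...), out_dir)` or the
`inst/cli/cnparcel` script.

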