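---
title: "Methods: microstructural parcellation of the caudate nucleus"
author: "cnparcel developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstructural parcellation of the caudate nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnparcel)
```

## The model

The caudate nucleus (CN) is an arc of gray matter whose voxelwise
diffusion anisotropy is weak (gray-matter FA) but consistently oriented.
The working model is that each CN voxel contains a mixture of two fiber
populations: a *tangential* population running along the nucleus' long
axis and a *radial* population (Wilson's pencils) running perpendicular
to it, toward the globus pallidus. The principal eigenvector of the
single diffusion tensor fitted to such a voxel points along whichever
population carries the larger volume fraction, so transitions in the
dominant population appear as sharp swings of the *radiality index* —
the mean acute angle between the principal direction and the local
tangent of the nucleus' longitudinal axis. Two landmarks of that profile
define the parcellation:

* the **45° crossing** in the central CN, where dominance flips from
  tangential (posterior) to radial (middle), and
* the **local minimum** near the head, a narrow maximally-tangential
  zone interrupting the radial field, beyond which lies the anterior
  segment.

### Pipeline stages and their assumptions

**Tensor fit.** Plain (unweighted) log-linear least squares of
ln S = ln S₀ − b gᵀDg per voxel. This assumes monoexponential decay at
the single shell (b = 1000 s/mm²) and treats the multi-compartment voxel
as one effective tensor — exactly the approximation whose directional
imbalance the radiality index exploits. All b = 0 volumes are averaged
into one baseline before fitting (mirroring repetition averaging); a
weighted pass is config-gated (`weighted = TRUE`) but off by default
because the estimator used originally is unstated and unweighted LS is
the simplest reproducible choice. Negative eigenvalues are clamped to
1e-12 mm²/s so FA stays defined in noisy background; signals ≤ 0 are
floored (with a warning) before the log.

**Longitudinal axis.** Every mask voxel's angle about the anterior
commissure (AC), measured in the best-fit plane of the mask (by PCA),
parameterises the axis; a cubic smoothing spline of each world
coordinate against this angle is sampled equidistantly at 45 parameter
values. Assumptions: the CN arcs monotonically around the AC within a
near-sagittal plane (enforced: angular range ≥ 10°, no internal angular
gaps), and the AC lies outside the arc. Arc length starts at the
posterior (−y) end.

**Radiality.** Each voxel is assigned to its nearest parameter sample
*after orthogonal projection* onto the spline (via a dense polyline),
which avoids double-assignment on the concave side of the arc. The angle
is computed against the tangent **at the voxel's projected point**, not
at the sample point: the defining property "principal direction equal to
the local tangent everywhere ⇒ radiality 0° everywhere" only holds under
this reading, and it removes a discretisation floor of ~0.7° (half the
sample spacing in angle) that the sample-tangent reading would impose.

**Boundaries.** The group profile is the across-subject mean on the
common 45-sample grid (the "averaged-profile" reading of the group
analysis; averaging tensor volumes in a common space instead is a
registration problem deliberately out of scope). The 45° crossing is
linearly interpolated inside a central search window (default arc
fractions 0.25–0.65); the head minimum is the discrete local minimum
inside a head window (default 0.60–0.90) after an optional 3-sample
moving average. Subject refinement searches ±10 mm *of arc length*
(not Euclidean distance — the procedure lives on the midline) around
each group boundary for the angle closest to 45°, respectively lowest.

**Tractography.** Fixed-step Euler integration (default step 0.5 mm,
half the interpolated voxel size) on a peak-direction field with
trilinear, sign-aligned interpolation; at each step the peak most
aligned with the incoming direction is followed. The published 2 mm
curvature radius becomes the discrete per-step angle bound
θ_max = 2·arcsin(step/2R); termination occurs on leaving the grid, on
interpolated amplitude below the cutoff, or on exceeding θ_max; tracks
shorter than 30 mm are discarded. The "fODF amplitude cutoff 0.05" is
interpreted as a fraction of the field's global maximum amplitude
(`cutoff_mode = "relative"`); for tensor fields an absolute FA cutoff is
config-gated. Manual bundle dissection becomes a declarative, ordered
rule file: first rule whose exclusion masks are avoided and whose every
AND-combined inclusion group is visited assigns the label.

**PLI.** Forward model from standard birefringence physics (Jones
calculus for a retarder between polarizers): crossed set
I = I₀ sin²(2(ρ−φ)) sin²(δ/2) (period 90°), quarter-wave set
I = I₀/2 (1 + sin(2(ρ−φ)) sin δ) (period 180°), with retardance
δ = δ_max cos²α. The inverse fits a + b·sin(hρ + c) by linear regression
on {1, sin hρ, cos hρ}; direction comes from the quarter-wave phase
(180°-unique), inclination from the normalised amplitude b/a = sin δ.
How the two filter sets were combined originally is not described; the
quarter-wave-phase + amplitude-inclination scheme implemented here is
one defensible reading, with the crossed set feeding the
maximum-intensity map. Inclination sign is unrecoverable from a single
section, so α is reported unsigned in [0°, 90°].

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_samples` | 45 | – | published sampling of the axis |
| `central_window` | 0.25–0.65 | arc fraction | "central part" of the CN; configurable |
| `head_window` | 0.60–0.90 | arc fraction | "near the head"; configurable |
| `search_radius` | 10 | mm | published subject refinement radius |
| `df` (spline) | 8 | – | see *Numerical choices* |
| `n_seeds` | 500 | – | published seed count |
| `step` | 0.5 | mm | half the 1 mm interpolated voxel |
| `curvature_radius` | 2 | mm | published constraint |
| `min_length` | 30 | mm | published filter |
| `cutoff` | 0.05 | – | published amplitude cutoff (relative mode) |
| `delta_max` | π/2 | rad | thin-section regime: amplitude→inclination invertible |
| phantom SNR | 20 | – | b=0 SNR typical of 3T single-shell dMRI |

## The synthetic world

`make_cn_phantom()` emulates the CN head + body as a planar circular arc
(default 120° of a 25 mm-radius circle) swept by a 4 mm tube on a 1 mm
isotropic grid — matching the interpolated resolution of the emulated
acquisition and yielding ≈45 distinguishable axis bins over ≈52 mm of
arc. The arc center doubles as the AC surrogate, so the angular
parameter is exact by construction. Every masked voxel mixes a
tangential and a radial compartment (eigenvalues (1.7, 0.3, 0.3)×10⁻³
mm²/s each); the radial volume fraction follows a piecewise-linear
schedule in arc fraction whose 0.5 crossing sits exactly on the first
planted boundary (default arc fraction 0.45) and whose V-shaped dip
bottoms exactly on the second (0.75), then rises again toward the tip.
Because the fitted tensor's principal direction flips where the fraction
crosses 0.5, this plants the 45° crossing and the near-head minimum at
known arc lengths. No quantitative compartment fractions exist for the
real CN; the schedule is calibrated only to reproduce the qualitative
profile shape (tangential → radial → tangential dip → radial). DWI
signals follow the multi-tensor mixture with Rician (magnitude) noise;
PLI sections get Gaussian (camera) noise; the background outside the
mask is isotropic (0.7×10⁻³ mm²/s) to avoid FA artifacts at the mask
edge. The tube is clipped to the arc's angular range (no spherical end
caps), keeping parameter coverage equal to arc length.

What the phantom does *not* emulate: head motion, eddy currents,
partial-volume mixing with white matter or CSF, anatomically realistic
CN shape (the real nucleus tapers and leaves the sagittal plane),
cortical targets, or fODF-level crossing-fiber complexity. A green test
therefore establishes correctness of the *computation* under the stated
model, not in-vivo validity of the parcellation.

## Numerical choices

* **Spline smoothing.** Generalised cross-validation grossly
  undersmooths against the full-thickness tube scatter (the recovered
  axis length tripled in testing), so the default is a fixed effective
  df = 8 per coordinate — the axis coordinates are near-trigonometric
  over ≤120° and need no more. The stated alternative rule "smoothing
  such that mean residual ≈ 1 voxel" is uninformative here because
  residuals are dominated by the tube radius, not by roughness.
* **Tangents.** `smooth.spline`'s natural boundary conditions (f″ = 0)
  bias its derivative near the profile ends, so tangents come from local
  quadratic regression (a Savitzky–Golay derivative, 9-sample window)
  over the evaluated curve instead.
* **Voxelisation limits.** Binary-mask aliasing leaves ~2–5° of tangent
  error at the two extreme samples of a mask-fitted axis regardless of
  estimator (several were tried). Parameter-recovery tests therefore use
  the fitted axis (boundary tolerance: one sample spacing), while
  radiality-extreme tests use the phantom's exact axis
  (`truth_spline()`), isolating the angle computation from axis
  estimation.
* **Ties.** Multiple 45° crossings → the one closest to the window
  center; multiple local minima → the deepest, then posterior-most;
  subject refinement ties → posterior-most sample; typical-subject ties
  → lowest index. All logged.
* **Inclination singularity.** α = arccos√(δ/δ_max) has infinite slope
  at δ = δ_max (α = 0), so sin δ values within 1e-12 of 1 are snapped to
  1; the induced error is below 1e-4° while preventing rounding noise
  from inflating to ~0.01°.
* **Degenerate inputs.** Angular range < 10° or internally gapped masks
  abort the axis fit with diagnostics; the angular-gap threshold scales
  with the voxel size at the innermost radius so grid discretisation
  near the arc apex is not mistaken for disconnection. Step ≥ 2R makes
  the curvature bound undefined and is rejected. Constant PLI series
  yield amplitude 0 with an explicit "phase undefined" flag.
* **Determinism.** All randomness (seed jitter, noise) derives from
  integer seeds; identical configuration + seed reproduces every text
  artifact byte-for-byte (tested).

## Known limitations

* Hemispheres are processed independently; whether left and right
  shared one group boundary originally is unknown, and no pooling
  across hemispheres is attempted beyond profile averaging.
* No Talairach/MNI normalisation, no automatic AC detection, no caudate
  tail (excluded for partial-volume reasons), no constrained spherical
  deconvolution (multi-peak fields can be supplied, but fODF estimation
  itself is out of scope), no probabilistic tractography.
* Published in-vivo summary values (e.g. per-subject mean FA of
  0.15–0.22) are not reproduction targets: they depend on scanner noise,
  segmentation and registration steps outside this package's scope.
* File formats are deliberately minimal subsets (NIfTI-1 single-file,
  uncompressed float TIFF, TCK Float32LE); they round-trip internally
  and open in standard tools, but exotic external variants of those
  formats may be rejected.
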