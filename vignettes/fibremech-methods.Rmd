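---
title: "From diffusion MRI to fibre-aware muscle mechanics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From diffusion MRI to fibre-aware muscle mechanics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibremech)
```

`fibremech` is a desk-scale toolkit for the full chain from
diffusion-weighted MR images of skeletal muscle to fibre-annotated
tetrahedral finite-element models, a transversely isotropic hyperelastic
muscle law with an embedded strain-time deep-tissue-injury model, and a
minimal static FE driver to exercise it. This vignette explains the models
and the design decisions; it states no result that the package's tests do
not themselves compute.

## 1. Imaging: mosaics, averaging, denoising

**Mosaic assembly.** Scanners often store a 3D diffusion-weighted
acquisition as a single 2D *mosaic*: an `N x N` grid of 2D tiles. Tiles
are traversed column-first, so tile `(k, l)` (row `k`, column `l`,
1-based) becomes slice `m = N (l - 1) + k` of the 3D stack. Internally
everything is 0-based R indexing; the 1-based formula appears only at this
boundary. Trailing empty tiles are detected as all-zero tiles unless the
populated count is given explicitly — for a 7x7 grid whose last row is
empty this yields 42 slices.

**Acquisition averaging.** Repeated acquisitions per gradient direction
are averaged into one volume per direction plus one unweighted (b = 0)
volume, reducing the noise variance by the repeat count. Averaging is
idempotent and keeps the gradient table; inconsistent tables across
repeats are rejected.

**Denoising.** Magnitude MR noise is Rician. `denoise_local_pca()` is a
deliberately compact variant of overcomplete local-PCA denoising: a
sliding cubic patch (radius 1 by default) is decomposed across the
diffusion dimension, eigencomponents with variance below a hard threshold
`tau = 2.3 * sigma^2` are suppressed, overlapping patches are averaged
uniformly, and the Rician bias of magnitudes is removed through
`m_corr = sqrt(max(m^2 - 2 sigma^2, 0))` (from `E[m^2] = A^2 + 2 sigma^2`).
The patch size and threshold are package defaults, chosen so that phantom
tests show strict RMSE reduction at realistic noise levels; they are not
taken from any published protocol, which left them unstated. The
overcomplete transform-domain aggregation of the full method is
intentionally omitted: the principle (local low-rank structure across
directions) is the same, and the simpler estimator is fully testable on
phantoms.

## 2. Tensor fitting and tractography

The diffusion tensor is fitted per voxel by log-linear least squares on
`ln(S/S0) = -b g' D g`, requiring at least 6 non-collinear directions and
a b = 0 volume; the scheme matrix is solved once and applied to all
voxels. Fractional anisotropy is the usual normalised eigenvalue
dispersion, clipped to [0, 1].

`track_streamlines()` integrates the principal eigenvector field with
bidirectional Euler steps. Fibre directions are axial (sign-free), so each
step aligns the eigenvector with the previous step direction (hemisphere
continuity). Stopping criteria: mask exit, FA below a threshold (0 by
default, as used for muscle, where FA is low), or per-step turning angle
above `max_angle_deg`. Two upstream tool parameters could not be mapped
faithfully: a GUI-specific "fibre smoothness" knob with undocumented
semantics (we expose `max_angle_deg` and `step_mm` instead) and a
"minimum length 10" whose unit is unstated — interpreted as millimetres
and configurable. Bundling follows the cropping-box idiom: a strand
belongs to a bundle iff at least one point lies in the closed axis-aligned
box. `bundle_to_mask()` voxelises strand points for segmentation export.

## 3. Meshes, registration, mask smoothing

Meshes are linear tetrahedra with per-element part labels. The node
ordering convention makes `det(x2-x1, x3-x1, x4-x1)/6` positive;
violating elements are repaired by swapping two nodes, with a warning.
Rigid registration is point-to-point ICP (nearest-neighbour pairing plus
the closed-form least-squares rigid fit), whose RMS objective is
non-increasing; the point-to-plane variant was not needed at desk scale.

`smooth_mask()` mirrors the morphological pipeline applied to
segmentation masks before meshing: dilate (6-neighbourhood), Gaussian-blur
the indicator, re-threshold at 0.5, then erode by the same number of
steps. The symmetric dilate/erode pair is what makes the pipeline
approximately volume-preserving; the residual change is curvature-driven
shrinkage of order `sigma^2 H` per surface point (H the mean curvature).
With the defaults (1 dilation step, sigma = 1 voxel) the relative volume
change on convex phantoms of realistic size (e.g. a cylinder of radius 20
voxels) stays below the 0.2 % bound that segmentation practice demands;
the bound is asserted by the tests, the filter parameters are ours.

## 4. Mapping fibres onto elements

For each element, the maximal runs of consecutively numbered strand
points inside it (barycentric point-in-tet test, boundary inclusive) each
contribute a trend line `g_s`: the total-least-squares principal axis of
the run, sign-aligned with the traversal direction. The effective element
direction is the weighted combination with squared-count weights

$$ f(x_i) = \sum_s w_s\, g_s, \qquad w_s = \frac{n_s^2}{\sum_s n_s^2}, $$

so longer runs dominate quadratically. Two amendments were needed to make
this well-posed for axial data: contributions are hemisphere-aligned to
the longest run before summation (otherwise two antiparallel runs of a
single physical fibre cancel to zero), and the result is normalised to
unit length (the magnitude of the weighted sum has no physical meaning;
orientation cards consume unit vectors). Weights sum to one by
construction, which the tests assert.

The per-muscle direction field is then smoothed with a Gaussian
radial-basis kernel,

$$ \tilde f(x_i) \propto \sum_e \phi(x_i, x_e)\, f(x_e), \qquad
   \phi = \exp\!\big(-(p\,\lVert x_i - x_e\rVert / L)^2\big), $$

with `L` the bounding-box diagonal of the muscle and `p = 20` by default:
larger `p` narrows the neighbourhood. The kernel weights are deliberately
not Shepard-normalised — the output is renormalised to unit length anyway,
so the normalisation constant cancels. Elements with no fibre information
receive interpolated directions, so after one smoothing pass no element of
a seeded muscle is missing. Smoothing runs once, not iteratively. An
optional density-scaled mode grows `p` with the element count of the
domain (`p * (n/1000)^(1/3)`), off by default, for users who refine meshes
and want a stable physical kernel width. One subtlety: `L` is the
*axis-aligned* bounding-box diagonal, so the default kernel width is not
strictly invariant under rotations of the muscle; grid-aligned rotations
preserve it exactly, and `smooth_fibre_field(..., L = )` accepts a fixed
length scale when full orientation independence matters. The smoothing
algebra itself commutes with rotations, which the tests assert at 1e-9. Export writes one
`*ELEMENT_SOLID_ORTHO` card per element (fixed-width ASCII, 1-based ids,
degenerate 8-node tets) with the fibre axis and an auto-generated
orthogonal second axis; an independent parser in the package round-trips
the dialect.

## 5. The constitutive law

Soft tissues are modelled as hyperelastic, quasi-incompressible and
transversely isotropic about the element fibre direction `a0`, with
structural tensor `M = a0 (x) a0` and fibre stretch
`Lambda = sqrt(M : C)`, `C = F'F`. The second Piola-Kirchhoff stress is
additively split:

$$ S = S_{\mathrm{iso}} + (1-\gamma)\,(S_{\mathrm{pas}} + \alpha\,S_{\mathrm{act}}). $$

The isotropic matrix is a compressible Mooney-Rivlin form,

$$ S_{\mathrm{iso}} = B_1 I + B_2 C + B_3 C^{-1} + k\,(J-1)\,J\,C^{-1}, $$

with `B1 = 2 c1 I3^(-1/3) + 2 c2 I3^(-2/3) I1`,
`B2 = -2 c2 I3^(-2/3)`,
`B3 = -(2/3) c1 I3^(-1/3) I1 - (4/3) c2 I3^(-2/3) I2`. At `F = I` the
coefficients cancel (`B1 + B2 + B3 = 0`), so the reference state is
stress-free for every passive parameter set — a property the tests assert
rather than assume. The fibre stress acts along `M`: the passive part
`c3 (Lambda^{c4} - 1)/Lambda^2` switches on at `Lambda = 1`; the active
part is `s_max/Lambda^2` times a two-branch exponential envelope peaking
at `Lambda = lambda_opt` (widths `dw_asc`/`dw_dsc`, exponents
`nu_asc`/`nu_dsc`). Both branch switches are continuous, and at the
optimum `Lambda^2 S_act . a0a0 = s_max` exactly. `gamma = 1` turns the
fibre terms off (fat/skin); `alpha` in [0, 1] scales activation.

Defaults are the published muscle set (`c1 = 2.5e-6`, `c2 = 6e-3`,
`c3 = 1e-3` MPa, `c4 = 6`, `s_max = 0.1` MPa, `dw_asc = 0.15`,
`dw_dsc = 0.16`, `nu_asc = 2`, `nu_dsc = 4`, `lambda_opt = 1.3`), in a
consistent mm-MPa-ms-g unit system. Three deliberate choices:

* **Bulk modulus.** The source parameter table omits the penalty modulus
  (`quasi-incompressible' is stated, a value is not). The default is
  `bulk_k = 0.1` MPa — stiff relative to the shear scale `2(c1 + c2)` but
  soft enough for single-point tetrahedra not to lock; it is a prominent
  parameter, and a near-incompressibility test runs at 10x the default.
* **Tangent.** The material tangent `2 dS/dC` is assembled in closed form
  (invariant derivatives plus the scalar fibre derivative) and verified
  against central finite differences of `S`; the spatial tangent includes
  the `J^{-1}` factor of the standard Cauchy-conjugate push-forward (the
  source states the push-forward twice, once with and once without the
  factor; we follow the standard form).
* **Fat/skin anisotropic entries.** The published table lists fibre
  parameters for skin/fat but sets `gamma = 1`; they are stored and
  ignored, exactly as the gating prescribes.

Viscoelasticity and activation dynamics are out of scope: `alpha` is a
constant input.

## 6. The injury model

Sustained compressive strain kills muscle cells. An element is *injured*
at the first instant its effective Green strain
`eps_eff = sqrt((2/3) E : E)` (full contraction of `E = (C - I)/2`, not
the deviatoric part — exactly as the criterion is written) exceeds the
time-decaying threshold

$$ \varepsilon_{\mathrm{crit}}(t) = \frac{K}{1 + \exp(\beta (t - t_0))} + C, $$

with `K = 0.268`, `t0 = 9.78e6` ms, `beta = 5.83e-7` 1/ms, `C = 0.332`.
The threshold decays from `K + C = 0.6` (short loading) to `C = 0.332`
(long loading) with midpoint `t0`; time is measured from load onset, and
the default analysis window is 2 h (7.2e6 ms), long enough for the
sigmoid to matter. Injury is irreversible within the window, so the
damage volume fraction — the volume-weighted percentage of injured
elements among the tracked parts (muscle by default) — is non-decreasing.
The convergence metric for meshes is the volume-normalised von Mises
stress `sigma_bar = (1/V) sum_e sigma_e v_e`.

## 7. The static FE driver

The full-limb analyses this workflow feeds are implicit-dynamic contact
simulations in a commercial solver; those are out of scope here. What the
package provides instead is the smallest solver that can *exercise* the
constitutive and injury models in a boundary-value setting:
total-Lagrangian Newton iterations on the static balance of linear
momentum (inertia dropped — multi-hour stance loading is quasi-static in
effect), linear tetrahedra with single-point integration (matching the
element class used at full scale; the known volumetric-locking risk of
this element is mitigated by the moderate bulk penalty and documented
here), exact consistent tangent `dP/dF = delta S + F C F`, Dirichlet
conditions by elimination, body forces and nodal loads, and equal load
increments (10 by default, tolerance 1e-8 relative residual). Newton
converges quadratically near the solution; the patch test (affine
Dirichlet data on a multi-element cube) reproduces the material-point
stress to 1e-8, and reactions balance applied loads.

**Convergence study conditions.** The refinement study solves a cylinder
of radius 10 mm and length 12 mm under 5 % axial compression with fully
clamped end faces (a no-slip platen analog — chosen over lateral-free
ends, which would make the deformation exactly homogeneous and the study
trivial), with the isotropic skin/fat parameter set. Four meshes with
target edge 10, 5, 2.5 and 1.25 mm (48 to 15 360 elements) keep the
finest solve within a few minutes on one CPU; these problem sizes are the
package's chosen desk-scale conditions. The quantity tracked is
`sigma_bar`; the study passes when the change between the two finest
levels stays below 1.5 %.

## 8. Phantoms: what they do and do not show

Every stage is testable without data downloads. `make_dwi_phantom()`
synthesises signals from the mono-exponential tensor model with
axially-symmetric eigenvalues (1.8e-3 / 0.3e-3 mm^2/s, typical muscle
values), fibre patterns (uniform axial, helical of known pitch), optional
seeded Rician noise, and emits the ground-truth tensor field alongside.
Default geometry mimics thigh-scale fields of view at reduced resolution
so the test suite stays fast. `make_cylinder_mesh()` maps a structured
square grid onto the disc (elliptical square-to-disc map) and splits each
hexahedron into six conforming tetrahedra; boundary nodes lie exactly on
the cylinder, so the mesh volume converges to `pi r^2 L` from below.

What passing phantom tests *do* show: the index mapping, estimators,
geometric predicates, constitutive algebra and solvers are correct on
inputs whose ground truth is known exactly. What they do *not* show:
robustness to the failure modes of real data — partial-volume effects at
muscle boundaries, spatially varying noise, EPI distortion, imperfect
fat suppression, anatomically realistic eleven-muscle geometry, or
tendon (untrackable at clinical field strengths). Conclusions about real
acquisitions require real acquisitions.

## 9. Numerical choices and degenerate inputs

* Point-in-tet tolerance 1e-9 in barycentric coordinates; boundary counts
  as inside (a point on a shared face contributes to both elements).
* Tensor fits mask out voxels with non-positive signals instead of
  failing; rank-deficient gradient schemes are rejected outright.
* `smooth_mask` on an empty mask is the identity with zero reported
  change; zero-step tracking and non-positive noise levels are rejected.
* Hemisphere alignment everywhere breaks the sign ambiguity of axial
  directions: to the previous step in tracking, to the longest run in
  element mapping, to the strongest-kernel contributor in smoothing. Ties
  resolve to the first maximum, which makes all operations deterministic.
* ICP degeneracy (collinear clouds) is detected from the singular values
  of the centred cloud and rejected; the solver reports rigid-mode
  diagnoses when the constrained dof set is insufficient instead of
  returning a misleading solution.
* All randomness (phantoms, noise) flows through a single integer seed;
  fixed seed means bit-identical outputs, which the CLI tests assert.

## 10. Known limitations

Single-tensor fits cannot represent crossing fibres; tracking is
deterministic Euler (no probabilistic or multi-tensor variants). The
local-PCA denoiser is single-pass with uniform aggregation, weaker than
overcomplete variants at strong noise. The FE driver has no contact
mechanics, so donning-type analyses are out of reach by design; the
single-point linear tetrahedron locks for bulk moduli far above the
default. Bundle overlaps (one strand in two muscles) are reported, not
resolved. These boundaries are deliberate: the package's contribution is
the verified chain from image to fibre-annotated model to
injury-annotated stress state at desk scale.
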