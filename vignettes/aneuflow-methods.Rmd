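---
title: "aneuflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aneuflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`aneuflow` post-processes gridded three-component velocity fields — from
4D Flow MRI, stereoscopic/tomographic PIV, or CFD — into wall shear
stress (WSS) maps on a triangulated lumen surface, vortex indicators, and
cross-modality agreement statistics, with a synthetic phantom generator
standing in for patient data.  It does *not* acquire or reconstruct
velocity fields: MRI pulse sequences, PIV cross-correlation, segmentation,
mesh smoothing and the Navier–Stokes solve itself are upstream of this
package.

## The WSS estimator

For a Newtonian fluid the wall traction is $\tau = 2\mu\,\dot\varepsilon
\cdot n$ with $\dot\varepsilon_{ij} = \tfrac12(\partial_j u_i +
\partial_i u_j)$ and $n$ the unit inward wall normal.  The pipeline is:

1. **Velocity gradients** (`gradient_tensor`): second-order central
   differences wherever both axis neighbours are lumen voxels, first-order
   one-sided differences where only one is.  Near-wall one-sided stencils
   are kept deliberately — the near-wall gradient *is* the signal for WSS,
   and discarding boundary voxels would bias it low.  A voxel with no
   usable stencil along some axis is flagged invalid and excluded from all
   downstream statistics.
2. **Vertex normals** (`compute_vertex_normals`): area-weighted averages
   of incident face normals.  Face windings are first made consistent by
   propagating orientation across shared edges (the iso-surfacer does not
   guarantee a winding), then each connected component is flipped so the
   normal at its vertex nearest a user-supplied interior point aims at
   that point.  This makes the result independent of input winding, which
   is also tested.
3. **IDW mapping** (`map_gradients_to_surface`): each vertex averages the
   tensors of its `n_neighbors` nearest valid voxel centres with weights
   $1/d^{p}$.  Defaults $p = 2$, 8 neighbours, search radius $3\times$
   the largest voxel pitch — conventional IDW settings; nothing in the
   estimator is sensitive to them at first order, and all are exposed.
   A vertex with no valid voxel in reach is flagged unmapped rather than
   extrapolated.
4. **Traction** (`wss_vectors`): the full viscous traction
   $2\mu\dot\varepsilon\cdot n$, evaluated componentwise.  No projection
   onto the tangent plane is applied by default — the magnitude reported
   is that of the full vector; `tangential = TRUE` additionally reports
   $\|\tau - (\tau\cdot n)n\|$ for users who want strictly
   surface-parallel WSS.
5. **Summaries**: `summarize_wss` uses an unweighted vertex mean (an
   area-weighted variant sits behind `area_weighted = TRUE`);
   `normalize_wss` divides by the mean magnitude over a user-selected
   parent-vessel vertex patch.  The patch boundary is a user input: there
   is no canonical definition of where the "parent vessel" ends.

On the analytic validation case (noise-free Poiseuille cylinder,
$\tau_w = 2\mu v_{max}/R$) sampled at a tomographic-PIV-like 0.63 mm
vector pitch, the vertex-median magnitude lands about 12% below the
analytic value — inside the 20% validation bound that in-vitro studies
report for this estimator class, as expected for a noise-free synthetic
(the experimental bound also absorbs measurement noise and wall-location
uncertainty).  The error is dominated by the inward offset of the voxel
centres feeding the IDW average: in a parabola the gradient magnitude at
depth $\delta$ inside the wall is low by a factor $1 - \delta/R$.  It
shrinks under grid refinement, monotonically in our tests.

## Dynamic similarity

The in-vitro phantom is scaled up (factor 3.77 here) and run with a
water–glycerol analogue, so velocities, vorticity and WSS live on
different scales per modality.  `build_similarity` encodes the standard
bookkeeping: with Reynolds matching $\rho V D/\mu$ across systems,

$$\frac{u_{vivo}}{u_{vitro}} = \frac{\mu_{vivo}}{\mu_{vitro}}
  \frac{\rho_{vitro}}{\rho_{vivo}} \frac{d_{vitro}}{d_{vivo}},$$

and WSS converts back to vessel scale through the product of the
viscosity, velocity and length ratios (vorticity through the velocity and
length ratios).  Applied to the analytic pipe-flow WSS this conversion is
exact, which is tested in closed form.  The characteristic velocity in
`reynolds` is the *inlet mean*; the characteristic length the inlet
diameter.  Any convention change is a caller-side substitution (pass
$v_{max}$ instead), not a package switch.

## Vortex indicators

`q_criterion` uses the standard second-invariant form
$Q = \tfrac12(\|W\|_F^2 - \|S\|_F^2)$, positive where rotation dominates
strain — consistent with positive-Q iso-surfaces delineating vortex
cores.  Values are reported in native units of the input field (1/s²); a
similarity-scaled out-of-plane vorticity is available separately
(`vorticity_z_scaled`), because whether any particular published Q level
refers to scaled or native units is generally ambiguous and the package
refuses to guess.

## Agreement statistics

* `downsample` interprets "bilinear" resolution matching as trilinear in
  3D: one code path, exact on affine fields (tested), with 2D plane
  comparisons obtained by slicing afterwards.  A target voxel is lumen
  only if all 8 enclosing source corners are — a conservative mask that
  refuses to interpolate across the wall.
* `pearson` drops missing samples pairwise; it is scale-invariant, so
  whether profiles are normalized before correlating is immaterial.
* `bland_altman` uses the sample ($n-1$) standard deviation for the
  $\pm 1.96\,SD$ limits of agreement, per standard practice when the
  printed source says only "SD".  `proportional_bias` is a plain
  least-squares slope of difference on mean — a descriptive trend, not an
  inference; no multiple-testing machinery is attached anywhere.

## The synthetic phantoms

`make_poiseuille` samples the parabolic profile exactly on the voxel grid
(lumen $r \le R$, one dry voxel margin) and triangulates the cylinder
wall.  `make_sac_phantom` adds a spherical side sac carrying a Hill's
spherical vortex, blended to zero at the sac boundary *through the Stokes
stream function*: the composite is therefore exactly divergence-free in
the continuum, and its discrete divergence converges to zero under grid
refinement (tested at first order).  Two numerical subtleties fixed the
design here:

* the blend must be a **quintic (C²) smoothstep**, not the more common
  cubic: the velocity contains $w'$, so a discontinuous $w''$ puts a jump
  into the velocity *gradient* at the shell edges and the discrete
  divergence stops converging there;
* the blend shell spans the outer **25%** of the sac radius
  (`blend_frac = 0.25`).  A much thinner shell concentrates velocity
  curvature below any affordable voxel pitch, which keeps the divergence
  check in its pre-asymptotic regime at desk scale.

The vortex strength defaults to 5% of the tube centreline velocity.
Sidewall-aneurysm sacs carry a slow recirculation driven by the parent
jet — a small fraction of the parent velocity — and this is what places
the sac wall far below the neck in the WSS map (the neck value exceeding
twice the sac mean is a property of the emulated flow class and is
asserted in the tests).

`emulate_modality` degrades a fine "truth" field by box-averaging over
each target voxel — including zero-velocity exterior voxels, which is the
partial-volume mechanism that makes coarse modalities underestimate
near-wall velocity and hence WSS — optionally slab-averaging along z
(laser-sheet thickness emulation), then adding i.i.d. Gaussian noise.
Presets (scaled-frame units): tomographic PIV 0.63 mm isotropic;
stereoscopic PIV 0.38 mm in-plane, 1 mm plane pitch and 1 mm depth
averaging; MRI 1.77 × 1.77 × 1.89 mm (0.47 × 0.47 × 0.5 mm at vessel
scale) with noise SD 5% of a 150 cm/s velocity-encoding limit mapped to
the scaled frame.  PIV *vector pitch* is a processing choice (window size
and overlap), not a physical constant, so presets are estimates and
everything is overridable.  A target voxel is lumen when at least 50% of
its contributing source voxels are — a symmetric partial-volume
threshold.

What the phantoms do **not** emulate: pulsatile waveforms, MR physics
(phase wraps, displacement artefacts, eddy currents), PIV particle
imaging and cross-correlation artefacts, wall compliance, non-Newtonian
rheology.  A green test on the phantom therefore establishes that the
*post-processing* is correct and that resolution-driven biases behave as
expected; it says nothing about acquisition-specific artefacts in real
data.

## Numerical choices and degenerate inputs

* Grid convention: voxel centre of index $(i,j,k)$ (1-based in R) at
  `origin + (index − 1) · spacing`; the on-disk CSV dialect records
  0-based indices.  Internal units are strictly SI; readers accept a
  `"mm"` hint and convert lengths on load.
* STL: vertices deduplicate by *exact* coordinate match (deterministic
  topology; no tolerance merging).  Binary STL stores float32 by format
  definition, so bit-exact round-trips hold at float32 there and at full
  double precision for the ASCII dialect (written with `%.17g`).
* Iso-surfacing (`iso_surface`) uses marching tetrahedra on the Kuhn
  6-tet cube decomposition with canonical edge interpolation (shared
  edges interpolate in global node order, so coincident vertices are
  bit-identical and weld exactly).  Node values within $10^{-4}$ voxel of
  zero are nudged off zero; an intersection exactly on a grid node would
  otherwise spawn a family of degenerate slivers and a non-manifold
  pinch.
* Trilinear sampling returns `NA` (never extrapolates) when any enclosing
  corner is outside the grid or mask; points landing exactly on the upper
  grid face are pulled into the last cell.
* Tie-breaks: box-averaging bins are half-open (lower edge inclusive);
  the partial-volume mask threshold is $\ge 50\%$.
* Degenerate inputs raise typed errors rather than returning silent
  values: zero-area vertex stars (with the offending vertex ids),
  non-manifold or non-orientable meshes, empty parent patches, zero
  normalization references, all-unmapped surfaces, zero-variance
  correlations, sub-minimum pair counts.
* `emulate_modality` seeds its noise locally and restores the global RNG
  state, so phantom generation is reproducible without disturbing a
  caller's random stream.

## Known limitations

* The IDW mapping underestimates WSS systematically at coarse resolution
  (inward-offset bias).  This is faithful to the estimator being modelled
  — the package quantifies the bias rather than hiding it — but users
  wanting unbiased wall gradients at coarse pitch need a model-based
  extrapolation this package deliberately does not provide.
* The sac phantom's wall shear at the sac boundary is an artefact of the
  stream-function blend (the true analytic wall gradient there is ~0);
  at practical grid pitches the IDW mapping reads the blend-shell shear.
  Comparisons on the sac phantom are therefore always *relative* (fine vs
  degraded), never against a closed-form sac WSS.
* `proportional_bias` near-zero slopes at mild degradations are noise;
  the positive-slope property is asserted only for MRI-like (≥ 4×)
  coarsening.
* Steady flow only; no oscillatory/time-averaged WSS indices.
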