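# aneuflow

Wall shear stress estimation and cross-modality flow comparison for
cardiovascular (aneurysm) hemodynamics.

## The problem

Wall shear stress (WSS) — the tangential viscous traction blood exerts on
the vessel wall — is a key quantity in intracranial-aneurysm research, but
every way of measuring the underlying velocity field disagrees with every
other: in-vivo 4D Flow MRI is coarse (~0.5 mm voxels), particle image
velocimetry (stereoscopic or tomographic) measures a scaled transparent
phantom with a blood-analogue fluid, and CFD solves an idealised model.
Comparing them requires a common post-processing chain: velocity-gradient
tensors on masked voxel grids, mapping those gradients onto a triangulated
lumen surface, dynamic-similarity scaling between the scaled in-vitro and
the in-vivo systems, and resolution-matched agreement statistics.

`aneuflow` implements that chain for users comparing flow fields across
modalities, plus a synthetic phantom generator (analytic Poiseuille pipe,
aneurysm-like tube-plus-sac flow, modality degradation emulation) so the
whole pipeline is testable without patient data.

## The model

For a Newtonian fluid with dynamic viscosity μ, the WSS vector at a wall
point with unit inward normal **n** is

    τ = 2 μ ε̇ · n,      ε̇_ij = (∂u_i/∂x_j + ∂u_j/∂x_i) / 2

with ε̇ the rate-of-deformation tensor, evaluated from finite-difference
velocity gradients mapped from the voxel grid to each surface vertex by
inverse-distance-weighted (IDW) interpolation.  Supporting machinery:

* **Q-criterion** `Q = (‖W‖² − ‖S‖²)/2` (rotation vs strain) for vortex
  cores, and the vorticity curl components;
* **dynamic similarity**: Reynolds matching `ρVD/μ` across systems gives
  the velocity ratio, and WSS/vorticity scale by
  `(μ_vivo/μ_vitro)(u_vivo/u_vitro)(d_vitro/d_vivo)` ratios;
* **agreement statistics**: V_ref velocity normalization, trilinear
  down-sampling to a common resolution, line-profile Pearson correlations,
  and Bland–Altman mean difference with 1.96 SD limits of agreement.

The analytic validation anchor is fully developed pipe flow: a parabolic
profile `u_z(r) = v_max (1 − r²/R²)` has exact wall shear stress
`τ_w = 2 μ v_max / R`.

## Worked example

Scaled-phantom conditions: blood (1060 kg/m³, 0.0035 Pa s) in vivo,
water–glycerol analogue (1147 kg/m³, 0.008113 Pa s) in a 3.77× scaled
phantom, inlet Reynolds number 350.

```r
library(aneuflow)

blood    <- fluid_spec(1060, 0.0035)
analogue <- fluid_spec(1147, 0.008113)
sim <- build_similarity(blood, analogue, d_ratio = 3.77)
sim$u_ratio                         # 1.760  (in-vivo / in-vitro velocity)
percent_deviation(327, 350)         # 6.6 %  (stereo-PIV flow-loop Re)
percent_deviation(335, 350)         # 4.3 %  (tomo-PIV flow-loop Re)

# Poiseuille phantom at the tomographic-PIV vector pitch (0.63 mm)
ph   <- make_poiseuille(5.655e-3, 24e-3, 0.4376, 0.63e-3)
surf <- compute_vertex_normals(ph$surface, c(0, 0, 12e-3))
G    <- gradient_tensor(ph$field)
sg   <- map_gradients_to_surface(G, surf)      # IDW: power 2, 8 neighbours
wss  <- wss_vectors(sg, surf, mu = 0.008113)
summarize_wss(wss)
#> WSS summary over 2223 vertices: mean 1.1 Pa, median 1.1 Pa, peak 1.157 Pa
analytic_wss_poiseuille(0.008113, 0.4376, 5.655e-3)
#> 1.2556  (Pa; the pipeline sits ~12% low at this resolution)

# degrade to 4D-Flow-MRI resolution and compare
mri <- emulate_modality(ph$field, modality_spec("mri"), seed = 1)
wm  <- wss_vectors(map_gradients_to_surface(gradient_tensor(mri), surf),
                   surf, 0.008113)
summarize_wss(wm)
#> WSS summary over 2223 vertices: mean 0.8357 Pa, median 0.8203 Pa, peak 2.632 Pa
ok <- wss$mapped & wm$mapped
bland_altman(wss$magnitude[ok], wm$magnitude[ok])
#> Bland-Altman over 2223 pairs: mean diff 0.2647, SD 0.2127, LoA [-0.1523, 0.6817]
```

The numbers tell the expected story: coarsening the velocity field
underestimates the mean WSS (0.84 vs 1.10 Pa), while the added imaging
noise inflates the peak — the same resolution-driven disagreement pattern
seen between MRI and PIV/CFD in multi-modality studies.

## Documentation

The methods vignette (`vignettes/aneuflow-methods.Rmd`) describes the
model assumptions, every tunable parameter with units and defaults, what
the synthetic phantoms do and do not emulate, numerical choices, and known
limitations.
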