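# scan2fem

Subject-specific thoracic FEM meshes and difference-EIT images from
colored 3D surface scans.

Thoracic electrical impedance tomography (EIT) reconstructs changes in
internal conductivity — most prominently lung ventilation — from voltages
measured on a belt of 32 electrodes. Reconstruction quality depends on how
well the forward model matches the subject's actual boundary shape and
electrode positions; generic chest meshes misplace the lungs and introduce
geometric artifacts. `scan2fem` turns a cheap, fast 3D scan of the thorax
(a colored surface triangulation in PLY format, such as a phone depth-scan
export) into a subject-specific finite-element model, for EIT researchers
who want patient-specific meshes without CT imaging or custom sensor
hardware.

## What it computes

The belt carries 32 fiducial stickers, six of them printed in known colors
at fixed electrode numbers (cyan 7, orange 12, red 17, yellow 22, green
27, pink 32). From the scan the package:

1. **Crops** the scan to the belt region and keeps the largest connected
   component (`crop`).
2. **Detects and numbers the fiducials** by color clustering; the six
   anchors orient the belt so the white stickers receive the in-between
   numbers, with occlusions (e.g. under the buckle) inferred from angular
   spacing (`detect_fiducials`, `label_electrodes`).
3. **Levels** the scan by the total-least-squares plane through the
   electrodes (`fit_plane`, `apply_leveling`).
4. **Fits a smooth low-parameter boundary model**: a radius field
   `r(θ, z) = Σ_m Σ_k C[m,k] ψ_m(θ) φ_k(z)` with a Fourier basis ψ in
   azimuth (order N = 12) and normalized Gaussian radial basis functions φ
   along height (M = 7 centers) — (2N+1)·M = 175 coefficients in total
   (`fit_surface`).
5. **Remeshes** the fitted surface with a force-equilibrium
   (Persson–Strang distmesh-style) iteration under a sizing field that
   refines toward each electrode, resolving every electrode as a labeled
   disc of facets (`remesh_surface`).
6. **Builds a tetrahedral FEM mesh** of the enclosed belt-band volume by
   concentric-shell extrusion of the closed boundary surface, electrode
   facet labels carried over exactly (`build_fem_mesh`, `write_msh`,
   `write_vtk`).
7. **Images tidal breathing**: a complete-electrode-model P1 forward
   solver (skip-4 injection, 3 mA), adjoint sensitivity matrix, and a
   one-step Gauss–Newton reconstruction with standard Tikhonov
   regularization on normalized voltage differences,
   `δσ = (JnᵀJn + λI)⁻¹ Jnᵀ (v1 − v0)/v0`, differencing the average
   end-inhale against end-exhale frames (`forward_solve`, `eit_jacobian`,
   `reconstruct`, `tidal_image`).

Scan precision and accuracy are quantified exactly as in validation
studies of such scanners: per-electrode RMS/max differences between
repeated scans and against tracked ground truth after label-correspondence
Procrustes alignment, plus contour-to-surface distances (`electrode_error`,
`precision_report`, `contour_to_surface`). A synthetic phantom generator
(`make_scan`, `make_tracked_points`, `make_eit_sequence`) produces every
input the pipeline consumes — colored scans with painted sticker discs,
tracked points, and simulated two-lung EIT recordings — so the whole chain
is testable without any scanner.

## Worked example

```r
library(scan2fem)

# 1. simulate a scanner-like colored scan of a 104.8 cm-perimeter thorax
#    phantom wearing the 32-electrode fiducial belt (2 mm scanner noise)
ph <- make_scan(phantom_spec(perimeter = 1048, axis_ratio = 1.1,
                             vertex_noise_sd = 2, color_noise_sd = 5,
                             resolution = 3, seed = 42))
ph$surface
#> <colored_surface> 14309 vertices, 27920 faces, RGB colored
#>   bbox x:[-184.1, 184.8] y:[-166.4, 164.6] z:[-64.6, 65.8] mm

# 2. crop to the belt band, detect and number the fiducials, level
cropped <- crop(ph$surface, crop_region(z_bounds = c(-45, 45)))
id <- identify_electrodes(cropped)
id$electrodes
#> <electrode_set> 32/32 electrodes
lev <- apply_leveling(cropped, id$electrodes)

# 3. smooth low-parameter boundary model
fit <- fit_surface(lev$surface)
fit
#> <surface_fit> N=12, M=7 (175 parameters), z in [-45.3, 45.1] mm, fit RMS 2.006 mm
fit_perimeter(fit, z = 0)
#> [1] 1047.25

# 4. electrode position error against the simulated ground truth
truth <- electrode_set(ph$truth$centers, ph$truth$labels)
electrode_error(id$electrodes, truth, align = TRUE)
#> <comparison_report> RMS 1.19 mm, max 2.66 mm over 32 electrode pairs (aligned)

# 5. electrode-encoded surface remesh + tetrahedral FEM mesh
belt <- remesh_surface(fit, lev$electrodes,
                       mesh_config(h_electrode = 4, h_background = 15,
                                   electrode_radius = 5, max_iter = 150))
mesh <- build_fem_mesh(belt, n_shells = 3)
mesh
#> <fem_mesh> 7533 nodes, 37620 tets, 32 labeled electrodes
```

The fit RMS of 2.0 mm is the radial residual against the 2 mm-noise scan
(the 175-parameter model averages the noise away — against the noise-free
shape the agreement is sub-millimetre), and the 1.19 mm electrode RMS is
the end-to-end localization error of the full crop → detect → label
chain at this noise level. `run_pipeline()` chains the same stages with
per-stage timing and artifact output, and `inst/exec/scan2fem` exposes
them as shell subcommands (`crop`, `electrodes`, `fit`, `mesh`, `recon`,
`simulate`, `run`).

From there, `eit_jacobian(mesh)` gives the sensitivity matrix on the
subject mesh and `tidal_image(frames, J)` reconstructs the tidal
conductivity change from a 30 s recording (simulated ones come from
`make_eit_sequence`); inflated lungs appear as two negative-δσ regions.

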