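---
title: "Methods: from colored thorax scans to subject-specific EIT models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from colored thorax scans to subject-specific EIT models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices
behind `scan2fem`, in the order the pipeline runs them, and states what
the synthetic phantom does and does not emulate.

## Inputs and assumptions

The pipeline's input is a colored surface triangulation of a thorax
wearing a 32-electrode belt, in millimetres (PLY files declaring metres
are rescaled when the bounding-box diagonal falls below 10, a safe
heuristic because no plausible thorax scan is 10 mm across). Six belt
fiducials carry known colors at electrodes 7, 12, 17, 22, 27 and 32; the
rest are white. Two geometric assumptions run through everything:

* the thorax at belt level is **star-shaped** about the vertical axis
  through the electrode centroid, so the boundary is a single-valued
  radius field r(θ, z);
* the subject holds still during the scan, so one rigid frame fits the
  whole surface (breathing-motion correction is out of scope).

## Fiducial detection and numbering

Vertices within an RGB Euclidean distance of 60 of a reference color
(and closer to it than to any other reference) form candidate sets; their
connected clusters on the mesh (minimum 5 vertices, to reject isolated
color-noise hits) are reduced to centroids projected back onto the
surface. The tolerance of 60 is deliberately loose: sticker colors are
saturated primaries, far from skin and from each other, and scanner color
is noisy.

Numbering sorts all detected fiducials by azimuth about their centroid in
the belt plane and picks the rotation direction along which the anchor
numbers increase cyclically; this makes the labeling independent of any
global handedness convention and of rigid motion. When fewer whites than
label slots lie between two anchors, the slot assignment minimizing the
nonuniformity of implied per-step angular spacing — the sum over gaps of
`(gap_angle/gap_steps − arc_mean)²·gap_steps` — is found by exhaustive
search (at most C(6, k) cases per arc). The tests check this against an
independent brute-force oracle over both directions and all consistent
labelings.

## Leveling

The electrode plane is the total-least-squares plane (smallest singular
vector of the centered electrode matrix); the applied rigid map is the
*minimal* rotation taking its normal to +z plus the translation taking
the electrode centroid to the origin. We deliberately apply no in-plane
spin, so leveling an already-leveled scan is the identity; an optional
`align_theta` flag additionally puts electrode 1 at azimuth zero for a
fully reproducible body frame. Leveling twice is the identity to 1e-8 and
pairwise distances are preserved to 1e-9 mm (rigidity), both under test.

## The boundary model

The fitted surface is
r(θ, z) = Σ_{m=0..2N} Σ_{k=1..M} C[m,k] ψ_m(θ) φ_k(z), with ψ the
Fourier basis {1, cos θ, sin θ, …, cos Nθ, sin Nθ} and φ_k *normalized*
Gaussian kernels (a partition of unity) at M uniform heights spanning the
fitted z-range. Defaults N = 12, M = 7 give 175 free coefficients.
Choices that matter:

* **Normalized (partition-of-unity) Gaussians** rather than plain ones:
  constants are represented exactly — a circular cylinder fits to
  machine precision — and extrapolation beyond the z-range flat-clamps
  naturally.
* **Kernel width 1.25× the center spacing.** Wider kernels (1.5×) leave
  the coefficient matrix statistically unidentifiable: the smallest
  eigenvalue of the design Gram collapses to ~0.3 even at 20 000 samples,
  and coefficient recovery under 0.5 mm noise fails, while the fitted
  *surface* is indistinguishable. 1.25× restores identifiability
  (recovery RMS 0.08 mm in the tests) at no cost in fit quality.
* **Ridge 1e-8 (absolute), solved by QR** on the ridge-augmented system.
  The ridge exists only to break exact rank deficiency; at 1e-8 its bias
  on a noise-free round-trip is 6e-8 mm. The normal equations are avoided
  because the overlapping Gaussian columns square their condition number.
* Fits use at most 30 000 evenly thinned vertices — beyond that the
  coefficient variance is negligible against scanner noise.

The signed distance to the fit is measured radially at the query point's
azimuth (height flat-clamped). For belt-band geometries, whose surface
normals are nearly horizontal, this tracks the Euclidean distance closely;
it is exact on cylinders and is what the remesher projects onto.

## Electrode-encoded remeshing

The remesher is a force-equilibrium (distmesh-style) truss relaxation on
the fitted surface, run in (θ, z) parameters with forces computed on the
3D positions and nodes re-projected to the surface every step (projection
is free: the surface is a radius graph). The periodic seam is handled by
ghost copies within a 12% angular margin before each planar Delaunay
triangulation. The sizing field ramps linearly from `h_electrode` inside
each electrode disc to `h_background` beyond three disc radii — the ramp
extent is a mesh-grading stability choice. Electrode rims are seeded with
fixed nodes (spacing ≈ h_electrode), so each disc boundary is resolved by
edges and the facets inside are labeled with the electrode number.

Defaults follow the belt-EIT meshing convention: h = 0.5 mm at the
electrodes, 5 mm in the background, electrode radius 5 mm (1 cm
electrodes). Tests and the acceptance script scale h up (2–15 mm) and use
smaller phantoms; this keeps the suite minutes-scale while exercising the
same code paths, and the sizes are stated where used.

Three standard refinements stabilize the loop: density control every 30
iterations (points whose trusses are compressed past a factor two are
removed), a step-size cooling schedule in the second half of the
iteration budget (a closed periodic surface has no open boundary to drain
the Fscale pre-compression into, so a few nodes otherwise oscillate
indefinitely at fixed step), and a protection ring (free nodes that
settle within half an `h_electrode` of a rim are deleted before the final
triangulation, since they would otherwise knock rim edges out of the
Delaunay). Convergence is declared when the largest interior-node move
drops below 1e-3·h_background; hitting the 500-iteration cap close to
equilibrium returns with a message, far from it raises an error.

## Tetrahedral meshing

The volume mesh extrudes the closed boundary surface (the remeshed tube
plus flat triangulated caps at the z-range ends) through concentric
shells scaled toward the domain centroid. Each boundary triangle and its
scaled copy bound a prism, split into three tetrahedra by cutting every
quadrilateral face along the diagonal through its minimum-index corner —
a rule that is identical from both sides of a shared face (so the mesh
conforms) and, because bottom-layer indices are always lower than
top-layer ones, can never produce the cyclic untetrahedralizable
configuration. The innermost shell is fanned onto a center node. This is
exact for star-shaped domains, which the fitted belt-band geometries are
by construction, and the outer boundary reproduces the input surface
triangle-for-triangle, so electrode labels transfer by identity (checked
in the tests). The shell count defaults to filling the radius at roughly
1.6·h_background per shell (capped at 10); core elements are smaller but
lower-quality — acceptable for a potential problem, and the quality
report (`mesh_quality`) makes the distribution visible. The trade-off
against a general unstructured tetrahedralizer is deliberate: exact
boundary and label preservation, no external executable, and volumes
correct to a fraction of a percent, at the price of graded interior
quality.

## EIT forward model and reconstruction

The forward model is the complete electrode model with linear (P1)
elements: contact impedance 1e-3 Ω·m² per electrode (a standard skin
value; configurable), charge conservation, and the zero-mean electrode
potential gauge enforced by a Lagrange multiplier, which keeps the system
symmetric — measured reciprocity error is at machine precision. Node
coordinates convert to metres internally so conductivity is in S/m and
voltages in volts. The protocol is pairwise injection with skip 4 at
3 mA: injection pairs (i, i+5), and per injection every skip-4 voltage
pair not touching an injecting electrode — 29 readings × 32 injections =
928 measurements per frame. The 195 kHz carrier is metadata; the model is
real-valued at a single frequency.

The sensitivity of measurement (d, m) to element conductivity is the
adjoint formula −vol·∇u_d·∇u_m, assembled from the 31 electrode-basis
field solves of one factorization; a central-difference check agrees to
5e-8 relative. Difference images are one-step Gauss–Newton with standard
Tikhonov regularization on normalized data: b = (v1 − v0)/v0 elementwise,
Jn = J/v0 row-wise, δσ = (JnᵀJn + λI)⁻¹Jnᵀb, computed through the
equivalent 928×928 measurement-space system. "Normalized" is interpreted
as elementwise relative difference — the standard difference-EIT usage.
The default λ = 1e-7 comes from an L-curve sweep on the synthetic
two-lung phantom (image norm stabilizes over λ ∈ [1e-8, 1e-6] while the
lung means stay put); it is a starting point, not a universal constant,
and scales with the Jacobian normalization.

Tidal images average the frames at the inhale peaks (v1) and exhale
troughs (v0) of the global signal. The global signal is the per-frame sum
of unmasked voltage *magnitudes* — with signed skip-pattern voltages a raw
sum can cancel; magnitudes make the breathing modulation monotone.
Peaks/troughs come from prominence-based detection (prominence ≥ 25% of
the smoothed signal range, 0.25 s moving-average smoothing), which is
rate-agnostic and ignores noise ripples. The channel filter masks
channels whose relative first-difference variance — blind to the slow
breathing component, sensitive to broadband noise — exceeds
max(25×median, 1e-4), with a hard cap at 0.25; if fewer than half the
channels survive the recording is rejected.

## Validation metrics

Scan-to-scan and scan-to-truth electrode errors are RMS/max over the
labels present in both sets (occlusions drop pairwise), after
closed-form orthogonal Procrustes alignment on label correspondences
(rotation + translation, determinant +1, no scaling). Alignment is
necessary because each scan lives in an arbitrary scanner frame; the
tests verify invariance of the aligned error under rigid motion of either
input. Contour accuracy is the unsigned nearest-point distance to the
triangulation (exact point-triangle distances, shortlisted by a
nearest-vertex prefilter with a fall-back that guarantees exactness) or
to the fit (radial distance magnitude), summarized as mean ± SD.

## The synthetic phantom

`make_scan` builds an ellipse-based cross-section (axis ratio 1.0–2.0)
modulated by fixed-phase order-2 and order-3 cosine bumps and a mild
linear taper in z, calibrated by arc-length integration so the belt-plane
perimeter matches the request to 0.5%; defaults cover the study-like
range (perimeters 77–105 cm, axis ratios 1.1–1.5). The bumps break the
symmetry that would otherwise mask labeling bugs. Stickers are painted
discs (radius 6 mm, from 12 mm stickers) at equal arc-length spacing;
skin color is (200, 160, 140) against saturated sticker primaries, and
Gaussian vertex and color noise are applied after painting,
deterministically per seed. Tracked "pointer" outputs add isotropic noise
to the true centers and sample front/back contours above the belt.
Simulated recordings modulate two ellipsoidal lung regions as
σ(t) = σ0(1 − depth·(1 + sin 2πft)/2), forward-solving at 7 modulation
levels and interpolating per channel (the response is smooth in the
modulation), then applying multiplicative noise.

What the phantom does **not** emulate: scanner registration drift (its
noise is i.i.d. per vertex, which is why synthetic electrode RMS at 2 mm
noise sits near the low end of the 1–6 mm band that brackets real-scanner
behavior), photographic texture, partial scans and holes, breathing
deformation during the scan, and anatomical internals beyond the two
lung ellipsoids. Passing tests therefore demonstrate correctness of the
algorithms and their coupling, not scanner-grade error magnitudes on real
subjects.

## Problem sizes and determinism

The test suite and acceptance script run phantoms at 3 mm triangulation
resolution (≈14 000 vertices), meshes at h = 4/15 to 10 mm with 2–5
extrusion shells (≈20 000–75 000 tetrahedra), and 928-measurement
protocols — sizes chosen so the full chain, including 50-trial
localization statistics, completes in minutes on one CPU. Every random
step (phantom noise, remesher seeding, measurement noise) is seeded, and
the acceptance script derives all of its seeds from the single `--seed`
argument.

## Known limitations

* The boundary model is single-valued in radius about one axis; strongly
  concave cross-sections or off-axis belts violate it.
* Caps are flat; if the physical scan band ends on a sloped torso the
  modeled volume differs near the ends.
* Interior mesh quality degrades toward the extrusion core; for
  quantitative absolute-EIT work a graded unstructured mesher would be
  preferable.
* Multi-scan merging (subjects who cannot stand) and movement/boundary
  perturbation inverse methods are out of scope.
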