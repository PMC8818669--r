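---
title: "fusiflow: methods, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fusiflow: methods, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusiflow)
```

# Scope and model

Fusiform intracranial aneurysms are circumferential dilations of a cerebral
artery. Because they have no neck, the usual saccular morphometrics do not
apply; the quantity of interest is the lumen cross-sectional area (CSA)
along the vessel centerline, and the clinical classification threshold is a
dilation exceeding 1.5× the nominal vessel diameter. `fusiflow` implements
that profiling, the virtual restoration of the pre-pathological vessel, a
fast virtual deployment of a braided flow diverter, and the standard
shear/flow indices (AWSS, OSI, RRT, OVI, KE) over one cardiac cycle, so
that the fusiform / healthy / treated states of a case can be compared
quantitatively.

The package deliberately does **not** segment images, extract centerlines
from patient meshes, mesh volumes, or solve the Navier–Stokes equations.
Surface meshes, centerlines and time-resolved field exports are inputs;
the synthetic-data module generates all of them with ground truth for
verification.

# Geometry

*Frames.* Cross-section planes need a perpendicular frame at every
centerline station. We use rotation-minimizing frames (double-reflection
parallel transport), not Frenet frames: Frenet normals are undefined on
straight segments and flip at inflections, which would corrupt the ray fan.
No convention for the "perpendicular plane" is canonical in the literature;
ours is documented here and verified by a zero-holonomy test on closed
planar loops (twist < 1e-3 rad after a full 10 mm-radius loop).

*Resampling.* `resample_centerline()` places points at uniform values of
the **stored** arc-length coordinate and carries those coordinates over,
rather than re-measuring the chords of the coarser polyline: chord
shortening on curved lines (about (Δs/R)²/24 relative) would otherwise leak
into the station coordinates. Loading a centerline from CSV recomputes arc
length from the chords, since a file carries no parameterization.

*Cross-section area.* Rays are cast at uniform angles in the frame plane;
the first outward triangle intersection per ray (Möller–Trumbore, with a
plane-slab triangle prefilter) yields an ordered boundary polygon whose fan
area is the CSA. The fan-polygon convention (rather than a mesh/plane
intersection contour) is robust to nearby branches. Accuracy is oracle
tested: on a 0.05 mm-edge cylinder of radius 2 mm the error is < 0.5% at
360 rays, on a 2:1 elliptic lumen < 1%. Rays that miss are classified:
if a boundary ring lies within the radial scale of the section, the plane
crosses an open inlet/outlet ("section crosses open boundary"), otherwise
the origin was not interior.

# Detection and the morphology report

`nominal_diameter()` is the median equivalent diameter over proximal +
distal end windows — the median tolerates a dilation tail leaking into a
window. `detect_fusiform()` finds contiguous runs with
d_eq > 1.5·d_nominal (ratio configurable), picks the run with the largest
CSA if several exist, and extends it outward to where d_eq first falls
below 1.1·d_nominal. The parent-vessel reference CSA_PV is the station
immediately proximal to that bound (configurable to a proximal-window
mean), and RI = 100·CSA_A/CSA_PV is stored unrounded and reported as
integer percent.

Two consequences are worth stating plainly. First, the reference station
sits where the diameter is already within ~10% of nominal, so on a smooth
synthetic bulge RI is systematically below the naive apex/base area ratio;
the end-to-end test therefore compares the pipeline's RI against the value
obtained by applying the *same* reference convention to the generator's
analytic radius law. Second, no neck-absence test is implemented — the
discrimination is purely the circumferential diameter criterion, because no
operational neck test exists for these lesions.

# Healthy reconstruction

The reference procedure in this field is a manual sculpt: the pathological
wall is locally smoothed and shrunk toward the proximal and distal healthy
parent diameters. We automate it as radial remapping plus constrained
Laplacian relaxation:

1. every vertex whose orthogonal foot point lies in the modification span
   is moved radially onto the target radius at its station;
2. `iterations` (default 20) rounds of Laplacian smoothing (λ = 0.5) are
   applied to those vertices against their fixed neighbours, each round
   followed by radial reprojection onto the target.

The reprojection is essential: plain Laplacian smoothing is a discrete
mean-curvature flow and visibly shrinks a tube in 20 iterations, which
would defeat any profile-recovery guarantee. With the constraint, restored
profiles match the generator's healthy tube within 5% at every station (the
residual comes from the anchor tolerance and mesh discretization).

*Anchoring.* The target radius is a monotone cubic (smoothstep) between
two anchor radii. By default (`anchor = "nominal"`) the anchors are placed
where the measured diameter first comes within 1.5% of the nominal
diameter, walking outward from the detected region — i.e. the vessel is
shrunk toward the *healthy parent* diameters and the modification span
covers the dilation's full support. The alternative `anchor = "region"`
anchors exactly at the detected region bounds; since those sit near
1.1×nominal, it intentionally leaves that residual dilation in place. We
made nominal anchoring the default because the restored vessel is meant to
emulate the pre-pathological artery, not a 10%-dilated one.

Outputs are validated: manifoldness via edge-use counts, no degenerate
triangles, and exact triangle–triangle intersection tests restricted to the
modified region (uniform-grid broad phase; vertex-sharing pairs excluded;
the measure-zero exactly-coplanar case is not tested). Vertices outside the
span are bit-identical to the input — verified with `identical()`.

The diseased centerline is reused for the restored vessel: the dilation is
circumferential, so the medial curve is approximately preserved; this
avoids depending on an external centerline extractor.

# Virtual stenting

A braided flow diverter with nominal diameter D, braid angle β₀ to the
axis, and N_w wires (half per handedness) satisfies, per turn,

- pitch p₀ = πD/tan β₀,
- wire length l_t = πD/sin β₀,
- over-expansion limit d_max = l_t/π (pitch → 0).

Deployment marches proximally from the distal landing station; each turn
takes d = min(lumen d_eq, D_nom) and the wire-length-conserving pitch
p(d) = √(l_t² − (πd)²), until the template's turn count N_t = L_nom/p₀ is
exhausted. This reproduces the clinically important vessel-induced
shortening/elongation: a 3 mm/75° device in a 2.5 mm lumen elongates by the
closed-form factor p(2.5)/p₀ = 2.29, and the test suite checks total wire
length is conserved within 0.1% on every deployment.

Choices worth noting:

- β₀ defaults to 75°, a typical dense braid; sizing tables do not list it.
- Kinematics use nominal diameters and wires sit exactly on the d/2
  cylinder; the 42 µm strut radius enters only the apposition gap. Mixing
  it into the kinematics would shift the elongation closed form by <1% but
  break the exact conservation law the tests rely on.
- The apposition gap is the distance from a wire point to the nearest wall
  vertex minus t_s/2, floored at zero (a negative raw value means the strut
  radius overlaps the wall sample — contact). Vertex sampling overestimates
  the true surface distance by at most about half an edge length; use
  meshes with edges well below the 0.25 mm malapposition threshold.
- When the lumen exceeds d_max somewhere, the strict contract is an error
  ("stent cannot appose"); `on_overexpansion = "cap"` instead deploys at
  D_nom and lets the apposition map report the malapposition, which is the
  realistic treatment scenario in a wide fusiform bulge and is what the
  pipeline uses.
- Metal coverage = (wire length × t_s − crossings × t_s²/sin 2β)/lateral
  area. The rhombic crossing overlap (t²/sin γ, γ the crossing angle
  between the ±β families) matters: at dense-braid parameters the
  square-overlap approximation is ~13% off, outside the 10% band of the
  brute-force rasterization oracle the tests run.
- Crossings are geometric; no contact mechanics, so opposite-handed wires
  interpenetrate by up to t_s at crossings. Landing position is user input.

# Boundary conditions

Inflow: a reference waveform is scaled to a case inlet preserving its
normalized shape. The default policy matches mean velocity (Q ∝ A); with
the mean-flow-proportional-to-area policy defined the same way, the two
coincide — both names are kept because configs refer to them. The scaling
law used by any particular lab is rarely published; this one is documented
and linear.

Outflow: fractions ∝ d^n (n = 3 by default, configurable 2–3). `"murray"`
uses the terminal equivalent diameter of each outlet branch;
`"shape_based"` uses the branch-averaged equivalent diameter, so the split
reflects the distal vessel's shape rather than one terminal section — the
two coincide exactly on untapered branches (a tested degenerate case).

# Hemodynamic indices

All integrals are periodic trapezoids: the first sample is reused at
t₀ + T, making constants exact, uniform sampling of sinusoids
spectrally accurate, and every index invariant under cyclic shifts of the
timestep ordering. Inputs must span a single cycle; `last_cycle()` trims a
multi-cycle export to its final period (the convention of simulating two
cycles and discarding the first). Degenerate denominators are defined here
because conventions vary: OSI/OVI are 0 where the shear/velocity vanishes
over the whole cycle, and RRT is capped at 1/ε (ε = 1e-9 Pa) and flagged
where (1 − 2·OSI)·AWSS < ε. KE is exposed as a density (J/m³) per point
plus its time average; volume-weighted summaries (`index_summary()` with
cell-volume weights) provide the integral form when wanted. The viscosity
entering analytic fields is dynamic, μ = 4 mPa·s (the value is stated in
mPa·s in the source literature even when labelled ν); kinematic viscosity
where needed is μ/ρ ≈ 3.79e-6 m²/s.

# Synthetic data: the stated world

`make_vessel()` builds surfaces of revolution with radius law
r(s) = r0 + (r_p − r0)·exp(−(s − s_c)²/2σ²) about straight, arc or helix
centerlines; seeded uniform vertex jitter (≤5% of edge length) exercises
robustness. Ground truth (radius law, healthy tube) is returned alongside,
which is what closes the verification loop: profiling a generated vessel
recovers r(s) within 1%.

The reference cardiac waveform is a two-harmonic synthetic stand-in
(T = 1 s, a₁ = 0.4, a₂ = 0.15, φ₁ = 0, φ₂ = π/4, Q₀ = 3 mL/s): positive,
periodic, pulsatility index ≈ 1.1. It is explicitly *not* a measured
waveform; no published table of the 4D-PC-MRI curve it stands in for is
available.

`womersley_fields()` emits the exact pulsatile solution in a straight rigid
tube (Poiseuille steady part; per-harmonic Womersley profiles with
α = R√(ωρ/μ)), as velocity samples on a polar grid and the matching
analytic wall shear, over **two** cycles. Complex Bessel functions J₀/J₁
are evaluated by power series for α ≤ 21 (relative error ≲1e-9) and by the
Stokes-boundary-layer asymptotic form above (validated range (0, 50]; the
two branches agree to ~2% at the switchover, consistent with the O(1/α)
truncation). What the generator does *not* emulate: curved or compliant
walls, secondary flows, turbulence, non-Newtonian rheology, or any flow in
a stented geometry — a green index test establishes correct integration of
fields, not CFD fidelity.

The three-state test fixture drives the same tube with strong (fusiform),
damped (treated) and mild (healthy) oscillatory harmonics; it encodes the
qualitative claim "treatment damps oscillation" so that `compare_states()`
flag logic is testable, nothing more.

# Tolerances and determinism

| Quantity | Tolerance | Source |
|---|---|---|
| ray-cast CSA, cylinder 0.05 mm edges | 0.5% | discretization bound |
| restored profile vs healthy tube | 5% | design choice (no published target) |
| wire-length conservation | 0.1% | discretization at 72 pts/turn |
| L_dep at nominal lumen | 0.5% | kinematic identity |
| index closed forms | ≤0.5% | trapezoid order |

Everything is deterministic given the seed: generators use a local RNG
stream, deployments are closed-form sweeps, and `run_case()` records a
config hash (FNV-1a) plus the seed in every report; re-running a config
yields byte-identical JSON.

# Known limitations

- The CSA_PV convention (single adjacent proximal station) makes RI
  sensitive to the 1.1× region-bound rule on smooth bulges; the
  proximal-window mean is provided as an alternative.
- Apposition uses vertex-sampled wall distances, adequate at sub-0.1 mm
  edges but not a signed closest-point query.
- The stent model has no contact mechanics or friction; deployed length in
  strongly curved vessels ignores second-order bend effects (~(a/R_bend)²).
- Self-intersection checking covers the modified region only, and not the
  exactly-coplanar case.
- The Case-2-style configuration (two inlets) is not modelled by the
  single-centerline pipeline; multi-inlet cases need per-branch runs.
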