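---
title: "Reconstructing hydrogel pore geometry from particle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing hydrogel pore geometry from particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porehull)
```

## The measurement problem

Hydrogels such as crosslinked PEG have two distinct length scales of
porosity. The *mesh size* — the distance between polymer crosslinks — is on
the order of a nanometre and controls the diffusion of small solutes. On top
of the mesh, polymerization defects create *micropores*, cavities of several
to hundreds of micrometres. Cross-sectional electron microscopy can image
micropores but requires freezing and fracturing the sample, and a 2D section
rarely cuts a pore through its widest extent. Tracking fluorescent tracer
beads trapped inside the pores probes the same structures in the native,
hydrated state: a bead rattling around a cavity repeatedly collides with its
walls, and over time its recorded positions trace out the cavity interior.

`porehull` implements the full analysis chain for such an assay, and a
seeded confined-Brownian-motion simulator that generates ground-truth
trajectories for every step of it.

## Models and estimators

### Mean squared displacement

For beads indexed by $i$ with positions $\mathbf{p}_i(t)$, the package uses
the displacement-from-origin ensemble MSD

$$\mathrm{MSD}(t) = \frac{1}{N_t}\sum_{i=1}^{N_t}
  \lVert \mathbf{p}_i(t) - \mathbf{p}_i(0) \rVert^2,$$

averaged at each frame over the $N_t$ tracks present at that frame. This is
*not* the lag-time-averaged MSD of microrheology: for confinement analysis
the reference point is each bead's own starting position, because a bead
confined in a pore has a maximum attainable displacement from where it
started, so the curve saturates at a plateau set by the pore size.

Two quantities are extracted:

* **Diffusion exponent** $n$, from $\mathrm{MSD} = 6 D t^n$ fitted as the
  ordinary-least-squares slope of $\ln \mathrm{MSD}$ against $\ln t$
  ($t = 0$ excluded; the whole curve by default). $n = 1$ is free diffusion,
  $n < 1$ sub-diffusive, confined motion. The intercept recovers the
  effective $D$. For planar data the prefactor is kept at 6 for consistency
  across assays; this scales `effective_D` but does not affect $n$.
* **Diffusion length**, the square root of the plateau MSD extrapolated to
  time zero by a linear fit over the plateau window. It is a proxy for the
  average pore diameter: for a bead equilibrated uniformly in a spherical
  accessible region of radius $R$ the expected plateau is
  $2 \times \tfrac{3}{5} R^2$, giving a diffusion length of
  $\approx 1.1 R$ — the same order as, but not identical to, the diameter.

**Plateau detection.** The plateau window, when not supplied, is the longest
suffix of the curve whose *suffix-wide* log–log OLS slope is below 0.1,
required to cover at least 20% of the timepoints. An earlier design used the
frame-to-frame local slope, but for realistic ensemble sizes the late-time
spacing of $\ln t$ is so small that pointwise slopes are pure noise; the
suffix regression pools all later points and is stable from a handful of
beads upward. A curve with no qualifying suffix (e.g. free diffusion) raises
a regime error rather than returning a meaningless intercept.

### Convex-hull pore models

Discarding the time dimension, each track is a point cloud bounded by the
pore walls, and the *convex hull* of the cloud — the smallest convex
polytope containing it — is the geometric model of the pore. From the hull
the package reports volume, surface area, the **Feret diameter** (largest
pairwise vertex distance), and the **sphericity**
$\pi^{1/3}(6V)^{2/3}/S$, which is 1 exactly for a sphere.

The 3D hull is computed by an incremental algorithm written for this
package (no 3D computational-geometry package is part of the stack):
an initial tetrahedron of extreme points is grown point by point; for each
point outside the current hull the visible faces are removed and replaced by
the cone of triangles from the horizon edges. Points within a relative
tolerance of $10^{-9}$ of a face plane are treated as interior, so hull
vertices are always a subset of the input localizations. The test suite
checks the implementation against an exhaustive facet-enumeration oracle on
small random clouds and against closed-form solids. 2D hulls delegate to
`grDevices::chull()` and are canonicalized to a closed counterclockwise
ring starting at the lowest-(y, x) vertex, which the centroid formula
requires.

**Bead-size correction.** Tracking reports the bead *centroid*, which can
approach a wall no closer than one bead radius, so raw hull diameters
under-report the pore by one bead diameter. The corrected diameter is
`diameter_raw + bead_diameter`. Only the diameter is corrected: correcting
volume or surface area would require a full Minkowski dilation of the hull
by the bead radius, which is deliberately out of scope, and the uncorrected
values carry a documented downward bias instead.

**Track eligibility.** Hulls of very short tracks grossly under-sample
pores, so tracks shorter than `min_track_length` (default 10 localizations —
a pragmatic floor; the assay literature states none) are excluded from hull
building but retained for the MSD. Degenerate clouds (coplanar in 3D,
collinear in 2D) are skipped with a recorded reason, never silently
projected to a lower dimension, because silent dimension changes would
corrupt the pore-population statistics.

### Simulated SEM sections

To compare the 3D pore population against cross-sectional micrographs the
package simulates what a section shows: pores are drawn uniformly at random
(seeded) until their total volume reaches a budget (default
$3\times10^5\,\mu m^3$; the draw stops just before the pore that would
exceed it, so the sampled volume is "equal or a little less than" the
budget); each selected pore is flattened by dropping the z coordinate of its
hull vertices and re-hulling in 2D; pores below a resolution floor (minimum
diameter supplied by the user from the micrographs; minimum area default
$10\,\mu m^2$) are removed. Because projection can only contract pairwise
distances, a flattened diameter never exceeds its 3D source — this single
inequality is the mechanism by which 2D imaging systematically
underestimates pore size, and it is asserted per pore in the tests.
Flattening is along z only, matching how a section is imaged; a
random-plane mode was considered and rejected as untestable against the
assay it emulates. Distribution comparisons use the two-sided Mann–Whitney
U test (`stats::wilcox.test`; Bonferroni via `stats::p.adjust` when several
pairs are tested).

### Pseudo-2D pore maps

Flattened pores overlap when plotted at their original coordinates, because
distinct z-planes collapse onto one. Two overlap-free layouts are provided:

* **fixed gap** — pores in a row, consecutive bounding boxes separated by a
  configurable gap (default 10 µm) along x;
* **packed** — one placeholder circle per pore with diameter equal to the
  pore's 2D Feret diameter (the Feret is used, consistent with how pore
  diameter is defined everywhere else in the package), circles packed by a
  front-chain algorithm, then each pore translated so its polygon centroid
  (shoelace formula over the closed CCW ring) sits on its circle's centre.

The packer is a port of the front-chain circle-packing algorithm used by
d3/packcircles: each circle is placed tangent to two circles of the
advancing front, and front circles that would be overlapped are spliced out
of the chain before retrying. Input order is preserved (the algorithm is
order-sensitive; sort by decreasing diameter for densest-first placement).
A deterministic tangent-candidate fallback — all positions tangent to a
pair of placed circles, nearest to the origin, overlap-checked against
*all* circles — guards the zero-overlap contract in chain configurations
the front-chain heuristic cannot resolve; in the property tests it is never
needed, but it makes the no-overlap invariant unconditional. The overlap
tolerance is $10^{-9}\,\mu m$. Repositioning is translation only — no
rotation — so all per-pore metrics survive the layout exactly.

### Flory–Rehner mesh size

The nanometre mesh scale is computed from an equilibrium swelling assay:
mass swelling ratio $Q_m = (m_{wet}-m_{dry})/m_{dry}$ for the relaxed and
swollen states, volumetric ratio $Q_v = 1 + (\rho_p/\rho_s)(Q_m - 1)$,
polymer volume fractions $\upsilon = 1/Q_v$, then the Flory–Rehner relation

$$\frac{1}{M_c} = \frac{2}{M_n} - \frac{(\bar{\upsilon}/V_1)
 \left[\ln(1-\upsilon_{2s}) + \upsilon_{2s} + \chi_1\upsilon_{2s}^2\right]}
 {\upsilon_{2r}\left[(\upsilon_{2s}/\upsilon_{2r})^{1/3}
 - \tfrac{1}{2}(\upsilon_{2s}/\upsilon_{2r})\right]}$$

and the mesh size $\xi = \upsilon_{2s}^{-1/3}\, l \sqrt{2 C_n M_c / M_r}$.
Units are self-consistent without hidden conversions:
$\bar{\upsilon} = 1/\rho_p$ in cm³/g against $V_1$ in mL/mol (cm³ = mL),
and $l$ in nm makes $\xi$ emerge in nm. The $2/M_n$ term takes the polymer
molecular weight *before* crosslinking (the quantity sometimes loosely
attributed to $M_c$ in derivations is contextually $M_n$; the package
follows the formula's requirement). The logarithm is evaluated exactly, not
series-truncated. A network whose fractions make $1/M_c \le 0$ (strong
deswelling) is reported as infeasible rather than returning a negative
molecular weight. Defaults are the usual PEG/PBS constants:
$\rho_p = 1.125$, $\rho_s = 1.011$ g/cm³, $V_1 = 18$ mL/mol,
$\chi_1 = 0.426$, $M_r = 44$ g/mol, $l = 0.15$ nm, $C_n = 4$.

## The simulator and what it does (not) emulate

`simulate_free()` draws independent Gaussian steps with per-axis variance
$2D\,\Delta t$, $D$ from Stokes–Einstein
$D = k_B T / (6\pi\eta r)$ with $k_B = 1.38\times10^{-23}$ J/K. Defaults
are the assay conditions throughout: $T = 300$ K, $\eta = 0.001$ Pa·s,
1 µm beads ($r = 0.5\times10^{-6}$ m, $D \approx 0.439\ \mu m^2/s$), 5 s
frames, 180 frames (a 15-minute acquisition).

`simulate_confined()` confines the walk to a sphere, cylinder
(microwell, default depth 45 µm), box, or arbitrary convex polyhedron,
*eroded by the bead radius*: the centroid never approaches a wall closer
than $r$, which is exactly the geometric fact the bead-diameter correction
compensates. Wall collisions use specular-style reflection (folding the
overshooting step back across the wall) rather than rejection sampling, so
step-length statistics are preserved; for the curved walls the fold is
radial, an approximation that is exact in the wall-normal direction and
immaterial at step lengths well below the geometry size. Initial positions
are uniform in the accessible region. Every output is fully determined by
the seed, and panel simulations derive per-well seeds from the master seed
so panels are reproducible element-wise.

Optional realism knobs, all off by default so that geometric tests are
exact: Gaussian localization noise (suggested σ = half a 0.46 µm pixel) and
1 µm z-stack quantization. The simulator does *not* model hydrodynamic wall
coupling, bead–polymer adsorption, or anything anomalous beyond
confinement. Consequently, passing tests demonstrate the correctness of the
estimators on ideal confined Brownian data — they do not certify
performance on tracks corrupted by localization error, drift, or
non-convex pores (a convex hull of a non-convex cavity overestimates its
volume by construction; alpha-shape reconstruction is a non-goal).

## Problem sizes used in the checks

The validation suite chooses ensemble sizes large enough for each property
to be statistically sharp while keeping a laptop run short:

* free-diffusion calibration and the exponent check use 1000 beads × 180
  frames (exponent sampling error well under the ±0.05 band);
* the in-silico microwell panel (wells of 9, 12, 30, 55, 175, 250 µm,
  depth 45 µm, 1 µm beads, 20 tracks per well) scales steps per well as
  $8 R^2/D$ with a floor of 2000 steps, because a track must traverse its
  well many times before its hull saturates — with a fixed 2000 steps a
  250 µm well simply cannot be filled within the simulated time
  ($R^2/D \approx 3.6\times10^4$ s against $10^4$ s simulated);
  the recovered-vs-true diameter regression then has slope ≈ 1.00 and
  $R^2 > 0.999$;
* the 18 µm spherical-pore recovery uses 5 beads × 10⁴ steps (hull
  diameter within 10%, sphericity > 0.9 and increasing with step count);
* the packing audit covers 100 seeded panels of up to 200 circles.

## Numerical choices

* Hull degeneracy tolerance: $10^{-9}$ relative to the coordinate scale;
  containment asserted to $10^{-9}\,\mu m$.
* Plateau rule: suffix log–log slope < 0.1, window ≥ 20% of timepoints,
  ≥ 3 points; negative plateau intercepts raise an error advising a later
  window instead of returning an imaginary diffusion length.
* Regime classification band: $|n - 1| \le 0.05$ counts as free.
* Packing: overlap tolerance $10^{-9}\,\mu m$; tangency is exact up to
  floating-point placement error (~$10^{-11}\,\mu m$ at panel scale).
* MSD grouping snaps times to the frame grid
  (`round(t / frame_interval)`), so float jitter in exported track times
  cannot split frames; tracks of unequal length contribute to each frame's
  average while they last ($N_t$ varies per frame).
* Seed splitting uses a fixed linear-congruential rule with values kept
  below $2^{31}$, and all seeded code paths restore the caller's RNG state.

## Known limitations

* Convexity is assumed; interconnected or concave pores are modelled by
  their convex envelope.
* Volume and surface area are not bead-corrected (documented bias; see
  above).
* The diffusion length is a pooled-ensemble estimate; per-sample fitting
  (e.g. per-gel replicates) is left to the caller by subsetting tracks.
* Tracks touching the imaging-volume boundary are not excluded by default;
  a caller worried about clipped pores in a finite z-stack should filter
  tracks before hull building.
* The pipeline's SEM stage requires `min_diameter` explicitly, because a
  resolution floor is a property of the reference imaging, not of this
  package — there is no defensible default.
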