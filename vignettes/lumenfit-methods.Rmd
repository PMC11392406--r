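---
title: "Reconstructing vessel surfaces from cell junction contours: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing vessel surfaces from cell junction contours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lumenfit` reconstructs the apico-luminal surface of an approximately
straight blood vessel — the motivating system is the zebrafish dorsal aorta
between 48 and 72 hours post fertilisation — using nothing but manually
annotated 3D contours of the endothelial cells' junctions, and then
quantifies both vessel geometry and the 3D morphology of every cell. This
vignette explains the models, the estimation procedures, the tunable
parameters and the numerical choices, and states what the synthetic-data
checks do and do not demonstrate.

## The problem

Endothelial junction markers label only a sparse net of curves on the
vessel wall. Any single axial position therefore carries far too little
information to outline the local cross-section, and the annotations live in
an arbitrary microscope ("mounting") coordinate frame. The package solves
three coupled problems: (1) turning noisy, unevenly spaced, doubly
annotated junction polylines into smooth closed curves; (2) estimating a
vessel-intrinsic coordinate system and a dense sequence of cross-sectional
shapes from the pooled curves; (3) delimiting and triangulating each cell's
surface patch on that reconstruction so that areas, perimeters,
compactness, elongation and circumferential position are well defined in
micrometres.

## Contour preprocessing

**Enrichment.** Each cell is annotated independently, so shared junctions
are annotated twice. For every cell the package inserts those points of
*other* cells that fall inside a cylinder of radius `r` (default 1 µm)
and length `‖p⁺ − p‖ + 2·dh` (default `dh` = 1 µm) around an edge of the
growing contour; a point inside a cylinder core is placed into the edge of
minimal orthogonal distance, a point caught only by a cylinder's extension
(sharp bends) is attached next to its nearest contour point on the side of
that point's nearer neighbour. The iteration order over foreign points
(ascending cell id, then point index) is fixed for reproducibility, since
insertions change which edges exist for later candidates. A point
duplicating an existing point of the growing contour to within 1 nm is
skipped: annotations of the same junction by two cells are almost never
bit-identical in practice, and admitting exact duplicates would create
zero-length edges.

**Interpolation and splines.** Straight segments are annotated sparsely, so
`floor(n_interp_rel · edge length)` equally spaced points are interpolated
per edge (default 2/µm). A periodic cubic smoothing spline
`s : [0,1] → R³`, parameterised by normalised cumulative chord length, is
then fitted per cell on a cyclic cubic regression-spline basis; the
smoothing parameter is chosen by bisection as the *largest* value whose
residual sum of squares still satisfies `SSR ≤ eps_spline · n` (default
0.1 µm² per point). This realises the classic tolerance formulation of
smoothing splines: `eps_spline` bounds the mean squared distance between
annotation and curve, independent of cell size. The basis dimension starts
near `min(n, 220)` and doubles if the tolerance is unattainable, so the
bound holds by construction. Equidistant samples
(`floor(n_spline_rel · arclength)`, default 2/µm, first sample at parameter
0) homogenise each cell's information content; arc lengths are computed
from densely sampled chords (relative error below 1e-6) and parameters
inverted by monotone interpolation.

## The cross-sectional shape model

A vessel cross-section is modelled as two half-superellipses joined at the
horizontal line through a midpoint `(m_x, m_y)`:
dorsal half `|x/c|^(2/α) + |y/a|^(2/α) = 1` (y ≥ m_y) and ventral half with
semi-axis `b` and exponent `β`. `α = β = 1` gives an ellipse and
`a = b = c` then a circle; exponents below 1 flatten the arc towards a
rectangle, which captures the dorsal flattening seen in the dorsal aorta
while leaving the ventral half free to stay round. Exponents are bounded to
[0.05, 2]: the lower bound avoids numerically degenerate corners, and the
upper bound keeps the implicit exponent `2/α ≥ 1`, i.e. both halves convex
and the curve simple. Convexity is load-bearing: the symmetric-difference
deviation between two shapes,
`dev_cross(φ; φ_ref) = area(φ △ φ_ref) / area(φ_ref)`,
is computed exactly (up to polygonal approximation, default 360 vertices)
by Sutherland–Hodgman clipping against the convex reference; a
deterministic lattice fallback covers non-convex references such as
measured angiogram outlines. Since the superellipse admits no closed-form
point distance, projections go through the dense polygon; arc length uses
adaptive quadrature of the analytic speed (singular but integrable at the
quarter points for exponents < 1), and equidistant sampling uses an
adaptively refined chord table so that spacing is uniform in arc length to
well under 1%.

The trigonometric parameterisation (`x = m_x + c·sgn(cos u)|cos u|^α`, …)
concentrates parameter speed near the axis points; because all downstream
consumers use *equidistant* points in arc length, results are independent
of this choice. Floating-point residues of `cos`/`sin` at the axis
parameters are snapped to zero before exponentiation — `(6e-17)^0.05` is
0.15, not 0, and would visibly displace the apex otherwise.

## Coordinate frame and mean shape

The frame (x left→right, y ventral→dorsal, z anterior→posterior) and a
single *mean shape* (midpoint pinned to the origin) are estimated jointly
by minimising the summed squared distances of all xy-projected spline
samples to the shape. The z-axis is initialised from the first principal
component (sign-matched to the annotated anterior–posterior vector), the
y-axis from the annotated dorsal–ventral vector orthogonalised against z.
Estimation alternates (i) a 7-parameter shape fit at fixed frame, with the
midpoint absorbed into the translation afterwards, and (ii) a 5-parameter
frame refinement (three rotations, in-plane translation), until the
objective improves by less than 1e-6 relative or 50 iterations. Axis signs
are then disambiguated against the annotations: an upside-down solution is
rotated 180° about z (swapping the roles of `a, α` and `b, β`, which leaves
the geometry unchanged), a reversed axis 180° about y (under which the
mirror-symmetric shape is invariant), and a left–right annotation that
still disagrees is reported as a warning. The mean shape is refitted once
at the final frame on all points.

Two estimator properties matter for interpretation. First, the raw
parameter vector is not identifiable: midpoint, semi-axes and exponents can
trade off along nearly identical curves, so recovered parameters should be
compared in shape space (`dev_cross`), not element-wise. Second, because
annotations are denser on curved contour segments, the pooled objective is
a sampling-weighted fit; on realistic densities its optimum can tilt by
about a degree relative to the generating frame even without noise. The
frame is, however, exactly equivariant: applying a rigid transform to the
data moves the estimate by that transform to within millidegrees, so all
derived measures are invariant to mounting orientation. A perfectly
circular vessel leaves the in-plane rotation undetermined (only the
annotated dorsal–ventral vector then orients the frame); any dorsoventral
asymmetry pins it.

## Local cross-sections, smoothing, grid

`M = floor(M_rel · z-extent)` equidistant planes (default 2/µm) span the
data. At plane k, every spline sample contributes with a truncated
Gaussian weight `exp(−Δz²/2ω_k²)` (zero beyond `Z_omega·ω_k`); `ω_k` is
chosen *minimal* such that each of the eight 45° octants around the origin
holds at least `n_oct` (default 30) points with non-zero weight — a closed
form: the maximum over octants of the `n_oct`-th smallest axial distance,
divided by `Z_omega`. Planes with an under-populated octant are skipped and
logged. The local shape minimises the weighted sum of *unsquared*
projection distances starting from the mean shape, subject to
`dev_cross(φ_k; mean shape) ≤ λ` (default 20%), which suppresses local
overfitting where one side of the vessel has only low-weight points;
`λ = 0` returns the mean shape itself, and a `squared_residuals` switch is
provided because squared least squares is the more common convention. The
bound-constrained fit runs L-BFGS-B against a coarsened polygon (the chord
sag of a 90-gon at a 10 µm radius is ~6 nm, far below annotation noise)
with a short full-resolution polish; if the unconstrained optimum violates
the deviation bound, a penalty refit followed by a bisection blend towards
the (always feasible) mean shape enforces `dev ≤ λ + 1e-6` exactly.

The seven parameter sequences are then convolved along z with a Gaussian
kernel (SD `sigma`, default 10 µm, truncated at `Z_sigma·sigma` and
renormalised over the available window at the boundaries and across skipped
planes; `sigma = 0` disables smoothing). Note the interaction between
`sigma` and axial shape variation: a 10 µm kernel attenuates a sinusoidal
variation of period 100 µm by ~18%, which is the main contribution to the
residual per-plane deviation on the synthetic tube. Finally each smoothed
shape is sampled into `floor(n_cross_rel · circumference)` equidistant ring
points (default 2/µm), forming the organized grid. `Z_omega = Z_sigma = 2`
by default: beyond two standard deviations the Gaussian tails carry under
5% weight, and truncating there keeps both the weighting and the smoothing
strictly local.

## Cell projection and triangulation

Each transformed cell spline is traversed densely (at least 512 samples,
4× its equidistant count); every crossing of a grid plane is refined by
bisection to 1e-10 in the parameter and snapped to the nearest ring point.
Consecutive duplicates collapse; a crossing pair that skips a plane
indicates a spline too coarse for the plane spacing and raises an error.
One refinement matters for area bookkeeping: a contour segment running
shallowly between two planes (a tangent dip at a cell's top or bottom, or
a near-horizontal boundary stretch) links crossings that are far apart on
the surface, and the straight chord between them would cut through the
vessel interior, inflating the triangle areas of both adjacent cells.
Such segments are re-traced along the nearest ring points on the side the
spline actually travels, so projected contours follow the surface
everywhere and the cell meshes of a full tessellation conserve the grid's
lateral area to a fraction of a percent.

Because contours may be annotated clockwise or counter-clockwise, which
side of the contour is "the cell" is ambiguous from the data. The package
decides geometrically in an unrolled chart (circumferential arc fraction,
plane index): ring points strictly inside the projected contour's chart
polygon — decided by parity of bridge-edge crossings both above and below
the ring — are the cell's interior grid points, which is the chart
equivalent of extracting the contour's side by flood fill from an interior
seed. Between each pair of neighbouring planes the two within-cell ring
paths are joined by a greedy strip of triangles, each using two adjacent
points on one ring and one on the other, with interior points linking to
their nearest neighbour on the opposite ring; the end edges of each strip
are exactly the contour's bridging edges, so all projected-contour edges
are mesh edges. After construction the boundary-edge multiset is verified
to equal the contour's edge multiset; a mismatch (possible for deeply
non-convex cell regions whose chart notches span more than a plane
spacing) raises an error rather than returning a wrong mesh. Cells winding
once around the vessel are meshed as full-ring bands.

## Morphometrics

Luminal area is the shoelace area of a ring polygon, luminal diameter the
maximal pairwise point distance. Cell surface area is the sum of mesh
triangle areas and the perimeter the total projected-contour edge length;
compactness `4π·area/perim²` is 1 for a circle. Compactness can
numerically exceed 1 when a poorly projected contour short-cuts across a
curved patch; such cells are flagged and, in practice, removed by the
projection-distance filter. Elongation divides the cell's z-extent by its
cross-sectional extension, taken as the smallest circular arc (about the
per-plane shape midpoints) covering the cell's angular range, evaluated at
the cell's median radial distance — the one genuinely open convention in
the measure set, chosen because it matches the "bounding box spanning the
angular range" description and is exposed in the documentation. A cell
whose covered directions leave no angular gap larger than a few point
spacings counts as fully wrapping and uses the full circumference.
Classification assigns each triangle's centroid to dorsal/ventral/left/
right quadrants split on the ±45° diagonals (boundary angles to the
counter-clockwise-next sector): a cell is dorsal or ventral if that sector
exceeds 50% of its area, left/right if either lateral sector alone does.
The detailed variant merges left+right and uses a 75% threshold for pure
labels, appending to a 50–75% leader every sector holding at least half of
the remainder, ordered by fraction. Dispersion is summarised by the
quartile coefficient of dispersion `(Q3 − Q1)/(Q3 + Q1)` with type-7
quartiles; relative deviations use `(altered − reference)/altered`.

Two exclusion filters run before reporting: cells whose symmetric
annotated-vs-projected contour distance (mean of point-to-segment
distances after densification to 0.1 µm, maximised over the two
directions) exceeds 0.742 µm — the annotation-uncertainty scale — and
planes with fewer than 2 annotated cells within 0.5 µm. Both thresholds
are configurable.

## Synthetic vessels

`tube_spec()`/`simulate_vessel()` generate the ground truth every test is
measured against: by default a 100 µm tube whose seven shape parameters
vary sinusoidally along the axis around an aorta-like calibre
(`a ≈ 9, b ≈ 11, c ≈ 10` µm, mild dorsal flattening `α ≈ 0.75`, midpoint
drifting by ±0.5–0.6 µm), with amplitudes of 0.6–0.8 µm on the semi-axes —
chosen so local shapes stay well inside the default 20% plausibility bound
while still varying visibly. Cells are Poisson-disk seeds in the unrolled
chart with (power-diagram) Voronoi boundaries — convex in the chart,
matching the roughly hexagonal patches of real endothelium. An optional
dorsal size bias deserves a note: thinning dorsal seed density alone does
not survive the downstream read-out, because the Poisson-disk hard core
homogenises cell areas and, above all, large cells spill past the
90-degree dorsal sector and escape the majority-vote classification, so a
1.3-fold density contrast reads out as barely 1.1. The generator therefore
thins dorsal seeds *and* calibrates a power-diagram weight on them, by
bisection, until the realised quadrant-classified median dorsal/ventral
cell-area ratio equals the requested factor — "dorsal cells are 1.3 times
larger" is made true in exactly the sense in which it is later measured.
Because classified medians over a handful of dorsal cells are dominated by
sampling noise, asymmetry-recovery checks pool cells over two generator
replicates of 40-cell vessels and read the ratio from all meshed cells
(the projection-distance filter correlates with cell size and would bias
the dorsal median downwards; it is exercised separately).
Annotation is emulated by discretising each boundary with a chord-error
criterion (denser points on bends, straight segments between consecutive
points), duplicating shared junction points in both adjacent cells, adding
per-cell isotropic Gaussian noise (default SD 0.25 µm, the annotation
uncertainty scale), and applying a random rigid mounting transform with
5°-jittered axis annotations. All randomness flows from one seed;
generation is bit-reproducible.

What passing synthetic checks shows — and what it does not: the generator
produces exactly superelliptic cross-sections, chart-convex cells and
isotropic noise, so recovery results demonstrate correctness of the
estimation machinery, not robustness to out-of-model effects such as
intersegmental-vessel bending, annotation outliers, curved centrelines or
non-superelliptic lumen shapes. The filters and the goodness-of-fit
measures are the designed line of defence for those, and cells or planes
failing them are reported, never silently dropped.

## Problem sizes and numerical defaults

The bundled checks run the full pipeline on a 100 µm / 25-cell / 0.25 µm
noise tube at the default resolutions (200 planes, ~130 ring points per
plane); the robustness scan re-estimates the same vessel seven times at half
the axial resolution, and the mesh-conservation check uses a
noise-free 40 µm / 10-cell vessel on a doubled-density grid with a tighter
spline tolerance (0.005 µm²), since that property isolates the meshing
rather than annotation smoothing. Key tolerances: spline arc length 1e-6
relative; plane-crossing bisection 1e-10 in parameter; constraint
enforcement `λ + 1e-6`; shape polygon 360 vertices (optimisation stage 90);
`omega` floored at 1e-6 µm; duplicate guard 1e-9 µm. Deviations from the
printed sources worth knowing: the per-plane objective uses the unsquared
norm (switchable), smoothing acts on raw parameter scales, and quartiles
are type 7.

## Known limitations

Straight vessels only (no curved centreline, no branches); cell patches
must be chart-convex up to sub-plane-spacing wiggles, else their
triangulation errors out; the absolute frame orientation carries a ~1°
sampling-density bias (equivariance is exact); compactness above 1 flags a
projection problem rather than biology; and the detailed classification's
remainder rule is one of several defensible readings of a compound-label
scheme.
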