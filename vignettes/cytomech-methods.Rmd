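---
title: "Modelling the first embryonic cleavage: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the first embryonic cleavage: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

The first embryonic division of a large egg cell is treated as a
mechanical process: an actomyosin contractile ring constricts the
equatorial cleavage furrow, and the remaining cytoplasm responds as a
passive, nearly incompressible elastic continuum. The cell starts as a
sphere; as the furrow band is drawn inwards the displaced matter pushes
the poles apart, producing the characteristic sphere-to-dumbbell shape
change and a polar elongation of 30% or more. Two environmental factors
modulate this picture: the vitelline envelope, a stiff extracellular
sphere that can confine the deforming cell, and (indirectly, through
envelope dilation) temperature. In small eggs a third force generator
matters: the mitotic spindle, whose pole separation is bounded near
60 um regardless of cell size, is long relative to a 100 um egg and
contributes directly to polar elongation.

`cytomech` implements this model as an incremental finite-element
simulation, together with the measurement pipeline used to extract the
corresponding quantities from time-lapse masks of real dividing cells,
a stepwise procedure to fit furrow/spindle schedules to measured
elongation curves, and a synthetic movie generator with exact ground
truth.

## Constitutive law and discretisation

Cytoplasm is modelled as an isotropic St. Venant–Kirchhoff material,

$$\sigma(\varepsilon) = \frac{E}{1+\nu}\Big(\varepsilon +
  \frac{\nu}{1-2\nu}\,\mathrm{tr}(\varepsilon)\,\mathbf I\Big),$$

with the strain linearised in the displacement within each increment
(the quadratic term of the Green–Lagrange strain is dropped; the
incremental procedure below keeps each step inside the small-strain
regime). Equilibrium $\nabla\cdot\sigma = 0$ is solved by a
displacement-based finite element method on linear (P1) tetrahedra;
loads enter exclusively as prescribed boundary displacements. The
strain energy of a solved increment is the volume sum of
$\tfrac{\lambda}{2}(\mathrm{tr}\,\varepsilon)^2 +
\mu\,\mathrm{tr}(\varepsilon^2)$ over elements; in incompressible mode
(the default whenever $\nu \ge 0.49$) the first, volumetric term is
dropped, as appropriate for $\nu \to 0.5$.

Only the modulus *ratio* matters anywhere in the package: all runs are
displacement-driven, so the absolute Young's modulus defaults to 1 and
results depend on $E$ only through the equatorial-to-polar ratio in
two-region materials and through linear scaling of energies.

**Near-incompressibility.** A displacement formulation is singular at
$\nu = 0.5$; the default is $\nu = 0.499$. Plain P1 tetrahedra lock
volumetrically in this regime. The package ships an optional
averaged-nodal-pressure treatment (`material(stabilize = TRUE)`), which
evaluates the volumetric energy on a node-averaged divergence field and
removes locking; it is exact for uniform-strain states, so the patch
test is unaffected. It is **off by default**: the reference elongation
curves that this package reproduces (shipped under
`inst/extdata/elongation_table.csv`) were themselves computed with
standard linear tetrahedra at a comparable resolution, and the plain
formulation reproduces them closely (final spindle-free elongation
1.313 vs the tabulated 1.300), whereas the locking-free solver relaxes
to a visibly softer response (about 1.19 at the same resolution).
Users interested in the continuum incompressible limit rather than in
reproducing the reference tables should refine the mesh and/or enable
the stabilisation.

## Geometry, meshing and remeshing

All geometry is dimensionless: physical lengths (um) are scaled so the
cell cross-section (diameter) equals 100 model units
(`to_model_units()`); a 400 um egg with an 8 um furrow and a 60 um
spindle maps to (100, 2, 15).

The deforming cell is axisymmetric about the division (z) axis at all
times, and the mesher exploits this: meshes are structured tetrahedral
solids of revolution built from the radial profile $r(z)$ — a stack of
triangulated disks connected by prisms, each prism split into three
tetrahedra with face diagonals through the smallest global vertex index
(which makes the subdivision conforming). The construction is exactly
deterministic; `make_sphere_mesh()` accepts a `seed` argument for
interface stability but ignores it. Axial stations are distributed
uniformly in profile arc length (concentrating them at the poles) and
refined around the furrow band, whose half-width must be resolved for
the band load to be applied at the right width.

Default resolution: `target_edge = radius/10`, with the angular
direction deliberately coarser (`n_theta = 16` in the simulation
driver) because the solution carries no angular variation; radial rings
follow `radius/(1.5 target_edge)`. At these defaults a full
10-increment run uses meshes of roughly 17k–25k tetrahedra and
completes in well under a minute per run; the sphere volume error is
below 1% and decreases monotonically under refinement.

Between increments the deformed boundary is extracted and a fresh mesh
is generated from it (`remesh_from_surface()`), avoiding degenerate
tetrahedra in later increments. The remesher checks that the input
surface is a closed manifold of sphere topology and rejects strongly
non-axisymmetric surfaces. Profile resampling loses a small amount of
enclosed volume to chordal error (~0.4% per remesh at default
resolution), which would accumulate to several percent over a run; the
remesher therefore rescales cross-sectional radii so the new mesh
matches the divergence-theorem volume of the input surface. Under
tight confinement the rebuilt profile is additionally clamped to the
vitelline sphere, since the surface may not penetrate the envelope.

## The incremental cleavage drive

A run consists of `n_steps` (default 10) increments mapped linearly to
dimensionless cleavage time $t_k = k/n$. In increment $k$:

1. the furrow band — surface nodes with $|z| \le FW(t_k)/2$ — is
   re-tagged on the current mesh (the final entry of a printed
   furrow-width schedule that ends one step short reuses the previous
   value);
2. band nodes are prescribed a radial contraction of their cylindrical
   radius by the furrow factor (default 5%, compounding across steps)
   with zero axial motion, which also removes all rigid-body modes;
3. if a spindle schedule is present, the axial line element is extended
   (below);
4. confinement constraints are applied;
5. the elastostatic problem is solved, the polar extent (max z minus
   min z of the deformed boundary) and the furrow (neck) diameter are
   recorded, the increment's strain energy is accumulated, and the
   surface is remeshed.

Elongation curves are reported as $L_n(t) = L(t)/L(0)$ in ratio
convention, 1.000 at $t = 0$.

**Spindle.** The mitotic spindle is driven kinematically: the axis
nodes spanned by the current pole separation are stretched affinely so
that the separation follows the schedule $SL(t_k)$ exactly. A line
element was chosen over a pair of point anchors deliberately: a point
anchor on a P1 mesh sheds its displacement into a local bulb and
transmits little to the poles (fitting a spindle schedule through point
anchors against the packaged small-egg curve drives the spindle to its
60 um bound), whereas the line element — a reasonable idealisation of
a spindle with extended asters — reproduces the packaged
spindle-extended reference curve within 0.025 and fits the final
spindle length to within 1% of the reference value. The drive is
bilateral (it can also retard axial flow when the furrow alone would
move matter faster than the spindle elongates), which keeps the fitted
response strictly monotone in the spindle length and the stepwise fit
well-posed.

**Confinement.** Three modes: `free` (homogeneous Neumann outer
boundary), `tight_sliding` (every non-furrow surface node constrained
to $u\cdot n = 0$ with the vitelline-sphere radial normal — the cell
may slide along the envelope but not leave or penetrate it), and
`contact` (the same constraint applied only to nodes currently at the
envelope radius, a unilateral approximation for loose envelopes that
are reached late in cleavage; surface nodes pushed beyond the envelope
are projected back at remesh time). Sliding constraints are enforced
by a local null-space rotation — the constrained direction is
eliminated per node — so the reduced system stays symmetric positive
definite and the constraint is satisfied to machine precision.

## Sensitivity scan semantics

`sensitivity_scan()` measures the polar elongation produced by a single
initial 10% contraction of the furrow over a grid of furrow widths
(4–20 um on a 400 um cell) and equatorial-to-polar stiffness ratios
($\log_{10} \in [-2, 2]$; the equatorial region is the slab
$|z| \le FW/2$ through the cell depth). Because a single linear
increment scales exactly linearly in the prescribed displacement, a
"10% contraction" read as a radius factor 0.90 would produce exactly
twice the per-increment response of the 10-step runs — which would
place the mid-grid values well above the upper end of the reported
2.5–6.2% range. The two readings are reconcilable only if the scanned
contraction refers to the furrow cross-sectional *area* (radius factor
$\sqrt{0.9}\approx 0.949$); the scan therefore defaults to
`semantics = "area"`, with `"radius"` available. At the default
resolution the scan spans 2.9–4.7%: the lower end agrees with the
reference range, the upper end falls short of the reported 6.2%, and
the stiffness response of the plain P1 solver is non-monotone at
extreme contrast (it peaks near $\log_{10}$ ratio +0.5; the
stabilised solver is monotone over the whole range but spans less).
The twofold-contrast orderings — wider furrow elongates more, stiffer
equator elongates slightly more — hold strictly.

## Confinement energetics

Summing per-increment strain energies (incompressible mode), tight
sliding confinement raises the mechanical cost of cleavage by a factor
of about 3.4 at default resolution, against a reported reference
factor of 4.8. This quantity is dominated by how strictly
incompressibility is enforced in the confined geometry, where the
deformation is squeezed into a boundary layer near the furrow: the
per-increment ratio grows from ~3 early to ~4–5 late in the run, the
summed ratio rises slowly under refinement, and the locking-free
stabilised solver yields substantially larger ratios (4.2–8 depending
on remesh policy). Whether the reference factor sums increments or
compares final configurations is not stated in the source tables; the
package reports the summed ratio and documents the discrepancy rather
than tuning for it.

# The image pipeline

Input is a time series of binary cell masks (optionally with a
parallel vitelline channel). Per frame (`measure_frame()`):

- the polar axis is the major principal axis of the mask's second
  moments; $L$ is the trimmed extent of the pixel projection on that
  axis (the three outermost pixels per side are discarded so that
  boundary-jitter outliers cannot inflate the length);
- $F$ is the furrow width: the width profile along the axis is computed
  as an anti-aliased area profile (each pixel contributes its
  unit-square overlap with 1 px axial slabs — plain point counting
  suffers lattice resonances at grid-aligned axes), and $F$ is the
  interior minimum of that profile within the central half of the
  extent when a genuine neck exists (at least 5% below the central
  region edges), otherwise the width at the centre (the minor axis of
  a pre-furrow cell). A V-flank correction subtracts the known
  smoothing bias of the slab at the profile vertex.
- $V$ is the vitelline-mask extent along the same axis; the V/C ratio
  is $V/L$;
- frames are flagged (`excluded`) when the two half-masses split at the
  neck differ by more than 25%, screening out non-symmetric divisions.

Series of $F(s)$ and $L(s)$ are smoothed by the 5-point masked median
filter (window truncated at the sequence edges; even-sized windows take
the lower median). The cleavage window is delimited on the
sum-of-absolute-derivatives indicator $SAD = |F'| + |L'|$ (central
differences, one-sided at the ends, median-smoothed): the start and
end are the nearest local minima left and right of the absolute
maximum. On real-valued noisy series a literal nearest-local-minimum
stop is dominated by jitter-scale dips, so the minima search descends
the SAD valley with a hysteresis band (35% of the SAD range) and
treats the first sample at the quiescent baseline (lowest quartile
mean plus 10% of the dynamic range) as the edge; the start edge is
advanced one frame to compensate the backward spread of the centred
derivative. Ties at the maximum break to the earliest frame, plateau
minima take the sample nearest the peak, and a flat SAD raises a
"no cleavage detected" error. Dimensionless time
$t = (s - s_s)/(s_e - s_s)$ then maps the window to $[0, 1]$ and
`normalize_curves()` interpolates $L_n$, $F_n$ (and $V_n$) onto a
regular grid of 11 points by default, in ratio convention
($L_n(0) = 1$; the offset convention $L/L(0) - 1$ is available).

Measurement accuracy, quantified against the generator's exact ground
truth: $L$ is within 1 px per frame noise-free and at the default
noise; $F$ is within ~1 px typically but carries an irreducible
pixel-convention ambiguity of up to ±1.5 px on individual frames
(worst at steep neck flanks), and within 2 px at the 95th percentile
under default noise. Window edges are recovered within ±1 frame and
final elongation within 1% — the quantities the downstream analysis
consumes.

# The synthetic generator

`generate_sequence()` renders a dividing cell as the union of two equal
circles whose radius and centre separation are solved in closed form
from the programmed tip-to-tip length and neck width, so the geometric
ground truth is exact; before the cleavage window the cell is a single
circle. Elongation follows an S-shaped profile modelled on the
packaged reference curves (near-linear with a late plateau for large
eggs, front-loaded for small eggs). The vitelline membrane is a
concentric ring with its own dilation schedule; the cell length is
capped at the vitelline diameter (tight confinement). Noise comprises
per-pixel boundary jitter (default SD 0.4 px, chosen so the recovery
invariants pass with margin) and salt-and-pepper flips (rate 5e-4),
removed upstream by a 3x3 binary opening.

`generate_population()` draws per-cell parameters (final elongation,
window length and position, initial V/C ratio, envelope dilation rate)
from log-normal distributions. The two named presets emulate the
statistical structure of the two incubation-temperature experiments:
`"sk18"` (median V/C at cleavage start 1.32, near-static envelope that
the elongating cell reaches in the late phase, V/C approaching 1) and
`"sk26"` (median 1.48, faster dilation, envelope never reached).
Child seeds derive deterministically from the master seed.

What the generator does *not* emulate: real texture and segmentation
artefacts, out-of-plane rotation, asymmetric division, illumination
drift, or shapes beyond the two-circle family (real necks are not
exactly circular-arc). Passing the recovery tests therefore validates
the pipeline's geometry and detection logic, not its robustness to
arbitrary segmentation quality.

# Schedule fitting

`fit_schedule()` reproduces a target elongation curve stepwise: the
deformed state of increment $k-1$ is retained and the free parameter of
increment $k$ (spindle pole separation by default, or the furrow band
width) is searched by bounded golden-section (parameter tolerance
1e-3, at most 50 objective evaluations) to minimise
$|L_n^{sim}(t_k) - L_n^{target}(t_k)|$. Because the constraint
structure within a step is fixed, the factorised stiffness system is
reused across the search — each trial costs a back-substitution. The
response is probed at five points before each search and flagged if not
monotone; targets unreachable within the bounds keep the best boundary
value and are flagged. The default bounds are 0–60 um for the spindle
(its principal upper length limit) and 3–17 um for the furrow width
(the range reported across species). The joint two-parameter fit is
deliberately not offered as a default: furrow width and spindle length
trade off against each other and the joint problem is not identifiable
from a single elongation curve.

# Population statistics

`compare_curves()` compares two groups of curves either pooling all
sampled values (default, two-sided Mann–Whitney) or on a timepoint
subset (e.g. the late phase $t \ge 0.7$), or by a permutation test on
per-curve means with exhaustive enumeration of relabelings when
feasible. The choice of a rank-based test follows standard practice
for small, non-normal samples; no claim is made to reproduce any
specific published p-value. Note that pooling all timepoints of a
curve treats within-cell samples as independent; under the null this
makes the pooled Mann–Whitney anticonservative (measured type-I error
0.26 at nominal 0.05 across 500 null population pairs), while the
permutation variant is exactly calibrated (0.050 measured). Use the
permutation method when a calibrated test on whole curves is needed;
the pooled test remains useful as a sensitive screen and for
timepoint-subset comparisons.

# Problem sizes and tolerances used by the test suite

Module tests run on deliberately small meshes (sphere radius 50,
target edge 10–12, 12 angular sectors — a few thousand tetrahedra) so
the full suite stays fast; the acceptance suite runs the default
resolution (~17k–25k tetrahedra, edge = radius/10). Solver tolerances:
Dirichlet values are imposed exactly (null-space elimination), sliding
constraints hold to machine precision, the sparse Cholesky solve is
direct. Golden-section tolerance 1e-3 on the parameter. Degenerate
inputs (zero furrow width, empty masks, flat SAD, non-manifold
surfaces, inverted elements, unconstrained rigid modes) raise typed
errors with diagnostics rather than propagating silently.

# Known limitations

- The solver is linear within each increment; geometric nonlinearity
  enters only through the incremental update and remeshing.
- Plain P1 elements at $\nu = 0.499$ lock; quantitative results carry
  the discretisation class deliberately (see above). The stabilised
  solver changes headline numbers.
- The remesher is specialised to (approximately) axisymmetric shapes;
  it cannot continue a simulation whose deformation breaks axisymmetry
  (none of the supported load programs do).
- Furrow width measurement on masks has ±1–1.5 px worst-case per-frame
  uncertainty from pixel quantisation.
- Vitelline friction is not modelled; confined-cleavage energies are
  lower bounds in that respect.
- Temperature never enters the constitutive law explicitly; it is
  represented only through its observable correlates (envelope size
  and dilation rate presets).
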