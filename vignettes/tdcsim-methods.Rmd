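---
title: "Models and methods behind tdcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tdcsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tdcsim` simulates the electric field that transcranial direct current
stimulation (tDCS) induces in a volume-conductor head model, and searches for
the bi-hemispheric electrode placement that maximizes that field in a
hand-motor target. This vignette explains the physical model, the numerical
choices, the synthetic-data generator and its limits, and the design decisions
that were genuinely open.

## The volume-conduction model

At tDCS frequencies (DC) the head is a passive resistive medium. With
isotropic, piecewise-constant conductivity $\sigma$, current conservation
reduces Maxwell's equations to the Laplace problem

$$\nabla \cdot (\sigma \nabla V) = 0 \quad \text{in } \Omega,$$

for the induced potential $V$ on the head domain $\Omega$, with insulating
(natural Neumann) boundaries everywhere on the scalp except under the
electrodes, where the injected current enters. The electric field is
$E = -\nabla V$, reported per element in V/m.

Tissue conductivities default to gray matter 0.265, white matter 0.126,
CSF 1.65, skull 0.010, skin 0.465 and stroke lesion 0.8087 S/m, the last
being an average of reference values for chronic brain lesions that
distinguishes lesioned tissue from CSF. Anisotropic white matter is out of
scope: its effect on *cortical* fields is secondary and it would require
tensor data the synthetic geometry cannot supply.

Units are a fixed convention audited by tests: coordinates in mm,
conductivity in S/m, current in mA. The product S/m x mm = mS and mA/mS = V
means the assembled system yields potentials directly in volts; one single
factor of 1000 converts V/mm element gradients to V/m.

## Discretization and solvers

The domain is meshed with linear (P1) tetrahedra and assembled into the
standard stiffness form $K_{ij} = \sigma_e V_e \nabla\phi_i \cdot
\nabla\phi_j$. Row sums of $K$ vanish (checked to 1e-10 relative), and the
single reference element matches the hand-derived 4x4 local matrix.

Electrodes are 5 x 5 cm pads modeled as uniform-current-density Neumann
patches: each boundary facet under the pad carries current proportional to
its area, spread equally over its three nodes, so the total load is exactly
the injected current on the anode and its negative on the cathode. The
complete-electrode model (contact impedance) is deliberately not used: only
pad size and total current are specified inputs, and the uniform-density pad
is the simplest model consistent with them.

The pure-Neumann problem fixes its potential null space in one of two ways:

* **CG** (default for one-off solves): Jacobi-preconditioned conjugate
  gradients on the zero-mean-augmented operator $K + \alpha \tfrac{1}{n}
  \mathbf{1}\mathbf{1}^T$, which avoids privileging an arbitrary pinned node.
  Default relative-residual tolerance 1e-9.
* **Direct** (used automatically for lead-field batches): sparse Cholesky
  (CHOLMOD) of $K$ with one pinned node, solutions demeaned afterwards.
  With dozens of load vectors per subject, one factorization plus cheap
  triangular solves is far faster than repeated CG, and both routes agree to
  solver tolerance (tested).

## The analytic oracle

Correctness of the FEM pipeline is checked against the classical
Legendre-series solution for concentric spherical shells. For a point source
of current $I$ on the outer surface, each harmonic in shell $j$ is
$A_j (r/r_j)^l + B_j (r_{j+1}/r)^{l+1}$ (the per-shell scaling keeps the
interface system well conditioned to high order); coefficients follow from
potential and radial-current continuity, regularity at the centre, and the
surface source condition. Because the FEM electrodes are finite pads, the
oracle can damp each harmonic by an equal-area spherical-cap factor, which is
the physically matched comparison; the point-source limit is recovered as the
cap shrinks. The series itself is validated against the closed-form
homogeneous-sphere solution (agreement ~1e-15).

On a 50 mm three-layer sphere (skin/skull/brain-like contrasts) with small
antipodal pads, FEM surface potentials at 4 mm mesh size agree with the
series to ~0.1–0.4% relative L2 (evaluated ≥25 mm from the pads, where the
pad-shape quadrupole terms are negligible), and the error decreases under
refinement. The 50 mm radius at 4 mm resolution (~150k tetrahedra) keeps this
oracle cheap while exercising every assembly and boundary-condition path.

## Synthetic head and cohort generator

No individual MRI data ship with the package, so the generator produces
layered-sphere heads: five concentric shells (skin/skull/CSF/gray/white) with
default outer radii 92/86/80/78/70 mm — round adult-head-scale values. The
mesh stacks geodesic (subdivided icosahedral) sphere surfaces at every tissue
interface plus intermediate radii, splits the resulting prisms consistently,
and closes the core with a vertex fan; every interface is an exact mesh
surface, elements are labeled by centroid shell membership, and total volume
converges to the analytic ball volume. Coordinates are RAS mm with the origin
at the sphere centre.

Fiducials sit at the axis poles (nasion +y, inion -y, preauriculars ±x), and
10–20 positions follow the arc construction: Cz at the vertex, C3/C4 at 20%
of the ear-to-ear arc from Cz. The hand-knob target is placed at mid-gray
depth beneath C3/C4 on the affected side and snapped to the centroid of the
nearest gray element — the snap rule guarantees the ROI sphere (paper-scale
default 2 mm) always contains at least one gray element, even on coarse
meshes where 2 mm is below the element size (at the default study resolution
the ROI typically holds a single element, so its "mean" is that element's
field).

Stroke lesions are spheres that only relabel elements (topology and total
volume conserved exactly): cortical lesions centred at 0.9 x the gray outer
radius on the affected side with radii 6–10 mm (straddling the cortex while
staying out of the skull), subcortical at 0.5 x confined to white matter
(radii 5–12 mm), brainstem near the inferior pole (4–8 mm). The default
cohort reproduces the 8/11/2 cortical/subcortical/brainstem split of 21
subjects. Initial FMA-UE scores follow
`clip(round(40 - 1.2 * volume^(1/3) - 10 * 1[cortical] + N(0, 5)), 0, 66)`,
chosen so the cohort median lands near 21 with a negative
lesion-severity association — enough structure for the correlation analyses
to exercise, with no claim of clinical realism. Each subject draws from a
deterministic per-subject seed (`master * 1009 + i`), so cohorts are
bit-reproducible.

What the generator does **not** emulate: gyral folding, CSF-filled lesion
cavities, ventricles, skull inhomogeneity, real lesion shapes, or any
patient-specific anatomy. Consequently the cohort-level *magnitudes*
(displacement medians, correlation strength) are emergent properties of
spheres, not predictions; only directions and invariants (optimized ≥
conventional, paired-test significance, negative severity association) are
meaningful, and that is what the tests assert.

## Montage optimization

Candidate electrodes form an evenly spaced square lattice (11.11 mm spacing)
in the tangent plane at each conventional position, projected onto the scalp
along rays from the head centre, with default extent ±44.44 mm (a 9 x 9
grid); the conventional centres are always included, so the optimum can never
fall below the conventional montage (superset dominance, asserted per
subject). Candidate pairs whose centres are closer than 70 mm are excluded to
prevent pad contact.

A naive search solves one FEM problem per pair (O(n²)). Instead the package
computes one **lead field** per candidate against a fixed reference patch at
the inion; by linearity the potential of any (anode, cathode) pair is the
difference of their lead potentials, restricted to the ROI through a sparse
gradient operator. This reduces n² solves to n with *exact* pair scores
(two-path agreement tested to 1e-6 and observed at ~1e-15). The search is
exhaustive over the current grids, then both grids re-centre on the incumbent
best and repeat (default up to 10 rounds, stopping when relative improvement
drops below 1e-4 or the best pair sits at the grid centres). Ties within
1e-9 relative resolve toward the pair nearest the conventional montage, then
lowest index — the search is fully deterministic.

The objective is the volume-weighted mean field magnitude over gray elements
in the ROI, matching the headline comparison metric; the cortical normal
component (projection onto the outward gray-surface normal at the nearest
gray/CSF interface point) is reported alongside but not optimized.

## Statistics

The group battery wraps base R's rank tests behind a uniform report surface:
paired Wilcoxon (exact null for ≤25 untied differences, tie-corrected normal
otherwise), Mann–Whitney (exact for small untied groups), Spearman's rho with
an exact permutation p for n ≤ 9 without ties and the t approximation above,
and a Kolmogorov–Smirnov normality screen against the fitted normal (whose
p-value is anti-conservative because the parameters are estimated — the
Lilliefors caveat — so it is used descriptively only). The Spearman 95% CI
uses the Fisher z transform with SE $1/\sqrt{n-3}$; quartiles use linear
interpolation. Every exact routine is tested against brute-force enumeration
oracles. No multiple-testing correction is applied across the battery, and
the report says so.

## Problem sizes and reproducibility

Default study conditions: mesh size 9 mm (~82k tetrahedra, ~15k nodes per
head), 21 subjects, 9 x 9 candidate grids per electrode with re-centering,
2 mA, 5 x 5 cm pads, 2 mm ROI. A full study runs in a few minutes on one
CPU; the FEM-vs-analytic oracle at 4 mm resolution adds about a minute. All
randomness flows from one master seed; identical configurations produce
byte-identical output tables, stamped with the seed and a config hash.

## Known limitations

* Spherical anatomy: no folding, no realistic lesion geometry; cohort-level
  effect sizes are not comparable to patient data.
* Uniform-current pad model: no contact impedance or sponge/gel layer.
* Isotropic conductivities; lesion conductivity is a single literature
  average and is configurable precisely because it is uncertain.
* ROI means at coarse resolution rest on few (often one) elements; refine
  the mesh or widen the ROI for smoother summaries.
* The optimizer searches electrode position only — not rotation, size,
  current, or multi-electrode layouts.
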