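---
title: "Boundary-constrained non-rigid registration and statistical shape models of branched vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-constrained non-rigid registration and statistical shape models of branched vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselssm)
```

## The problem

A statistical shape model (SSM) of an anatomical surface needs every shape
in the cohort expressed with the same vertices in the same anatomical
order — the correspondence problem.  For branched vessels such as the
thoracic aorta with its three supra-aortic branches, correspondence is hard
precisely where it matters: the branches are thin, variable in position and
orientation, and easily matched to the wrong partner by purely
surface-distance-driven methods.  `vesselssm` implements a registration
algorithm that deforms a template mesh onto each cohort member by gradient
descent on a Chamfer objective, with two ingredients that make branched
anatomy tractable:

1. **open boundaries as landmarks** — each clipped vessel end is a labeled
   boundary loop, and a weighted Chamfer term per label pulls every source
   opening onto the *same-label* target opening; and
2. **Laplacian-preconditioned steps** — the raw gradient is diffused over
   the mesh by `(I + γL)⁻¹` before stepping, which keeps the deformation
   smooth without adding a penalty to the objective itself.

The registered, Procrustes-aligned cohort then feeds a linear (PCA) shape
model evaluated by generalisation, specificity and compactness.

## Objective and optimizer

For source vertex set $V_s$ and target $V_t$ the surface term is the
symmetric Chamfer distance (mean squared nearest-neighbour distance, mm²),
computed between point clouds, not between continuous surfaces.  With
labeled boundary loops $B^j$ the full objective is

$$\phi = d_{CD}(V_s, V_t) \;+\; \sum_j \alpha_j\, d_{CD}(B_s^j, B_t^j),$$

with every $\alpha_j = 0.1$ by default.  Because each boundary term is
normalised by its own (small) vertex count, a single weight of 0.1 balances
loop terms against the surface term over a wide range of mesh resolutions;
setting $\alpha = 0$ recovers a purely geometric registration, and the
branch-crossover test in the suite shows exactly what that loses.

Nearest-neighbour assignments are recomputed every iteration and treated as
constants when differentiating, so the gradient of each squared distance is
linear in the coordinates.  The update is

$$x \leftarrow x - \eta\, A\!\left((I + \gamma L)^{-1} \nabla\phi\right),$$

where $L$ is the combinatorial (unit-weight) graph Laplacian of the source
mesh and $A(\cdot)$ is a *uniform-Adam* momentum step: standard first/second
moment accumulators with bias correction, except that the second-moment
normaliser is a single scalar — the maximum of the bias-corrected second
moment over all entries.  A per-entry normaliser (plain Adam) would rescale
each vertex independently and undo the smoothing that the preconditioner
just applied; the uniform normaliser only rescales the whole step, keeping
the direction field intact.  Defaults are $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\varepsilon = 10^{-8}$.

**Composition order.**  We smooth the raw gradient first and let the
momentum normaliser act on the preconditioned direction.  With a spatially
uniform normaliser the two orders produce *parallel* directions — the
accumulators are linear in their input up to the scalar denominator — so
the choice only sets the effective step length.  Normalising after
preconditioning makes the step length $\eta$ mean "millimetres of maximum
vertex motion per iteration", independent of how strongly $\gamma$ smooths;
normalising before would shrink the step by the (resolution-dependent)
smoothing factor and make $\eta$ impossible to interpret across scales.

`(I + γL)` is symmetric positive definite for $\gamma \ge 0$; it is
factorised once per scale with a sparse Cholesky decomposition and reused
for all iterations (topology is constant within a scale).  The
$\gamma = 0$, momentum-off limit reproduces textbook gradient descent to
machine precision, which the test suite asserts at $10^{-12}$.

A deliberate consequence of the uniform normaliser is scale invariance:
even a tiny residual gradient is normalised to a unit-magnitude direction,
so the optimizer never "settles" — it oscillates at amplitude $\sim\eta$
around the optimum.  Iteration counts are therefore fixed per scale
(no early stopping), and $\eta$ at the finest scale should sit below the
mesh resolution.

## Multi-scale schedule

Registration runs coarse-to-fine over $n$ scales.  Source and target are
decimated to each scale's vertex budget by uniform Lloyd vertex clustering
(systematically seeded, fixed iteration count, hence deterministic); the
coarsest pair is registered; the coarse displacement is interpolated by a
radial basis field (polyharmonic kernel $r$ with an appended linear
polynomial — exact on affine, hence rigid, displacements) and applied to
the next finer source; and so on to native resolution.  $\gamma$ decreases
towards fine scales: coarse scales should move large-scale features
smoothly, fine scales recover detail.

The reference schedule for ~20,000-vertex aortic surfaces is three scales
of 4,000 / 18,000 / 20,000 points with $N$ = 700 / 1,000 / 1,500 iterations,
$\gamma$ = 120 / 80 / 50 and $\eta$ = 0.007 / 0.01 / 0.02
(`aorta_scale_schedule()`).  The package's tests and the acceptance study
use reduced schedules on 1,000–2,200-vertex synthetic meshes (coarse scales
of 500–1,500 points, 120–300 iterations per scale), chosen so that each
registration finishes in seconds while still exercising every stage; at
these sizes the final root-Chamfer distance sits well below the mesh edge
length, which is the resolution-limited optimum.

Boundary labels do not survive decimation (vertex indices change), so each
coarse mesh's loops are re-labeled by greedy nearest-centroid matching
against the native labeled loops, and the boundary terms are evaluated at
*all* scales.  If a decimated mesh's loop count differs from the native one
(very aggressive decimation can open or close a hole), label recovery fails
and that scale runs with $\alpha = 0$; the fallback is recorded in the
result and warned about.  Decimation ratios above roughly 40 % of the
native count preserved all five loops in every fixture we generate.

## From registered meshes to a shape model

Registered shapes are packed as $3k$-vectors $(x_1, y_1, z_1, \dots)$ and
aligned by generalized Procrustes analysis: each shape is rigidly aligned
(rotation + translation, *no scaling* — overall size is anatomical signal,
not nuisance) to the evolving mean until the mean moves less than 0.001 mm.
The template itself is refined iteratively: the Procrustes mean becomes the
new template, registration repeats, and the loop stops when the template
moves less than 0.1 mm (default cap: 5 outer iterations).

PCA uses the $1/(M-1)$ covariance convention and keeps
$m = \min(M-1, 3k)$ modes, computed through the $M \times M$ Gram matrix
(dual PCA) since $3k \gg M$ — mathematically identical to the direct
eigendecomposition.  Two reproducibility conventions: each eigenvector's
sign is fixed so its largest-magnitude entry is positive, and eigenvalues
below $10^{-12} \lambda_1$ are treated as exact zeros (their eigenvectors
are numerical noise and are zeroed too, so projections onto dead modes
return exactly 0).

## Intrinsic evaluation

* **Generalisation** $G(K)$ (mm²): leave-one-out.  For each held-out shape
  the remaining $M-1$ shapes are re-aligned by GPA, a reduced model is
  fitted, the held-out shape is rigidly aligned to the reduced mean
  (the paper-level procedure does not say how the excluded shape enters
  the reduced frame; rigid alignment without scaling is the choice
  consistent with the rest of the pipeline), projected on $K$ modes and
  reconstructed.  $\epsilon_i(K)$ is the **mean** per-vertex Euclidean
  distance — the per-vertex aggregation is our documented choice, recorded
  in the report metadata — and $G(K) = \tfrac1M \sum_i \epsilon_i^2(K)$.
* **Specificity** $S(K)$ (mm): $H$ samples with
  $\omega_i \sim \mathcal N(0, \lambda_i)$, each compared to its nearest
  training shape by mean per-vertex distance; $S$ is the average over
  samples.  $H$ defaults to 1,000 and the seed is mandatory, so the value
  is exactly reproducible.
* **Compactness** $C(K)$: cumulative explained-variance fraction.

All three accept a vertex mask for regional evaluation (e.g. the branches
alone).  For masked compactness the mode variances are weighted by the
energy each mode carries on the masked coordinates, which is the exact
decomposition of the restricted covariance trace.  An independent
straight-line reimplementation of all three metrics (plain loops, no shared
code) is kept in the test helpers and must agree to $10^{-10}$ on a
five-shape toy set.

## The synthetic cohort

No patient data ship with the package.  The generator builds an idealised
thoracic-aorta-like tree: an analytic centerline (vertical ascending
segment, semicircular arch with a smooth out-of-plane excursion, vertical
descending segment), swept with parallel-transport frames into a structured
tube mesh; three branch stubs extruded from rectangular patches opened in
the arch; five labeled open boundaries; a per-vertex longitudinal
coordinate (arc length, continued into branches); and optional smooth
radial noise (relaxed white noise, seeded).  Default dimensions are
realistic for an adult aorta: 12 mm root radius with 15 % taper, 30 mm arch
radius, 60/150 mm straight segments, 4–4.5 mm branch radii.  Populations
are generated by perturbing scalar parameters along "planted modes" with
Gaussian coefficients on a frozen discretisation layout, so all members are
isotopological; `plant_shape_modes()` instead plants exactly orthonormal
deformation fields in shape space, giving a ground truth against which PCA
recovery is checked quantitatively (variances within 25 %, principal angles
below 5° at $M = 60$).

What the generator does *not* emulate: CT segmentation artifacts,
non-circular lumen cross-sections, branch ostium geometry beyond a blended
junction, wall thickness, or pathology other than a radial aneurysm bump.
Passing tests therefore demonstrate the correctness and internal
consistency of the algorithms, not clinical-grade performance on real
segmentations.

Homogenisation utilities mirror the preprocessing a real cohort needs:
area-proportional vertex budgets (`scaled_vertex_count()`, so equal average
edge length across a cohort), longitudinal clipping of each vessel at
$\tilde L = C + L$ with exact re-triangulation of the cut (140 mm for the
descending aorta and 18 mm for the branches are the conventional retained
lengths), and per-vessel length standardisation against the raw cohort.
Centerlines are analytic here; computing centerlines for arbitrary real
meshes is out of scope, and ICP pre-alignment is offered on surface
vertices (flagged in the documentation) where no centerline exists.

## Numerical choices and degenerate inputs

* STL vertex welding tolerance: $10^{-8}$ mm (STL stores no shared
  vertices).
* Isolated vertices are kept with a zero Laplacian row plus a warning,
  never silently dropped.
* The RBF system is solved in centred, unit-scale coordinates with one step
  of iterative refinement, and field evaluation uses direct coordinate
  differences rather than the expanded inner-product formula (which cancels
  catastrophically near control points); control-point reproduction is
  $\le 10^{-8}$ mm.  Above 5,000 control points the fit subsamples
  systematically.
* Cluster decimation is deterministic but, like any clustering, sensitive
  to coordinate perturbations at the tie-breaking level; the pipeline
  therefore skips numerically-identity ICP transforms so that identical
  inputs follow bit-identical paths.
* Ties in nearest-neighbour queries resolve to the lowest index in both
  the compiled grid search and the R reference scan.
* A dataset with zero total variance defines $C(K) = 1$ for all $K$;
  specificity sampling with all variances zero returns the distance of the
  mean to the training set.
* All randomness (noise fields, population coefficients, specificity
  draws) flows through explicit integer seeds; registration itself is
  deterministic.

## Known limitations

* The branch-junction blend is parametric, not an implicit-surface union;
  extremely large branch radii relative to the main tube would produce
  visible creases at the patch boundary.
* Trees below ~600 vertices cannot host three separated branch patches and
  are rejected by the layout planner.
* The optimizer's scale-invariant step means the loss plateaus at an
  $\eta$-dependent floor rather than converging to machine zero; choose
  the finest-scale $\eta$ below the target accuracy.
* Very aggressive decimation (below ~40 % of native resolution on our
  fixtures) can change surface topology; the multi-scale driver degrades
  gracefully (unconstrained scale + warning) but the coarse registration
  quality suffers.
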