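# vesselssm

Non-rigid registration and statistical shape modelling of branched vessel
surfaces — triangle meshes of the thoracic aorta and its supra-aortic
branches, or any vessel-like anatomy whose clipped open ends can serve as
landmarks.

Building a statistical shape model (SSM) requires every cohort member to be
expressed with the same vertices in corresponding anatomical positions.
For branched vessels that correspondence is the hard part: the branches are
thin, close together and highly variable, and purely distance-driven
registration happily maps a branch onto its neighbour.  `vesselssm`
registers a template mesh onto each target by minimising

    φ(S, T) = d_CD(V_s, V_t) + Σ_j α_j · d_CD(B_s^j, B_t^j)

where `d_CD` is the symmetric Chamfer distance (mean squared
nearest-neighbour distance between vertex sets, mm²) and the `B^j` are
labeled open-boundary loops (`root`, `descending`, `SA1`–`SA3`) acting as
anatomical landmarks with weight `α = 0.1`.  Minimisation uses
Laplacian-preconditioned momentum descent,

    x ← x − η · UniformAdam( (I + γL)⁻¹ ∂φ/∂x ),

where `L` is the mesh's combinatorial graph Laplacian: the inverse diffuses
the gradient across the surface, so deformations stay smooth without a
penalty term in the objective.  Registration runs coarse-to-fine over a
multi-scale schedule, transferring each scale's displacement to the next by
a thin-plate-type RBF field.  Registered shapes are aligned by generalized
Procrustes analysis (rotation + translation only — size is anatomy, not
nuisance), modelled by PCA (`s = s̄ + Σ ω_i φ_i`), and evaluated by the
standard intrinsic metrics: generalisation (leave-one-out reconstruction
error, mm²), specificity (realism of sampled shapes, mm) and compactness
(cumulative explained variance).

A synthetic generator of aorta-like branched-tube meshes — analytic
centerline, five labeled openings, planted population variation — makes the
whole pipeline runnable and testable without any patient data.

## Worked example

```r
library(vesselssm)

# two synthetic aorta-like trees with the same connectivity
src <- generate_vessel_tree(vessel_tree_params(n_vertices = 2200, seed = 3))
tgt <- generate_vessel_tree(
  vessel_tree_params(n_vertices = 2200, seed = 4, radius = 13,
                     arch_radius = 33, out_of_plane = 10),
  layout = src$layout)

cfg <- registration_config(scales = list(
  list(point_count = 900,  iterations = 250, gamma = 120, learning_rate = 0.05),
  list(point_count = 1500, iterations = 250, gamma = 80,  learning_rate = 0.03),
  list(point_count = 5000, iterations = 300, gamma = 50,  learning_rate = 0.02)))

res <- multiscale_register(src$mesh, tgt$mesh, cfg)
res
#> <registration_result> 800 iterations over 3 scale(s)
#>   final sqrt(Chamfer) 3.09 mm, Hausdorff 4.253 mm
mean_edge_length(tgt$mesh)
#> [1] 3.75558
```

The final root-Chamfer distance (3.09 mm) is below the target's average
edge length (3.76 mm) — the resolution-limited optimum for a point-cloud
metric — and every boundary loop ends on its same-label counterpart.
`autoplot(res)` shows the loss trace with the characteristic drop after
each scale transition.  Fitting and inspecting a shape model:

```r
pop   <- plant_shape_modes(src$mesh, variances = c(9, 4, 1), M = 60, seed = 7)
model <- fit_pca(shape_dataset(pop$shapes, src$mesh$faces))
head(tidy(model), 4)
#> # A tibble: 4 × 5
#>    mode variance_mm2 sd_mm variance_fraction cumulative_fraction
#>   <int>        <dbl> <dbl>             <dbl>               <dbl>
#> 1     1        8.79  2.96             0.686                0.686
#> 2     2        3.22  1.79             0.251                0.937
#> 3     3        0.811 0.900            0.0632               1
#> 4     4        0     0                0                    1
glance(model)$modes_90pct
#> [1] 2
```

The three planted variances (9, 4, 1 mm²) are recovered as the three
leading eigenvalues; all remaining modes are numerically zero.
`generate_shape(model, c(3 * sqrt(model$variances[1])))` produces the
classic "+3 SD" extreme shape of mode 1, and `evaluate_ssm()` returns the
generalisation/specificity/compactness table for a grid of mode counts.

For shell use, `inst/cli/vesselssm.R` wraps the same functions as
subcommands (`synth`, `distances`, `register`, `gpa`, `fit-ssm`,
`evaluate`, `run`).

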