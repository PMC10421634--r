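# ethokit

Unsupervised behavioral decomposition from markerless 3D pose tracking.

`ethokit` turns multi-session recordings of an animal's 3D landmarks (15
landmarks at 30 Hz by default) into a layered, quantitative description of
its behavior:

- **Postures** — recurring body configurations. Frames are QC'd,
  gap-interpolated and similarity-normalized (neck at the origin, unit
  spine, common facing direction); 23 features per frame (19 joint angles +
  4 speeds) are min–max normalized per subject and group, reduced by PCA to
  95% variance, embedded in 2-D from the fuzzy kNN graph
  (`min_dist = 0.001`, `n_neighbors = 20`), and segmented by a watershed of
  the kernel density on a 200 × 200 grid.
- **Behavioral modules** — actions, as communities of the posture
  transition graph. The lag-T transition matrix
  `M[i, j] = P(S(t+T) = i | S(t) = j)` over posture *runs* is clustered with
  the Paris algorithm; the module partition is the dendrogram cut
  maximizing directed Newman modularity
  `Q = (1/m) Σ_ij (A_ij − k_i^out k_j^in / m) δ(c_i, c_j)`.
- **Hierarchy** — the Paris dendrogram itself, scored by the normalized
  Dasgupta quality; partitions are compared with adjusted mutual
  information (AMI).
- **Timescales** — modularity and stability curves over transition lags,
  fitted with `M = a·e^{bT} + c`; the half-life `H = −log(2)/b` measures
  how far into the future behavioral organization persists.
- **Statistics** — 100× label-shuffle nulls (add-one permutation p-values),
  two-way ANOVAs across subject and task, pairwise-session AMI matrices
  with permutation p-values and BH correction, and partialled t-tests.

Sessions recorded on different days are aligned before embedding by mutual
nearest neighbors (K = 100) with distance-weighted correction vectors,
smoothed by a 15th-order running median (`X2′ = X2 − C`).

A synthetic pose generator (`behavior_repertoire()`, `render_poses()`,
`make_demo()`) plants known postures, modules, hierarchy, dwell times,
batch offsets and tracking failures, so the whole pipeline is validated
against ground truth without any animal data.

## Worked example

```r
library(ethokit)

# simulate a small 2-subject x 3-task study with planted structure
dir <- tempfile()
manifest <- make_demo(dir, seed = 1, n_frames = 2500,
                      repertoire = behavior_repertoire(n_postures = 6,
                                                       n_modules = 2,
                                                       seed = 5))

# run the full pipeline: preprocess -> align -> embed -> cluster -> stats
res <- run_pipeline(manifest, out_dir = file.path(dir, "run"),
                    config = run_config(K = 40, n_neighbors = 15,
                                        n_epochs = 100, lags = c(1, 2, 3, 5, 8),
                                        n_permutations = 10, seed = 9))
res$stats$sessions
```

The session table printed by the example (seeds as above) is:

```
              session subject          task n_postures n_modules modularity
1           subj1_OFF   subj1           OFF          8         2      0.342
2 subj1_ON_controlled   subj1 ON_controlled          8         2      0.362
3     subj1_ON_random   subj1     ON_random          8         2      0.392
4           subj2_OFF   subj2           OFF          8         2      0.383
5 subj2_ON_controlled   subj2 ON_controlled          8         2      0.392
6     subj2_ON_random   subj2     ON_random          8         2      0.384
  dasgupta modularity_p mean_dwell_s half_life
1    0.539       0.0909        0.419      1.33
2    0.546       0.0909        0.356      1.67
3    0.558       0.0909        0.451      5.01
4    0.559       0.0909        0.463      2.12
5    0.561       0.0909        0.401      1.95
6    0.557       0.0909        0.420      1.84
```

Reading it: the embedding/watershed stage recovered 8 posture basins per
session for the 6 planted templates (transition blends contribute a couple
of small extra basins at this short session length); the
modularity-maximizing cut finds the 2 planted modules in every session,
with Q ≈ 0.38 and a modularity p-value at the floor of the 10-permutation
null (1/11 ≈ 0.0909); mean posture dwell is ≈ 0.42 s against the planted
0.6 s mean (short sessions over-segment runs slightly), and the modularity
half-life is short, as it should be for a chain with only two modules and
10% cross-module mass. The run directory contains per-frame posture labels,
per-session transition matrices (CSV), dendrograms (Newick), module tables,
metric curves, a JSON report and a manifest with the full config and seed.

Individual stages are ordinary functions returning tibbles or light S3
objects with `tidy()`, `glance()` and `autoplot()` methods:
`read_pose_table()`, `qc_filter()`, `interpolate_gaps()`,
`normalize_pose()`, `compute_features()`, `normalize_features()`,
`pca_reduce()`, `umap_embed()`, `density_map()`, `watershed_postures()`,
`compress_runs()`, `transition_matrix()`, `lag_sweep()`,
`paris_dendrogram()`, `best_cut()`, `modularity_score()`,
`dasgupta_score()`, `ami()`, `metric_curve()`, `fit_half_life()`,
`shuffle_null()`, `compare_sessions()`, `mutual_nearest_neighbors()`,
`correction_vectors()`, `apply_alignment()`.

See the vignette (`vignettes/behavioral-decomposition.Rmd`) for the models,
parameter meanings, design decisions and limitations.

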