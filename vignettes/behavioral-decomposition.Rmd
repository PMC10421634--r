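---
title: "Unsupervised behavioral decomposition from 3D pose: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised behavioral decomposition from 3D pose: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ethokit)
```

## The problem

Markerless 3D tracking can record every landmark of a freely moving animal at
video rate for hours, but the resulting coordinate streams are not yet
*behavior*. ethokit implements an unsupervised decomposition of such
recordings into a layered description:

1. **Postures** — recurring body configurations, found as basins of a
   watershed segmentation of the density of pose features embedded in 2-D;
2. **Behavioral modules** — sets of postures that preferentially transition
   into one another, found as modularity-maximizing communities of the
   posture transition graph; roughly "actions" (walking, climbing, sitting);
3. **A behavioral hierarchy** — a dendrogram over postures from Paris graph
   clustering, scored by the Dasgupta quality;
4. **Timescales** — how far into the future this organization persists,
   measured as the half-life of exponential fits to modularity and module
   stability as functions of transition lag.

The package is organized so every stage is usable on its own, and ships a
synthetic pose generator with planted ground truth so each stage — and the
whole pipeline — is testable without any animal data.

## Preprocessing model

Pose tables carry one frame per row (`frame`, `time_s`, `<landmark>_{x,y,z}`
in meters) for a 15-landmark skeleton at 30 Hz. Three steps produce
normalized postural orientations:

* **QC.** A frame is discarded if any landmark leaves the arena (default box
  2.45 x 2.45 x 2.75 m) or if the mean bone length falls below 10 cm — the
  signature of a collapsed reconstruction. Both thresholds are parameters of
  `qc_filter()`.
* **Gap interpolation.** Missing runs of at most 10 frames (0.33 s) are
  filled per coordinate by *shape-preserving* (monotone Hermite) piecewise
  cubics, using up to four valid frames on each side. We chose the monotone
  variant over a natural cubic spline to avoid overshoot on short gaps; on
  locally linear motion the two coincide, and our tests pin the linear case
  exactly. Boundary gaps have no bracketing data and are never filled.
* **Similarity normalization.** Each frame is translated so the neck sits at
  the origin, scaled so the neck-hip spine has length 1, and rotated by the
  proper rotation that maps the spine to −Z and the spine-orthogonalized
  left-to-right shoulder axis to +X. Only "translate, scale to unit spine,
  face a common direction" is dictated by the problem; the particular axis
  convention is ours and is stated here because any reimplementation needs
  one to be reproducible. The map is invariant under rigid motion plus
  positive uniform scaling (tested with random similarity transforms) and
  degenerate frames (zero spine, shoulders parallel to the spine) are
  invalidated rather than guessed.

The order QC → interpolation → normalization means interpolation also
repairs frames that QC invalidated, when their neighbors are sound.

## Feature engineering

Per frame we compute 23 features: the 19 vertex angles of the skeleton's
joint triplets (on normalized coordinates; angles are similarity-invariant)
and four speeds — the center-of-mass speed and the per-axis |X|, |Y|, |Z|
speeds. Speeds are computed from the *raw* arena-frame coordinates, because
normalization removes exactly the translation that speed measures; the
centroid is smoothed by a 5-frame centered running mean and differentiated
centrally. Features are min-max normalized to [0, 1] per feature *group*
(angles | COM speed | axis speeds) and per subject, so no group dominates
the embedding by scale and between-subject limb differences do not create
spurious subject clusters. PCA then retains the smallest leading component
set reaching 95% cumulative variance.

## Batch alignment

Sessions recorded on different days carry small systematic measurement
offsets. Before embedding, each session's feature matrix is aligned to a
reference session (the largest) by mutual nearest neighbors: two K = 100
euclidean kNN searches define mutual pairs; each sample's correction vector
is a weighted mean of its differences to its mutual matches; a 15th-order
running median smooths the corrections over time, empty entries are filled
by temporal interpolation, and the smoothed matrix is subtracted.

Two details are deliberate choices. The weighting of matches "by distance"
is implemented as a Gaussian kernel with sigma equal to the median mutual
pair distance, with `inverse` and literal `proportional` weighting available
as switches; exact matches (zero distance) absorb all weight, which is the
continuity limit of inverse weighting and makes self-alignment an exact
no-op. And alignment operates on the 23 normalized features rather than raw
coordinates, since it immediately precedes embedding.

A caveat worth stating: nearest-neighbor matching recovers a batch offset
only when the data are *clustered* (matches then pair corresponding
postures); on a featureless cloud the local differences average to zero.
Even in the clustered regime the estimate carries a small shrinkage bias of
the order of the within-cluster spread, because matches are preferentially
selected on the near side of each cluster. Our validation therefore probes
the regime the method is meant for: tight posture clusters (1% observation
noise per normalized feature) under an offset of norm 0.5.

## Embedding, density and postures

The PCA scores are embedded in 2-D from their fuzzy k-nearest-neighbor
graph: exact euclidean kNN (`n_neighbors = 20`), per-point bandwidth
calibration so each point's membership weights sum to log2(k), fuzzy-union
symmetrization, and a stochastic gradient layout whose attraction curve is
fitted from `min_dist = 0.001` and `spread = 1`, with uniform negative
sampling (rate 5, 200 epochs, PCA initialization scaled to max 10). The
layout RNG is an internal xorshift stream, so results are bit-reproducible
from the seed alone, single-threaded.

Posture segmentation estimates a Gaussian kernel density on a 200 x 200
grid spanning the embedding (bandwidths by a Silverman-type normal
reference rule, exposed as a parameter; the density is renormalized to
integrate to 1), then applies the watershed transform so each density peak
seeds a basin. Two merge rules clean the basin map: basins whose peak rises
less than 1% of the global maximum above their saddle are merged into the
deeper neighbor (low-persistence filaments — continuous trajectories
between postures trace thin ridges of density that are not postures), and
basins with near-zero peak density or no assigned points are absorbed
likewise. Every frame then takes the basin of its grid cell, with
background cells resolved to the nearest basin, so label totality holds.
Basin assignment is invariant to rescaling the embedding, since grid and
bandwidths scale with the data.

## Transition graphs, modules, hierarchy

Posture labels are compressed to maximal runs; dwell times are reported in
seconds. The lag-T transition matrix `M[i, j] = P(S(t+T) = i | S(t) = j)`
is estimated over *runs* (so lag counts posture changes, not frames);
at T = 1 the diagonal is structurally zero, at higher lags self-returns are
real and kept. Sessions never contribute cross-boundary transitions.

The transition graph is clustered with the Paris algorithm: agglomerative
merging by the node-pair sampling distance d(a, b) = p(a) p(b) / p(a, b) on
the symmetrized weights (the distance is reducible, so merge heights are
monotone and greedy merging is exact). Modularity of a module partition is
evaluated on the *directed* matrix in the Newman out/in-strength form —
the transition graph is directed, and the trivial one-module partition
scores exactly 0 — with a symmetrized switch for sensitivity checks. The
reported module assignment is the dendrogram cut maximizing Q over 51
equally spaced heights in [0.4, 1.4]; the merge heights inside the window
are also evaluated (the partition only changes at merges, so this costs
nothing and avoids grid aliasing), the window auto-extends with a warning
when a dendrogram's height span lies outside it, and ties prefer the
coarser partition. Hierarchy quality is the Dasgupta score
1 − cost/(n · total weight), and partitions are compared by adjusted
mutual information under the permutation-model expectation; all three have
brute-force oracle tests on small graphs.

## Timescales and statistics

Modularity and stability (AMI between best cuts at consecutive lags) are
traced over a lag list and fitted with M = a·e^{bT} + c by bounded
nonlinear least squares (trust-region Levenberg-Marquardt, b constrained to
[−10, −1e−6], initialized from a log-linear regression), giving the
half-life H = −log(2)/b and an adjusted R². Flat curves are flagged
degenerate, with H reported missing rather than infinite.

Significance of modular and hierarchical structure uses a label-shuffle
null: permute the run-level posture labels, rebuild the graph, recluster,
recompute; 100 shuffles by default, with the add-one permutation p-value
(1 + #{null ≥ obs})/(1 + n), which cannot report p = 0. We shuffle runs
rather than frames because the statistic is computed on runs: frame-level
shuffling would additionally destroy dwell structure the statistic never
sees (a frame-level switch exists). Cross-session comparisons offer the
two-way type-II ANOVA on the crossed subject and task factors (no
interaction), pairwise-session module AMI with per-pair label-permutation
p-values and Benjamini-Hochberg correction, and unpaired t-tests on
group-mean-subtracted ("partialled") AMIs for the within- vs between-
subject and task-pair contrasts. Sessions are treated as independent units;
a mixed-effects treatment is out of scope.

## The synthetic generator

`behavior_repertoire()` plants the structure the pipeline is meant to find.
Postures are landmark templates sampled *hierarchically*: each module draws
a center pose by perturbing a quadrupedal reference pose (sd 0.08 m per
landmark), each posture perturbs its module center (sd 0.05 m), and
sampling repeats until all template pairs are at least 0.8 rad apart in
joint-angle space. The hierarchical draw makes modules kinematically
coherent, the way actions are: postures of one module resemble each other.
This matters beyond realism — transition frames blend adjacent templates,
and if templates were i.i.d., the blends of *all* posture pairs would pass
near the grand-mean pose and pile into a single hub basin of the embedding
that short-circuits the transition graph's modular structure. With coherent
modules, the 90% of transitions that stay within a module blend locally.

Labels follow a between-posture Markov chain (within-module mass 0.9,
optionally split again over super-modules) with geometric dwell times of
mean 18 frames — 0.6 s at 30 Hz, the typical posture dwell scale in
primates; the geometric choice is a modeling decision (memoryless dwells
match the first-order analysis downstream, which only sees between-run
transitions). Rendering adds linear 3-frame blends at run boundaries, a
center-of-mass trajectory following each posture's velocity tendency
(0–0.4 m/s, reflecting off the cage walls), per-subject uniform limb
scaling, and isotropic Gaussian observation noise (sd 1 cm).
`corrupt_session()` adds per-landmark session offsets (sd 2 cm), dropout
runs, and the two outlier types QC must catch (escapes and collapses).

What the generator does *not* emulate: realistic joint-angle dynamics
within a posture, multi-animal interaction, non-stationary repertoires, or
structured (non-Gaussian) tracking noise. Passing tests on this generator
therefore demonstrates that the pipeline recovers planted discrete-state
structure through the full feature/embedding/graph stack — not that any
particular animal's behavior has such structure.

## Problem sizes and numerical choices

The validation suite runs single sessions of 20,000 frames (about 11
minutes of recording at 30 Hz) for posture/module recovery, 60,000–90,000
frames of label sequence for graph statistics (labels need no rendering),
100-replicate nulls, and 20-replicate paired comparisons; these sizes give
stable statistics while keeping a full run in minutes on one CPU. Other
defaults worth knowing: embedding epochs 200; KDE margins extend one
bandwidth plus 5% of span beyond the data; the Paris implementation joins
disconnected components at 1.1x the largest merge height with a warning;
constant features map to 0 with a warning; and every stochastic step takes
an explicit seed, with pipeline stages drawing named sub-seeds from the
master seed.

## Known limitations

* The embedding engine implements the standard fuzzy-graph layout but is
  not a drop-in reimplementation of any particular library; embeddings are
  comparable in quality, not numerically identical.
* MNN alignment corrects additive, locally constant batch effects only, and
  carries the shrinkage bias discussed above.
* Watershed posture counts depend on the KDE bandwidth; the Silverman rule
  is a sensible default for unimodal-ish cluster shapes but is exposed
  precisely because it is a rule of thumb.
* The modularity cut window default [0.4, 1.4] matches the Paris height
  scale of typical posture transition graphs; for unusual graphs rely on
  the auto-extension (it warns when used).
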