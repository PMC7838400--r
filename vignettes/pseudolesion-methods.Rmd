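---
title: "Modular analysis of lesioned functional connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular analysis of lesioned functional connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudolesion)
```

# The scientific problem

A focal brain lesion (most commonly a middle-cerebral-artery stroke) removes
a set of grey-matter regions and every functional connection they carried.
Simulation studies model this as *node subtraction*: delete the lesioned
nodes and their edges from a healthy functional connectome and measure what
happens to the network. Those simulations predict that deleting *global
(connector) hubs* — nodes whose edges spread across modules — should
*increase* network modularity (modules become more segregated), while
deleting *local (provincial) hubs* — nodes strongly wired inside their own
module — should *decrease* it. Chronic-stroke connectomes, however, tend to
show the opposite relationship for global-hub damage, which suggests that a
second, slower process follows the subtraction: *long-term re-organization*
of connectivity among the remaining regions.

`pseudolesion` implements the comparison framework that separates the two
processes:

* **pseudo-lesions** — the lesioned node set of each patient applied to each
  healthy control's connectome, isolating pure node subtraction;
* **real-lesion connectomes** — here, a synthetic analogue produced by
  subtraction followed by an explicit re-organization transform;
* **simulated targeted lesions** — removal of all identified global or
  local hubs from each control, reproducing the classic attack simulations.

All graph analysis uses a *fixed* reference partition: modularity is
Newman's Q evaluated against a reference modular organization obtained once
from the healthy-control group (agglomerative Ward clustering of the average
Fisher-z matrix), not re-optimized per graph. Hub roles are measured with
the participation coefficient (PC) and the within-module degree z-score
(WD), and hubs are the nodes whose template value exceeds the cohort mean by
more than one (population) standard deviation, strictly.

# Pipeline stages and their conventions

**Background connectivity.** Task-fMRI time series are residualized against
task and nuisance regressors (an intercept is always included, so Pearson
centering is consistent), correlated pairwise, Fisher z-transformed with
clipping at `atanh(1 - 1e-7)`, and averaged across runs in z space.
Averaging happens after the transform; the transform order follows the
estimation sequence of the underlying method description.

**Proportional thresholding.** For each connectome the top
`round(p * n_pairs)` entries by *signed* z become edges of an undirected
binary graph; rounding is half-away-from-zero, and ties at the cut are
resolved by z descending then lexicographically smaller pair, which makes
edge sets nest across thresholds. Metrics are averaged over
`p in {0.10, 0.20, 0.25, 0.30, 0.40}`, except hub-topography comparisons,
which default to the single 25% threshold. For lesioned connectomes the
proportion is taken over retained-node pairs only. Signed (not absolute)
ranking is the package default because binarized hub analyses conventionally
keep the strongest positive couplings; hemispheric modularity restricts the
*connectome* to one hemisphere first and then thresholds the restriction,
so each hemisphere is a self-contained graph. Both choices are genuinely
underdetermined conventions; the alternative hemisphere convention
(restricting an already-thresholded graph) is available through
`hemisphere_subgraph()` on a `binary_graph`.

**Metrics.** Q, PC and WD use the standard fixed-partition formulas; PC of
an isolated node is 0, WD in a zero-variance module is 0, and all standard
deviations (WD and the hub cut) are population (divide-by-n) SDs, matching
the classic formulation of the within-module z-score; sample SDs are
available via the `sd_type` argument. Nodal templates average each node
over the subjects in which it was retained, recording `n_contributing` so
that low-coverage nodes in heavily lesioned cohorts can be filtered by the
user.

**Lesion resolution.** A voxel mask lesions a node when strictly more than
`frac_threshold` (default 25%) of the voxels in the node's sphere (default
radius 5 mm; the radius is exposed because the source literature reports
both 5 mm and 10 mm in different places) are damaged. A voxel belongs to a
sphere when its center lies within the radius. Sensitivity thresholds
(10/20/30%) are plain arguments.

**Inference.** Damage-modularity coupling is tested by permutation: the
per-mask damage vector is permuted (masks are the exchangeable units) and
the per-control correlations recomputed, with the mean correlation as the
group statistic and an add-one (never-zero) p-value. The default side is
one-sided in the direction of the observed correlation, which back-computes
correctly from the reported r/p pairs of the motivating study; note that
choosing the side from the observed sign doubles the null rejection rate,
so the two-sided variant (`side = "two_sided"`) is what satisfies nominal
type-I calibration and is used in the package's calibration tests. The
real-vs-pseudo comparison resamples the ten per-control correlations with
replacement, compares the single real-group correlation against the
bootstrap distribution of the mean, and doubles the smaller tail
(capped at 1). This procedure is anticonservative by construction — a
single draw is compared against the distribution of a mean — and should be
read as the published procedure, not as a calibrated test; the package's
tests therefore assert its tail and centrality behaviour rather than a
nominal error rate. Laterality of a hub set is tested with a 1-df
chi-square goodness-of-fit of left/right counts against 50/50, without
continuity correction.

# The synthetic cohort generator

The generator exists so that every stage above can run and be tested
without fMRI data. It emulates a healthy-control cohort as direct draws of
Fisher-z matrices: block means (within-module `atanh(r_within)`,
between-module `atanh(r_between)`) plus planted hub structure plus
independent symmetric Gaussian subject noise. No positive-definiteness is
enforced — everything downstream consumes ranks and thresholds, which are
invariant to a PD projection, and the transparent additive construction
makes every planted effect auditable.

Several design points matter and were chosen from the mechanics of the
measures themselves:

* **Node space.** Nodes come in mirrored left/right pairs (no `x == 0`
  nodes, so the midline is unambiguous) and every module is bilateral.
  Modules are *spatially diffuse* (centroid scatter comparable to the
  coordinate box), like real distributed functional systems; lesion masks,
  in contrast, are spatially contiguous. This separation is what lets a
  vascular-territory-like mask cut across modules instead of amputating a
  single module wholesale.
* **Continuous within-module strength.** Each node carries a fixed factor
  from a smooth, hemispherically mirrored spatial field (`strength_sd`,
  clipped at 1.6 SD to avoid clustering outliers), added to its
  within-module entries. Real connectomes have strong continuous
  within-degree heterogeneity; without it, WD degenerates to a
  noise-driven z-score and damage scores lose their meaning. The spatial
  smoothness makes contiguous masks coherent samplers of the field, and
  the mirroring keeps the strength topography bilateral.
* **Planted hubs.** Global hubs are the mirrored central pairs of one
  module and receive `hub_boost` on their between-module entries. The
  boost is deliberately modest relative to the within/between contrast:
  uniform between-module boosts make connector-hub rows nearly identical
  to one another, and too large a boost makes Ward clustering split the
  hubs into their own cluster instead of recovering the planted modules.
  Local hubs are each module's top *module-centered* strength nodes
  (round-robin across modules, half per hemisphere) with an extra
  within-module boost; both the centering and the round-robin placement
  follow from WD being a per-module z-score, which under-calls hubs
  concentrated in few (or high-variance) modules. Two boost parameters are
  needed because a provincial boost acts on ~module-size entries against a
  high baseline while a connector boost acts on all between-module entries
  against a low one; a single shared increment cannot express both roles.
* **Lesion masks.** Contiguous left-hemisphere node sets grown
  breadth-first over a 6-nearest-neighbour coordinate graph from seeds that
  cycle through a shuffled tour of the left nodes, so the 25-mask set
  reliably spans hub-rich and hub-poor territory. Sizes are uniform within
  bounds chosen to match the lesioned-node fractions of typical MCA stroke
  cohorts (about 2–13% of nodes).
* **Re-organization transform.** `pc_coupling` is the signed coupling
  between a lesion's global-hub damage and the modularity of the
  re-organized network: negative values add inter-module connectivity in
  proportion to (cohort-centered) PC damage, emulating compensatory
  integration that drives modularity down where connector-hub loss was
  greatest, without shifting the group-mean connectivity level.
  `wd_coupling` is the within-module analogue. Hub promotion selects
  `new_hub_count` surviving nodes (alternating local/global type,
  right-hemisphere with probability `rh_bias`), drawn once per cohort so
  group templates can detect them. The transform is a hypothesis
  instrument: defaults reproduce the qualitative re-organization
  fingerprint (flipped PC-damage coupling, excess and right-shifted new
  hubs), and are not an inference about mechanism.

## Default problem sizes

Two node-space sizes are used. The targeted-attack analyses run on the
default 60-node, 6-module space with 10 controls. The lesion-cohort
analyses (25 masks x 10 controls, plus 25 synthetic patients) run on a
120-node, 6-module space: with 60 nodes the within-module pair share (15%)
exceeds two of the five proportional thresholds, so within-module degrees
saturate and WD loses resolution, whereas at 120 nodes the share (7.8%)
sits below the smallest threshold — the same regime as the real 235-node,
10-module set (~10%). Subject and mask counts (10 controls, 25
patients/masks, 250 pseudo-lesion connectomes) mirror the motivating
study's cohort sizes.

```{r, eval = FALSE}
study <- simulate_study(seed = 1, params = cohort_params(n_nodes = 120),
                        size_min = 5, size_max = 16)
a1 <- run_analysis1(study)   # targeted attacks
a2 <- run_analysis2(study)   # pseudo vs real damage-modularity coupling
a3 <- run_analysis3(study)   # hub neurotopography
```

# What the synthetic tests do and do not show

Passing tests demonstrate that the pipeline's machinery is correct (the
metrics match brute-force oracles; the resampling procedures are calibrated
where calibration is claimed) and that the full analysis recovers planted
effects with the stated reliability under the generator's assumptions:
Gaussian z-space noise, additive block/hub structure, hemispherically
mirrored anatomy, vascular-like contiguous masks. They do not show anything
about hemodynamics, preprocessing, registration, lesion segmentation, or
the biological mechanism of re-organization — the generator has no
biophysics, no vascular territories and no anatomical atlas fidelity — and
a real-data effect size need not match the planted ones.

# Numerical choices

* Fisher clip `1e-7`; residual variance below `1e-12` is a degenerate
  series error naming the node.
* Edge-count rounding is half-away-from-zero; edge ties break by z then
  lexicographic pair order; both choices are for cross-platform
  determinism.
* Ward clustering runs on Euclidean distances between matrix rows with the
  diagonal replaced by the row's maximum off-diagonal entry
  (`stats::hclust(method = "ward.D2")`, the same criterion as SciPy's Ward
  linkage); cluster labels are renumbered in order of first appearance.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`), and `simulate_study()` records every derived
  sub-seed in its manifest; identical seeds reproduce byte-identical
  objects.
* Degenerate statistics (zero-variance t-tests, edgeless graphs, constant
  damage vectors) raise classed conditions or are flagged in the result
  tables rather than propagating NaN.

# Known limitations

* The module count must be supplied to `reference_partition()`; there is no
  model selection for k.
* Hub identification near the mean+1SD cut is sensitive to the WD ceiling
  (within-module degree is capped by module size), so planted-hub recovery
  is only guaranteed when boosts dominate the background heterogeneity.
* The bootstrap group comparison inherits the anticonservativeness of the
  published procedure (see above).
* Community detection by Q-optimization (Louvain/Leiden) and alternative
  centralities are deliberately out of scope: Q is always evaluated against
  the fixed reference partition.
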