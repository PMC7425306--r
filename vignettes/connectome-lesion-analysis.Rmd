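---
title: "Graph-theoretical analysis of structural connectomes after focal lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical analysis of structural connectomes after focal lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connectolesion)
```

## The analysis problem

A focal brain lesion (for example an ischaemic stroke in the basal ganglia)
does not only destroy tissue locally: the white-matter tracts passing through
the lesion degenerate, and with them the network of connections between
distant, intact grey-matter regions. This package implements a complete
group-level analysis of that phenomenon on *weighted structural connectomes*:
networks whose nodes are parcellated grey-matter regions (41 per hemisphere:
34 cortical, 6 subcortical, one brainstem-level node) and whose edge weights
derive from tractography streamline counts divided by the summed volumes of
the two endpoint regions,

$$ w_{st} = \frac{\mathrm{counts}_{st}}{V_s + V_t}, $$

symmetrized by averaging with the transpose. Whole-brain (82 × 82) and
intrahemispheric (41 × 41) matrices are analysed separately; the
intrahemispheric matrices exclude interhemispheric (transcallosal)
connections.

The package covers five layers:

1. **Connectome construction** — volume normalization, symmetrization, group
   averaging, proportional thresholding, hemispheric extraction
   (`weights_from_counts()`, `density_mask()`, `hemisphere_submatrix()`).
2. **Graph metrics with null-model normalization** — median connectivity
   strength $q_{50}$, weighted global efficiency, Onnela clustering,
   Louvain modularity, node strength; efficiency and clustering are reported
   as ratios to their mean over degree-, strength- and weight-preserving
   random null networks (`global_metrics()`, `null_ensemble()`).
3. **Group statistics** — mixed-effects lesion-status models, multi-threshold
   permutation correction (MTPC) over a density sweep, Bonferroni-corrected
   mass-univariate node tests, clinical regressions (`fit_lesion_model()`,
   `mtpc()`, `mass_univariate_nodes()`, `clinical_regression()`).
4. **Edgewise inference** — the network-based statistic (NBS) with
   permutation family-wise error control by component extent (`nbs_test()`).
5. **A computational lesion model** — weighted Watts–Strogatz networks with
   preferential removal of long-range connections
   (`run_lesion_experiment()`).

Because real diffusion-MRI cohorts cannot ship with a package, a
synthetic-cohort generator (`sample_cohort()`) produces data with the
statistical structure the analysis assumes, including a planted
cortico-subcortical lesion effect, so every stage is exercised end to end.

## Thresholding and the density sweep

Graph metrics of weighted brain networks depend strongly on network density.
The analysis therefore thresholds every network with a *sparsity mask*
derived from one reference — the average network of the healthy
participants — retaining the $\kappa \cdot n(n-1)/2$ strongest node pairs,
for $\kappa$ from 20% to 80% in steps of 5% (13 levels). All subjects share
each mask, so at a given density every network has the same binary topology
and group differences are carried by the weights. Local (node and edge)
analyses use a fixed $\kappa = 0.5$.

Two conventions the original procedure leaves open were fixed as follows:

* The retained-pair count is rounded half away from zero; ties in the
  reference are broken by (row, column) order, which makes masks from one
  reference exactly nested across densities.
* Whole-brain and hemispheric masks are built separately, each from its own
  healthy average; the hemispheric reference pools the controls' left and
  right hemispheres (the two hemispheres share the region sequence, so
  homologous pairs align).

## Metric conventions

* **$q_{50}$** is the median over *nonzero* pair weights; a median over all
  entries of a sparse matrix would be 0 and uninformative.
* **Global efficiency** uses path lengths $1/w$ and averages $1/d_{ij}$ over
  ordered pairs; disconnected pairs contribute 0 (the standard convention).
  All-pairs distances are computed by Floyd–Warshall in compiled code.
* **Clustering** is the Onnela weighted coefficient with weights scaled by
  the network maximum; nodes of degree < 2 contribute 0. It is invariant to
  global rescaling of the weights.
* **Modularity** is weighted Newman–Girvan $Q$, maximized by Louvain with 20
  seeded restarts followed by a greedy single-node refinement; the trivial
  one-community partition ($Q = 0$) is always a candidate, so unstructured
  graphs never return a negative optimum. On very small graphs (≤ 12 nodes)
  the optimizer additionally runs an exact bipartition scan plus depth-2
  relocation, merge and split lookaheads, which attains the global optimum on
  all exhaustively checkable test graphs.
* **Null models**: each surrogate randomizes the binary topology by
  Maslov–Sneppen double-edge swaps (10 attempted swaps per edge), preserving
  the degree sequence exactly, then re-assigns the original weight multiset
  to the new edges — rank matching on the product of endpoint strengths
  followed by a stochastic swap descent (50 proposals per edge, capped at
  25,000 proposals) on the squared strength error, with a targeted polish of
  concentrated residuals. The weight multiset is preserved exactly and the
  strength sequence to an ensemble-mean relative L2 error of 1–2% on
  41-node, $\kappa = 0.5$ fixtures; an occasional surrogate whose rewired
  topology constrains the match can sit near 10%, which leaves the
  null-ensemble means — the quantities used for normalization — essentially
  untouched. Weights are max-normalized internally so the surrogates are
  exactly scale-equivariant. Normalized metrics are ratios of the observed
  value to the null-ensemble mean.

A note on normalized efficiency: against degree-, strength- and
weight-preserving surrogates, *any* lattice-like modular network has
normalized efficiency below 1, because randomization converts strong local
edges into strong shortcuts. The small-world signature of the healthy
synthetic networks is therefore normalized clustering > 1 together with a
small-world index $\sigma = C_{\mathrm{norm}} \cdot E_{\mathrm{norm}} > 1$,
not $E_{\mathrm{norm}} > 1$ itself. Group *contrasts* in normalized
efficiency are unaffected by this offset.

## Statistical layer

**Lesion-status model.** Hemisphere-level observations (each patient: one
ipsilesional + one contralesional value; each control: two healthy values)
are modelled as

`value ~ side + lesion_status + (1 | subject)`

fitted first with the side × status interaction, which is dropped when a
likelihood-ratio test gives p ≥ 0.05. The omnibus effect of lesion status is
the likelihood-ratio statistic $\Lambda_2$ (with its $\chi^2$ p-value); a
Satterthwaite-approximated F is reported alongside because group tables are
conventionally printed as F statistics. Post-hoc mean separation uses
Tukey-adjusted pairwise contrasts; residual normality is checked by
Shapiro–Wilk. Printed denominator degrees of freedom depend on the
approximation chosen and are not matched to any particular convention.

**MTPC.** Metrics measured over the 13-density grid are tested with a
multi-threshold permutation correction: per density a one-way F across group
levels (equivalent to $t^2$ for two groups), `n_perm` label permutations
keeping each unit's whole curve intact, critical value $A_{crit}$ = the
(1 − α) quantile of the permutation maxima across densities, and a cluster
criterion — a contiguous supra-critical density cluster is significant only
if its area under the statistic-by-density curve exceeds the mean
supra-critical cluster area in the permutations. For the three-level
lesion-status analysis the permutation operates at the subject level
(patient/control assignment is shuffled and pseudo-patients receive a
permuted lesion side), because a subject's two hemisphere curves are not
exchangeable with each other. Within the permutation engine the statistic is
a plain one-way F rather than the mixed-model likelihood ratio: under
subject-level permutation the two are monotonically related for these
balanced designs, and the F is cheap enough to permute thousands of times.
The pooled-residual variant removes hemisphere-and-density cell means
(computed over all observations) before testing, isolating lesion status
from any left/right asymmetry.

**Mass-univariate node tests.** The lesion-status model is fitted per region
on node strengths at $\kappa = 0.5$; regions are flagged at the Bonferroni
threshold 0.05/41.

**NBS.** Edgewise pooled-variance two-sample t statistics; edges exceeding
the primary threshold (default t = 3.1; the package reports the
corresponding two-sided edgewise tail probability for the two-sample degrees
of freedom, without forcing any specific sidedness convention onto it) are
binarized, their connected components measured by extent, and family-wise
error controlled by the permutation distribution of the maximal extent with
add-one correction. Component size is extent (edge count), the NBS default;
deficit and excess contrasts run one-sided per direction. Edges with zero
variance across all subjects are excluded.

## The synthetic cohort: what it emulates, what it does not

`sample_cohort()` generates the study conditions the analysis expects:
17 patients (8 with left-sided lesions) and 21 controls.

Healthy connectomes place each hemisphere's 41 regions on a ring; expected
streamline counts combine (i) exponential decay with ring distance
(lattice/geometry), (ii) a same-module bonus over four contiguous modules
(mesoscale structure), (iii) a hub profile for the six subcortical nuclei,
whose thalamo- and striato-cortical projections connect them to the whole
hemisphere regardless of embedding distance, and (iv) strong homotopic
interhemispheric connections. Counts are negative-binomial (size 2, i.e. a
quadratic overdispersion coefficient of 0.5) around this profile, and each
subject carries a global log-normal scaling (sdlog 0.12) of all counts,
which is what makes the subject random intercept of the mixed models
meaningful. The resulting whole-brain weighted density is ~0.64.

The planted lesion multiplies counts by attenuation factors: 0.45 for edges
incident to the target regions on the lesioned side (precentral,
postcentral, superior parietal, superior temporal, insula, caudate, putamen,
pallidum, thalamus), 0.80 for the remaining ipsilesional edges, 0.92
contralesionally, an extra 0.75 on the longest tercile of ipsilesional edges
by ring distance, plus mean-one multiplicative log-normal noise (sdlog 0.1).
A per-patient severity in (0, 1) scales the target attenuation; its
correlation with the clinical grip-strength deficit defaults to 0, matching
the null clinical association of the motivating study, and can be raised to
verify that the regression stage recovers a planted association. These
defaults were fixed once, by the calibration simulations that the test suite
re-runs, so that a default cohort reproduces the qualitative pattern of
interest — an ipsilesional $q_{50}$ deficit, reduced normalized efficiency
with increased clustering and modularity in patients, and mass-univariate
node deficits covering the target set — and were not revisited afterwards.

Clinical scores: the grip-strength deficit is log-normal (meanlog log 7,
sdlog 0.8 kg), a standardized effect near Cohen's d = 1 versus zero; the
upper-extremity Fugl-Meyer score is concentrated at its ceiling of 66
(55% at ceiling, the rest a few points below), as is typical of chronic
cohorts with mild-to-moderate residual impairment.

All randomness descends from one master seed with documented offsets
(subject i's healthy counts use seed + i, lesion noise seed + 1000 + i,
clinical scores seed + 900, subject scaling seed + 800), so a cohort is
bit-reproducible.

What the generator does **not** emulate: diffusion-MRI physics, tractography
biases, spatially realistic lesion geometry, distance-dependent
false-positive streamlines, or any voxel-space processing. Passing tests on
synthetic cohorts therefore demonstrate that the statistical machinery
recovers planted effects of realistic size under realistic noise — not that
the pipeline is robust to the artefacts of real tractography.

One bookkeeping convention: the parcellation counts 34 cortical + 6
subcortical + 1 brainstem-level region per hemisphere, 82 nodes in total,
i.e. the brainstem-level node is represented once per hemisphere. The
cortical names follow the FreeSurfer Desikan–Killiany atlas as a stand-in
for the original region list.

## The Watts–Strogatz lesion model

`ws_generate()` builds a weighted ring lattice (41 nodes, mean degree
k = 10, so exactly 205 edges) and rewires each lattice edge with probability
P = 0.25 into a random non-duplicate shortcut; rewiring moves edges and
never deletes them, so the mean degree is exactly k for any seed. The
weighted-lattice weight scheme is not dictated by the model itself; the
default gives each lattice slot weight 1/offset (shortcuts inherit their
slot's weight), with `uniform` as the alternative — the group-contrast
directions hold under both. "Long-range" means a realized ring distance
greater than k/2 = 5, i.e. anything outside the lattice neighbourhood, which
captures rewired shortcuts and nothing of the untouched lattice; the cutoff
is configurable. `lesion_long_range()` removes round(q · count) of these
edges uniformly at random (q = 0.5 by default), leaving every short-range
edge untouched.

`run_lesion_experiment()` simulates 21 intact and 17 lesioned realizations,
normalizes efficiency and clustering per realization against its own null
ensemble, computes modularity, and compares the arms with Welch t-tests. The
expected pattern — lower normalized efficiency, higher normalized clustering
and higher modularity in the lesioned arm — emerges because removing
shortcuts lengthens paths while leaving the clustered lattice
neighbourhoods, and the nulls preserve only degrees, strengths and weights,
not geometry.

## Numerical and design choices

* Rounding of retained-pair and removal counts: half away from zero
  (base R's `round()` rounds half to even).
* Efficiency of disconnected pairs: 0. Empty networks: efficiency and
  clustering 0; $q_{50}$ and modularity raise errors (no defined value).
* Normalization with a zero null mean raises an error rather than returning
  infinity.
* Degenerate inputs: constant observation vectors make the mixed model
  return a flagged degenerate result with a warning; networks in which no
  degree-preserving swap exists cannot be randomized and raise an error.
* Permutation p-values use the add-one correction, so they are never 0.
* The Results-section symbol λ that the motivating analysis reports next to
  $q_{50}$ is never defined in its methods; it has no counterpart here.

## Problem sizes used by the shipped analyses

The analysis scripts and the acceptance script run at desk scale, chosen as
a deliberate package default: null ensembles of 100 (the publication-scale
convention is 1000), 500–1000 permutations (convention 5000), and the full
13-level density sweep. `run_config(publication_scale = TRUE)` switches to the
publication-scale sizes. Calibration tests use 100–200 simulated datasets
with 200–500 permutations each; the statistical guarantees being checked
(type-I error, FWER) are properties of the procedure, not of the ensemble
sizes, which only set the Monte-Carlo resolution of the check.

## Known limitations

* The generator's ring embedding makes "long-range" well defined but is a
  crude stand-in for anatomical distance; its long-range pairs are weak by
  construction, so the planted long-range attenuation mostly affects the
  unthresholded connectivity analysis ($q_{50}$), while the normalized-GGP
  group contrast is carried by the subcortical hub damage.
* With masks shared across subjects, group differences in thresholded
  metrics are purely weight-driven; subject-specific masks would add
  topological variability the original procedure deliberately avoids.
* The exhaustive modularity oracle in the test suite is limited to 8 nodes
  (set-partition enumeration); beyond that the Louvain + refinement optimum
  is checked only against closed forms.
* lme4 may report singular random-effect fits on degenerate synthetic
  inputs; these are suppressed deliberately in the mass-univariate loop,
  where the likelihood-ratio statistic remains well defined.
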