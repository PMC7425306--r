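# connectolesion

Group-level graph-theoretical analysis of weighted structural brain
connectomes after focal (stroke-like) lesions, with a synthetic-cohort
generator so the entire pipeline runs end to end without any imaging data.

## The problem

Chronic stroke does more than destroy tissue locally: the white-matter
tracts through the lesion degenerate, changing the *topology* of the
structural connectome in both hemispheres. Quantifying that requires a chain
of standard but fiddly steps — building weighted networks from
tractography-style streamline counts, thresholding them consistently,
computing graph parameters that are comparable across subjects, and testing
group differences with procedures that control family-wise error over
densities, nodes and edges. This package implements that chain for
parcellations with 41 regions per hemisphere (82 nodes):

* **Connectome construction** — edge weight = streamline count divided by
  the summed endpoint volumes, `w(s,t) = counts(s,t) / (V_s + V_t)`;
  symmetrization by transpose-averaging; whole-brain (82×82) and
  intrahemispheric (41×41) matrices.
* **Proportional thresholding** — sparsity masks retaining the κ·n(n−1)/2
  strongest pairs of the *healthy average* network, swept from κ = 20% to
  80% in steps of 5%; local analyses at fixed κ = 50%.
* **Global graph parameters** — median connectivity strength (q50), global
  efficiency (mean inverse shortest-path length on lengths 1/w), Onnela
  weighted clustering, Louvain modularity. Efficiency and clustering are
  normalized by their mean over degree-, strength- and weight-preserving
  random null networks (Maslov–Sneppen rewiring + strength-matched weight
  re-assignment, in compiled code).
* **Statistics** — mixed-effects lesion-status models
  (`value ~ side + lesion_status + (1 | subject)`, likelihood-ratio omnibus
  Λ₂, Satterthwaite F, Tukey post-hocs), multi-threshold permutation
  correction (MTPC) across the density sweep, Bonferroni mass-univariate
  node tests (0.05/41), the network-based statistic (NBS, primary threshold
  t = 3.1, FWER by permutation of maximal component extent), and clinical
  regressions.
* **Computational lesion model** — weighted Watts–Strogatz networks
  (41 nodes, k = 10, P = 0.25); removing half of the long-range connections
  reproduces the empirical signature: lower normalized efficiency, higher
  normalized clustering and modularity.

## Worked example

```r
library(connectolesion)

cohort <- sample_cohort(seed = 1)        # 17 patients / 21 controls
nets   <- build_connectomes(cohort)      # whole brain + hemispheres
qv  <- cbind(left  = sapply(nets$left,  q50),
             right = sapply(nets$right, q50))
fit <- fit_lesion_model(hemisphere_observations(qv, cohort$subjects))
print(fit)
```

```
<lesion_model> Lambda2 = 108.882, omnibus p = 2.273e-24
post-hoc (Tukey):
 contrast                          estimate           SE    df t.ratio p.value
 healthy - contralesional      0.0001239090 4.909488e-05 40.39   2.524  0.0406
 healthy - ipsilesional        0.0004989915 4.909488e-05 40.39  10.164  <.0001
 contralesional - ipsilesional 0.0003750826 2.357871e-05 36.00  15.908  <.0001
```

The planted lesion produces the expected pattern: ipsilesional median
connectivity strength is far below the healthy level (58% of it in this
cohort), with a much milder contralesional reduction. The same cohort can be pushed
through the full pipeline — density-swept normalized graph parameters with
MTPC, node-strength mass-univariate tests, NBS and the Watts–Strogatz lesion
simulation — with one call:

```r
report <- run_pipeline(run_config(seed = 1), cohort = cohort,
                       report_path = "results/report.json")
print(report)
```

```
<pipeline_report>
  q50 omnibus: Lambda2 = 108.88, p = 2.27e-24
  MTPC efficiency_norm: significant in whole_brain, left_hemisphere, right_hemisphere, pooled_residual
  MTPC clustering_norm: significant in whole_brain, left_hemisphere, right_hemisphere, pooled_residual
  MTPC modularity: significant in left_hemisphere, right_hemisphere, pooled_residual
  nodes flagged (Bonferroni): 41 of 41
  NBS: largest component extent 248, FWER p = 0.0020
  lesion sim:
           metric     t        p lesioned_minus_intact
1 efficiency_norm -6.04 1.33e-06               -0.0554
2 clustering_norm 11.82 1.73e-12                0.6452
3      modularity 11.21 7.04e-13                0.0672
  elapsed: 404.8 s
```

Reading the output: patients' thresholded networks are less integrated
(lower normalized efficiency) and more segregated (higher normalized
clustering and modularity) than controls' across the density sweep —
MTPC flags every scope for efficiency and clustering, and the hemispheric
and pooled-residual scopes for modularity; node-strength deficits are
flagged across the attenuated hemisphere with the strongest effects in the
planted cortico-subcortical motor set; NBS isolates one connected deficit
subnetwork (248 edges, FWER p = 0.002) dominated by edges touching the
target regions; and removing long-range connections from Watts–Strogatz
networks reproduces the same three directional shifts.

The same stages can be run as a narrated workflow with intermediate tables
under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1
Rscript analysis/02_connectivity_strength.R
Rscript analysis/03_global_topology.R 1      # slowest stage (several minutes)
Rscript analysis/04_local_analyses.R 1
Rscript analysis/05_clinical_and_lesion_model.R 1
```

## Package layout

```
R/                  implementation (generator, connectome, metrics,
                    null models, group stats, NBS, lesion sim, pipeline)
src/                compiled kernels (efficiency, clustering, null models)
analysis/           numbered workflow drivers writing results/ tables
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette (model, assumptions, design choices)
scripts/acceptance.R  headline-number reproduction script
```
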