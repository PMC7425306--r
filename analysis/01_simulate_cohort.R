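#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the synthetic cohort the downstream analyses run on: 17 patients
# (8 left-sided lesions, planted cortico-subcortical attenuation) and 21
# controls, with clinical scores, and writes it to results/cohort/ as
# per-subject count CSVs plus node/subject tables and a seed manifest.

suppressPackageStartupMessages(library(connectolesion))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cohort <- sample_cohort(seed = seed)
dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

cat(sprintf("cohort: %d subjects (%d patients, %d left lesions), seed %d\n",
            nrow(cohort$subjects),
            sum(cohort$subjects$group == "patient"),
            sum(cohort$subjects$lesion_side == "left", na.rm = TRUE), seed))
pat <- cohort$subjects$group == "patient"
cat(sprintf("grip deficit: median %.2f kg (patients); UEFM median %d\n",
            median(cohort$subjects$grip_delta_kg[pat]),
            median(cohort$subjects$uefm[pat])))
cat("written to results/cohort/\n")
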