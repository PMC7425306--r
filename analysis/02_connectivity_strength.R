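#!/usr/bin/env Rscript
# Stage 2 — build connectomes and test global connectivity strength.
#
# Reads the cohort written by stage 1, builds volume-normalized whole-brain
# and intrahemispheric connectomes, and fits the mixed-effects lesion-status
# model to the median connectivity strength (q50) of each hemisphere.
# Writes results/q50_observations.tsv and results/q50_model.json.

suppressPackageStartupMessages(library(connectolesion))

cohort <- read_cohort("results/cohort")
nets <- build_connectomes(cohort)
qv <- cbind(left = vapply(nets$left, q50, numeric(1)),
            right = vapply(nets$right, q50, numeric(1)))
obs <- hemisphere_observations(qv, cohort$subjects)
fit <- fit_lesion_model(obs)

write.table(obs, "results/q50_observations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(lambda2 = fit$lambda2, p_omnibus = fit$p_omnibus,
       interaction_p = fit$interaction_p, shapiro_p = fit$shapiro_p,
       group_means = as.list(tapply(obs$value, obs$lesion_status, mean)),
       posthoc = fit$posthoc, f_table = fit$f_table),
  "results/q50_model.json", auto_unbox = TRUE, digits = NA, pretty = TRUE,
  force = TRUE)

cat(sprintf("q50 omnibus: Lambda2 = %.2f, p = %.3g (interaction p = %.2f)\n",
            fit$lambda2, fit$p_omnibus, fit$interaction_p))
print(fit$posthoc, digits = 3)
means <- tapply(obs$value, obs$lesion_status, mean)
cat(sprintf("group means: healthy %.4g, contralesional %.4g (%.0f%%), ipsilesional %.4g (%.0f%%)\n",
            means["healthy"], means["contralesional"],
            100 * means["contralesional"] / means["healthy"],
            means["ipsilesional"],
            100 * means["ipsilesional"] / means["healthy"]))
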