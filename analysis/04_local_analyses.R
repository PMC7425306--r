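#!/usr/bin/env Rscript
# Stage 4 — localization: mass-univariate node tests and NBS.
#
# Node strengths at the fixed 50% density are tested per region with the
# lesion-status mixed model (Bonferroni 0.05/41); edgewise deficits are
# localized with the network-based statistic at t = 3.1 (patients'
# ipsilesional hemispheres vs controls). Writes results/node_tests.tsv,
# results/nbs_edges.tsv and results/nbs.json.

suppressPackageStartupMessages(library(connectolesion))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cohort <- read_cohort("results/cohort")
subjects <- cohort$subjects
parc <- cohort$parcellation
nets <- build_connectomes(cohort)
refs <- healthy_references(nets, subjects)
msk <- density_mask(refs$hemi, 0.5)
regions <- parc$name[parc$hemisphere == "left"]
n_s <- nrow(subjects)

S <- rbind(
  t(vapply(seq_len(n_s), function(i)
    node_strength(apply_mask(as_weights(nets$left[[i]]), msk)), numeric(41))),
  t(vapply(seq_len(n_s), function(i)
    node_strength(apply_mask(as_weights(nets$right[[i]]), msk)),
    numeric(41))))
colnames(S) <- regions
obs <- data.frame(subject = rep(subjects$id, 2),
                  side = rep(c("left", "right"), each = n_s),
                  stringsAsFactors = FALSE)
obs$lesion_status <- mapply(connectolesion:::status_of, id = obs$subject,
                            side = obs$side,
                            MoreArgs = list(subjects = subjects))
mu <- mass_univariate_nodes(S, obs)
write.table(mu, "results/node_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- mu[mu$significant, ]
cat(sprintf("%d of 41 regions significant after Bonferroni (0.05/41)\n",
            nrow(sig)))
cat("strongest deficits:",
    paste(head(mu$region[order(mu$p)], 8), collapse = ", "), "\n")

pat <- which(subjects$group == "patient")
ctrl <- which(subjects$group == "control")
g_a <- lapply(pat, function(i) as_weights(nets[[subjects$lesion_side[i]]][[i]]))
g_b <- lapply(ctrl, function(i)
  (as_weights(nets$left[[i]]) + as_weights(nets$right[[i]])) / 2)
nb <- nbs_test(g_a, g_b, t_threshold = 3.1, direction = "A<B",
               n_perm = 1000, seed = seed + 21)
print(nb)
if (length(nb$components)) {
  cp <- nb$components[[1]]
  edges <- data.frame(node1 = regions[cp$edges[, 1]],
                      node2 = regions[cp$edges[, 2]])
  write.table(edges, "results/nbs_edges.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("largest deficit component: %d edges, FWER p = %.4f\n",
              cp$extent, cp$fwer_p))
}
jsonlite::write_json(
  list(t_threshold = nb$t_threshold, edgewise_p = nb$edgewise_p,
       n_components = length(nb$components),
       extents = vapply(nb$components, function(cp) cp$extent, numeric(1)),
       fwer_p = vapply(nb$components, function(cp) cp$fwer_p, numeric(1))),
  "results/nbs.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("written results/node_tests.tsv, results/nbs_edges.tsv, results/nbs.json\n")
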