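#' Build all connectomes of a cohort
#'
#' Converts every subject's count matrix into a volume-normalized whole-brain
#' connectome plus its two intrahemispheric submatrices.
#'
#' @param cohort a [sample_cohort()] / [read_cohort()] object.
#' @return list with `whole`, `left`, `right`: named lists of connectomes.
#' @export
build_connectomes <- function(cohort) {
  parc <- cohort$parcellation
  whole <- lapply(cohort$counts, function(m)
    weights_from_counts(symmetrize(m), parc$volume_mm3, parc))
  list(whole = whole,
       left = lapply(whole, hemisphere_submatrix, side = "left"),
       right = lapply(whole, hemisphere_submatrix, side = "right"))
}

#' Healthy-average reference networks
#'
#' The whole-brain reference is the element-wise average over control
#' subjects' whole-brain networks. The hemispheric reference pools control
#' subjects' left and right hemispheres (region sequences are identical, so
#' homologous pairs align) into one 41 x 41 average; it is used for both
#' hemispheres' sparsity masks.
#'
#' @param nets result of [build_connectomes()].
#' @param subjects cohort subject table.
#' @return list with `whole` and `hemi` weight matrices.
#' @export
healthy_references <- function(nets, subjects) {
  ctrl <- subjects$id[subjects$group == "control"]
  if (length(ctrl) == 0) stop("no control subjects; reference undefined")
  whole <- Reduce(`+`, lapply(nets$whole[ctrl], as_weights)) / length(ctrl)
  hemi_mats <- c(lapply(nets$left[ctrl], as_weights),
                 lapply(nets$right[ctrl], as_weights))
  hemi <- Reduce(`+`, hemi_mats) / length(hemi_mats)
  list(whole = whole, hemi = hemi)
}

# lesion status of one subject's hemisphere
status_of <- function(subjects, id, side) {
  s <- subjects[subjects$id == id, ]
  if (s$group == "control") "healthy"
  else if (identical(as.character(side), s$lesion_side)) "ipsilesional"
  else "contralesional"
}

#' Global-graph-parameter curves for a set of networks
#'
#' Runs [density_sweep()] on each network against the common reference and
#' stacks the results into per-metric curve matrices (rows = networks,
#' columns = densities), plus node strengths at the fixed local density.
#'
#' @param nets named list of connectomes (one scope).
#' @param reference reference matrix for mask construction.
#' @param kappas density grid.
#' @param spec [null_spec()]; the per-network seed is offset from its seed.
#' @param local_kappa fixed density for node strengths.
#' @return list of matrices `efficiency_norm`, `clustering_norm`,
#'   `modularity`, `q50`, and `strength` (rows = networks).
#' @export
ggp_curves <- function(nets, reference, kappas = default_kappas(),
                       spec = null_spec(n_nulls = 100L),
                       local_kappa = 0.5) {
  res <- lapply(seq_along(nets), function(i) {
    sp_i <- spec
    sp_i$seed <- spec$seed + 101L * i
    density_sweep(nets[[i]], reference, kappas = kappas, spec = sp_i,
                  local_kappa = local_kappa)
  })
  pull <- function(col) {
    m <- do.call(rbind, lapply(res, function(r) r$global[[col]]))
    rownames(m) <- names(nets)
    m
  }
  strength <- do.call(rbind, lapply(res, function(r) r$strength))
  rownames(strength) <- names(nets)
  list(efficiency_norm = pull("efficiency_norm"),
       clustering_norm = pull("clustering_norm"),
       modularity = pull("modularity"),
       q50 = pull("q50"),
       strength = strength,
       kappas = kappas)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults (null ensembles of 100, 500 permutations) keep a full
#' run on one CPU in the minutes range; `publication_scale = TRUE` switches to
#' 1000 nulls and 5000 permutations.
#'
#' @param n_patients,n_controls,n_left_lesions,seed cohort parameters.
#' @param kappas density grid for the global sweep.
#' @param local_kappa fixed density for local (node/edge) analyses.
#' @param n_nulls,n_perm ensemble and permutation sizes.
#' @param nbs_t primary NBS threshold.
#' @param publication_scale use the publication-scale ensemble sizes.
#' @param do_mtpc,do_nbs,do_nodes,do_clinical,do_lesion_sim stage toggles.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_patients = 17L, n_controls = 21L,
                       n_left_lesions = 8L, seed = 1L,
                       kappas = default_kappas(), local_kappa = 0.5,
                       n_nulls = 100L, n_perm = 500L, nbs_t = 3.1,
                       publication_scale = FALSE,
                       do_mtpc = TRUE, do_nbs = TRUE, do_nodes = TRUE,
                       do_clinical = TRUE, do_lesion_sim = TRUE) {
  if (publication_scale) { n_nulls <- 1000L; n_perm <- 5000L }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_left_lesions = n_left_lesions, seed = seed,
                 kappas = kappas, local_kappa = local_kappa,
                 n_nulls = n_nulls, n_perm = n_perm, nbs_t = nbs_t,
                 do_mtpc = do_mtpc, do_nbs = do_nbs, do_nodes = do_nodes,
                 do_clinical = do_clinical, do_lesion_sim = do_lesion_sim),
            class = "run_config")
}

mtpc_summary <- function(m) {
  list(a_crit = m$a_crit, significant = m$significant,
       null_mean_auc = m$null_mean_auc, stat = m$stat,
       clusters = m$clusters)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Sequences cohort simulation, connectome construction, the q50
#' mixed-effects contrast, MTPC over the density sweep (whole brain, each
#' hemisphere, and the pooled side-centred residuals) for the three global
#' graph parameters, the Bonferroni mass-univariate node-strength analysis,
#' NBS, clinical regressions and the Watts-Strogatz lesion experiment, and
#' returns (optionally writes) a machine-readable report.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-built cohort (otherwise simulated from `cfg`).
#' @param report_path optional path for the JSON report.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(cfg = run_config(), cohort = NULL,
                         report_path = NULL) {
  t_start <- Sys.time()
  if (is.null(cohort))
    cohort <- sample_cohort(cfg$n_patients, cfg$n_controls,
                            cfg$n_left_lesions, seed = cfg$seed)
  subjects <- cohort$subjects
  parc <- cohort$parcellation
  regions <- parc$name[parc$hemisphere == "left"]
  nets <- build_connectomes(cohort)
  refs <- healthy_references(nets, subjects)
  report <- list(config = unclass(cfg),
                 cohort = list(n_patients = sum(subjects$group == "patient"),
                               n_controls = sum(subjects$group == "control"),
                               seed = cohort$params$seed))

  # --- q50 mixed-effects contrast on unthresholded hemispheric networks ---
  qvals <- cbind(left = vapply(nets$left, q50, numeric(1)),
                 right = vapply(nets$right, q50, numeric(1)))
  obs_q <- hemisphere_observations(qvals, subjects)
  fit_q <- fit_lesion_model(obs_q)
  report$q50 <- list(
    lambda2 = fit_q$lambda2, p_omnibus = fit_q$p_omnibus,
    interaction_p = fit_q$interaction_p, shapiro_p = fit_q$shapiro_p,
    group_means = as.list(tapply(obs_q$value, obs_q$lesion_status, mean)),
    posthoc = fit_q$posthoc, f_table = fit_q$f_table)

  # --- density-swept global parameters ---
  lesion_sides <- stats::setNames(
    subjects$lesion_side[subjects$group == "patient"],
    subjects$id[subjects$group == "patient"])
  sweeps <- list(
    whole = ggp_curves(nets$whole, refs$whole, cfg$kappas,
                       null_spec(cfg$n_nulls, seed = cfg$seed + 1L),
                       cfg$local_kappa),
    left = ggp_curves(nets$left, refs$hemi, cfg$kappas,
                      null_spec(cfg$n_nulls, seed = cfg$seed + 2L),
                      cfg$local_kappa),
    right = ggp_curves(nets$right, refs$hemi, cfg$kappas,
                       null_spec(cfg$n_nulls, seed = cfg$seed + 3L),
                       cfg$local_kappa))
  metrics3 <- c("efficiency_norm", "clustering_norm", "modularity")

  if (isTRUE(cfg$do_mtpc)) {
    group2 <- factor(subjects$group, levels = c("control", "patient"))
    mt <- list()
    for (mn in metrics3) {
      per_scope <- list()
      # whole brain: two-group contrast
      per_scope$whole_brain <- mtpc_summary(
        mtpc(sweeps$whole[[mn]], group2, densities = cfg$kappas,
             n_perm = cfg$n_perm, seed = cfg$seed + 11L))
      # per hemisphere: three-level lesion status of that hemisphere
      for (side in c("left", "right")) {
        st <- vapply(subjects$id, status_of, character(1),
                     subjects = subjects, side = side)
        per_scope[[paste0(side, "_hemisphere")]] <- mtpc_summary(
          mtpc(sweeps[[side]][[mn]],
               factor(st, levels = c("healthy", "contralesional",
                                     "ipsilesional")),
               densities = cfg$kappas, n_perm = cfg$n_perm,
               seed = cfg$seed + 12L))
      }
      # pooled side-centred residuals, subject-level permutation
      curves <- rbind(sweeps$left[[mn]], sweeps$right[[mn]])
      hemi_lab <- rep(c("left", "right"), each = nrow(subjects))
      subj_lab <- rep(subjects$id, 2)
      st <- mapply(status_of, id = subj_lab, side = hemi_lab,
                   MoreArgs = list(subjects = subjects))
      per_scope$pooled_residual <- mtpc_summary(
        pooled_residual_mtpc(curves, hemi_lab,
                             factor(st, levels = c("healthy",
                                                   "contralesional",
                                                   "ipsilesional")),
                             densities = cfg$kappas, n_perm = cfg$n_perm,
                             seed = cfg$seed + 13L, subject = subj_lab,
                             lesion_sides = lesion_sides))
      mt[[mn]] <- per_scope
    }
    report$mtpc <- mt
  }

  if (isTRUE(cfg$do_nodes)) {
    strengths <- rbind(sweeps$left$strength, sweeps$right$strength)
    colnames(strengths) <- regions
    obs_n <- data.frame(
      subject = rep(subjects$id, 2),
      side = rep(c("left", "right"), each = nrow(subjects)),
      stringsAsFactors = FALSE)
    obs_n$lesion_status <- mapply(status_of, id = obs_n$subject,
                                  side = obs_n$side,
                                  MoreArgs = list(subjects = subjects))
    report$nodes <- mass_univariate_nodes(strengths, obs_n)
  }

  if (isTRUE(cfg$do_nbs)) {
    pat <- subjects$id[subjects$group == "patient"]
    ctrl <- subjects$id[subjects$group == "control"]
    g_a <- lapply(pat, function(id)
      as_weights(nets[[lesion_sides[[id]]]][[id]]))
    g_b <- lapply(ctrl, function(id)
      (as_weights(nets$left[[id]]) + as_weights(nets$right[[id]])) / 2)
    nb <- nbs_test(g_a, g_b, t_threshold = cfg$nbs_t, direction = "A<B",
                   n_perm = cfg$n_perm, seed = cfg$seed + 21L)
    report$nbs <- list(
      t_threshold = nb$t_threshold, edgewise_p = nb$edgewise_p,
      components = lapply(nb$components, function(cp) list(
        extent = cp$extent, fwer_p = cp$fwer_p,
        edges = data.frame(node1 = regions[cp$edges[, 1]],
                           node2 = regions[cp$edges[, 2]]))))
  }

  if (isTRUE(cfg$do_clinical)) {
    pat_idx <- subjects$group == "patient"
    ipsi_q <- vapply(which(pat_idx), function(i)
      qvals[i, subjects$lesion_side[i]], numeric(1))
    report$clinical <- list(
      q50_vs_grip = clinical_regression(ipsi_q,
                                        subjects$grip_delta_kg[pat_idx]),
      q50_vs_uefm = clinical_regression(ipsi_q, subjects$uefm[pat_idx]))
  }

  if (isTRUE(cfg$do_lesion_sim)) {
    sim <- run_lesion_experiment(ws_config(),
                                 lesion_sim_config(n_nulls = cfg$n_nulls),
                                 seed = cfg$seed + 31L)
    report$lesion_sim <- list(table = sim$table, tests = sim$tests)
  }

  report$elapsed_s <- as.numeric(Sys.time() - t_start, units = "secs")
  class(report) <- "pipeline_report"
  if (!is.null(report_path)) {
    dir.create(dirname(report_path), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  q50 omnibus: Lambda2 = %.2f, p = %.3g\n",
              x$q50$lambda2, x$q50$p_omnibus))
  if (!is.null(x$mtpc)) {
    for (mn in names(x$mtpc)) {
      sig <- vapply(x$mtpc[[mn]], function(s) s$significant, logical(1))
      cat(sprintf("  MTPC %s: significant in %s\n", mn,
                  if (any(sig)) paste(names(sig)[sig], collapse = ", ")
                  else "none"))
    }
  }
  if (!is.null(x$nodes))
    cat(sprintf("  nodes flagged (Bonferroni): %d of %d\n",
                sum(x$nodes$significant), nrow(x$nodes)))
  if (!is.null(x$nbs) && length(x$nbs$components))
    cat(sprintf("  NBS: largest component extent %d, FWER p = %.4f\n",
                x$nbs$components[[1]]$extent, x$nbs$components[[1]]$fwer_p))
  if (!is.null(x$lesion_sim)) {
    cat("  lesion sim:\n"); print(x$lesion_sim$tests, digits = 3)
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}

#' Structural check of a pipeline report
#'
#' Verifies that a report (or its JSON serialization) contains the sections
#' and fields of the published report schema
#' (`inst/extdata/report-schema.json`).
#'
#' @param report a `pipeline_report` or a list parsed from the JSON file.
#' @return TRUE (invisibly) or an error describing the missing field.
#' @export
validate_report <- function(report) {
  need <- c("config", "cohort", "q50")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("report is missing sections: ", paste(missing, collapse = ", "))
  if (!all(c("lambda2", "p_omnibus") %in% names(report$q50)))
    stop("q50 section incomplete")
  toggles <- c(do_mtpc = "mtpc", do_nodes = "nodes", do_nbs = "nbs",
               do_clinical = "clinical", do_lesion_sim = "lesion_sim")
  for (tg in names(toggles)) {
    if (isTRUE(report$config[[tg]]) && is.null(report[[toggles[[tg]]]]))
      stop("enabled stage missing from report: ", toggles[[tg]])
  }
  invisible(TRUE)
}
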