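#' Hemisphere-level observations for the lesion-status model
#'
#' Expands per-subject, per-side metric values into the observation table the
#' group models use: each patient contributes one ipsilesional and one
#' contralesional value, each control two healthy values.
#'
#' @param values numeric matrix or data.frame, one row per subject, columns
#'   `left` and `right`.
#' @param subjects subject table with columns `id`, `group`
#'   (`patient`/`control`) and `lesion_side` (NA for controls).
#' @return data.frame with columns `subject`, `side`, `lesion_status`
#'   (factor: healthy, contralesional, ipsilesional) and `value`.
#' @export
hemisphere_observations <- function(values, subjects) {
  stopifnot(nrow(values) == nrow(subjects),
            all(c("left", "right") %in% colnames(values)))
  obs <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    status <- function(side) {
      if (s$group == "control") "healthy"
      else if (identical(side, s$lesion_side)) "ipsilesional"
      else "contralesional"
    }
    data.frame(subject = s$id, side = c("left", "right"),
               lesion_status = c(status("left"), status("right")),
               value = c(values[i, "left"], values[i, "right"]),
               stringsAsFactors = FALSE)
  }))
  obs$lesion_status <- factor(obs$lesion_status,
                              levels = c("healthy", "contralesional",
                                         "ipsilesional"))
  obs$side <- factor(obs$side, levels = c("left", "right"))
  obs
}

quiet_lmer <- function(formula, data, reml = FALSE) {
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
}

#' Mixed-effects lesion-status model
#'
#' Fits `value ~ side + lesion_status + (1 | subject)` to hemisphere-level
#' observations. The model is first fitted with the side x lesion-status
#' interaction; if the interaction is not significant by likelihood-ratio
#' test (p >= 0.05) it is refitted without, as is standard. Reports the
#' omnibus likelihood-ratio statistic for lesion status (Lambda2), a
#' Satterthwaite-approximated F test, Tukey-adjusted pairwise post-hoc
#' contrasts between the three status levels, and a Shapiro-Wilk test of the
#' residuals.
#'
#' @param observations data.frame from [hemisphere_observations()].
#' @return list of class `lesion_model` with elements `lambda2`, `p_omnibus`,
#'   `f_table`, `posthoc` (data.frame), `interaction_p`, `shapiro_p`,
#'   `degenerate`, and the fitted `model`.
#' @export
fit_lesion_model <- function(observations) {
  obs <- observations
  obs$lesion_status <- droplevels(factor(obs$lesion_status))
  if (nlevels(obs$lesion_status) < 2)
    stop("need at least 2 lesion-status levels")
  cell_n <- table(obs$lesion_status)
  if (any(cell_n < 3))
    warning("fewer than 3 observations in some lesion-status cell")
  if (stats::var(obs$value) == 0) {
    warning("degenerate input: zero variance in values")
    return(structure(list(lambda2 = 0, p_omnibus = NA_real_, f_table = NULL,
                          posthoc = NULL, interaction_p = NA_real_,
                          shapiro_p = NA_real_, degenerate = TRUE,
                          model = NULL),
                     class = "lesion_model"))
  }
  has_side <- nlevels(droplevels(obs$side)) > 1
  f_full <- if (has_side) value ~ side * lesion_status + (1 | subject)
            else value ~ lesion_status + (1 | subject)
  f_add <- if (has_side) value ~ side + lesion_status + (1 | subject)
           else value ~ lesion_status + (1 | subject)
  f_null <- if (has_side) value ~ side + (1 | subject)
            else value ~ 1 + (1 | subject)
  m_add <- quiet_lmer(f_add, obs)
  interaction_p <- NA_real_
  chosen <- m_add
  if (has_side && nlevels(obs$lesion_status) > 1) {
    m_full <- quiet_lmer(f_full, obs)
    lrt <- stats::anova(m_add, m_full)
    interaction_p <- lrt$`Pr(>Chisq)`[2]
    if (!is.na(interaction_p) && interaction_p < 0.05) chosen <- m_full
  }
  m_null <- quiet_lmer(f_null, obs)
  lrt0 <- stats::anova(m_null, m_add)
  lambda2 <- lrt0$Chisq[2]
  p_omnibus <- lrt0$`Pr(>Chisq)`[2]
  # Satterthwaite F for the lesion-status factor, as printed in group tables
  m_f <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f_add, data = obs, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore"))))
  f_table <- tryCatch(as.data.frame(stats::anova(m_f, type = 3)),
                      error = function(e) NULL)
  posthoc <- tryCatch({
    emm <- emmeans::emmeans(m_f, "lesion_status")
    as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                    adjust = "tukey"))
  }, error = function(e) NULL)
  sh <- tryCatch(stats::shapiro.test(stats::residuals(chosen))$p.value,
                 error = function(e) NA_real_)
  structure(list(lambda2 = lambda2, p_omnibus = p_omnibus, f_table = f_table,
                 posthoc = posthoc, interaction_p = interaction_p,
                 shapiro_p = sh, degenerate = FALSE, model = chosen),
            class = "lesion_model")
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf("<lesion_model> Lambda2 = %.3f, omnibus p = %.4g\n",
              x$lambda2, x$p_omnibus))
  if (!is.null(x$posthoc)) {
    cat("post-hoc (Tukey):\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

# one-way F statistic per column of a values matrix, given a grouping factor
oneway_f_by_column <- function(values, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  n <- nrow(values)
  gm <- colMeans(values)
  cnt <- as.numeric(table(groups))
  means <- rowsum(values, groups) / cnt
  ssb <- colSums(cnt * (sweep(means, 2, gm))^2)
  ssw <- colSums((values - means[as.integer(groups), , drop = FALSE])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  ifelse(msw > 0, msb / msw, 0)
}

# contiguous supra-critical clusters of a statistic curve; AUC by trapezoid
supra_clusters <- function(stat, densities, a_crit) {
  above <- stat > a_crit
  if (!any(above)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      auc = numeric(0), peak = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- lapply(keep, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    auc <- if (i2 > i1) {
      sum(diff(densities[i1:i2]) *
            (utils::head(stat[i1:i2], -1) + utils::tail(stat[i1:i2], -1)) / 2)
    } else stat[i1] * 0  # single-density cluster has zero trapezoid area
    data.frame(start = densities[i1], end = densities[i2], auc = auc,
               peak = max(stat[i1:i2]))
  })
  do.call(rbind, out)
}

#' Multi-threshold permutation correction (MTPC) over a density sweep
#'
#' Tests a group effect on a metric measured over a grid of network
#' densities, combining effect magnitude and persistence across densities.
#' Per density the group statistic is a one-way F across the group levels
#' (equivalent to t^2 for two groups). Unit labels are permuted `n_perm`
#' times keeping each unit's curve intact; the critical value `A_crit` is the
#' (1 - alpha) quantile of the permutation maxima across densities. Observed
#' contiguous supra-critical clusters are significant if their area under the
#' statistic-by-density curve exceeds the mean supra-critical cluster area in
#' the permutations.
#'
#' For the three-level lesion-status analysis, pass hemisphere-level curves
#' plus `subject` ids and the original patient lesion sides; permutation then
#' operates at the subject level (patient/control assignment is shuffled and
#' pseudo-patients get a permuted lesion side), keeping both of a subject's
#' hemisphere curves together.
#'
#' @param curves numeric matrix, one row per unit, one column per density.
#' @param groups factor of group labels (one per row).
#' @param densities numeric density grid (columns of `curves`).
#' @param n_perm number of permutations (default 5000).
#' @param alpha family-wise level.
#' @param seed integer seed.
#' @param subject optional subject id per row; with `side` and
#'   `lesion_sides`, enables subject-level lesion-status permutation.
#' @param side optional hemisphere label per row (`left`/`right`).
#' @param lesion_sides optional named character vector: lesion side per
#'   patient subject id.
#' @return list of class `mtpc_result`: `stat`, `densities`, `a_crit`,
#'   `clusters` (data.frame), `null_mean_auc`, `significant`, `n_perm`.
#' @export
mtpc <- function(curves, groups, densities = default_kappas(),
                 n_perm = 5000L, alpha = 0.05, seed = 1L,
                 subject = NULL, side = NULL, lesion_sides = NULL) {
  curves <- as.matrix(curves)
  if (ncol(curves) != length(densities))
    stop("density grid does not match curve columns")
  if (n_perm < 100) warning("n_perm < 100 gives unstable critical values")
  groups <- factor(groups)
  subject_level <- !is.null(subject) && !is.null(side) &&
    !is.null(lesion_sides)
  obs_stat <- oneway_f_by_column(curves, groups)

  if (subject_level) {
    subj_ids <- unique(subject)
    n_subj <- length(subj_ids)
    is_patient <- subj_ids %in% names(lesion_sides)
    n_pat <- sum(is_patient)
    sides_pool <- unname(lesion_sides)
    relabel <- function() {
      pat_idx <- sample.int(n_subj, n_pat)
      new_side <- rep(NA_character_, n_subj)
      new_side[pat_idx] <- sample(sides_pool)
      names(new_side) <- subj_ids
      st <- ifelse(is.na(new_side[subject]), "healthy",
                   ifelse(new_side[subject] == as.character(side),
                          "ipsilesional", "contralesional"))
      factor(st, levels = c("healthy", "contralesional", "ipsilesional"))
    }
  } else {
    relabel <- function() groups[sample.int(length(groups))]
  }

  perm_max <- numeric(n_perm)
  perm_curves <- matrix(0, n_perm, ncol(curves))
  withr_seed(seed, {
    for (p in seq_len(n_perm)) {
      st <- oneway_f_by_column(curves, relabel())
      perm_curves[p, ] <- st
      perm_max[p] <- max(st)
    }
  })
  a_crit <- stats::quantile(perm_max, 1 - alpha, names = FALSE, type = 7)
  clusters <- supra_clusters(obs_stat, densities, a_crit)
  null_aucs <- unlist(lapply(seq_len(n_perm), function(p) {
    cl <- supra_clusters(perm_curves[p, ], densities, a_crit)
    if (nrow(cl) > 0) max(cl$auc) else NULL
  }))
  null_mean_auc <- if (length(null_aucs) > 0) mean(null_aucs) else 0
  significant <- nrow(clusters) > 0 && any(clusters$auc > null_mean_auc)
  structure(list(stat = obs_stat, densities = densities, a_crit = a_crit,
                 clusters = clusters, null_mean_auc = null_mean_auc,
                 significant = significant, n_perm = n_perm, alpha = alpha),
            class = "mtpc_result")
}

#' @export
print.mtpc_result <- function(x, ...) {
  cat(sprintf("<mtpc> A_crit = %.3f, %d supra-critical cluster(s), %s\n",
              x$a_crit, nrow(x$clusters),
              if (x$significant) "SIGNIFICANT" else "not significant"))
  if (nrow(x$clusters) > 0) print(x$clusters, digits = 3)
  invisible(x)
}

#' MTPC on side-centred residuals pooled across hemispheres
#'
#' Removes the hemisphere effect before testing lesion status: from each
#' data point the hemisphere- and density-specific average (over all
#' observations) is subtracted, and the MTPC analysis is run on the pooled
#' residuals.
#'
#' @param curves hemisphere-level curves (rows = subject x side).
#' @param hemisphere `left`/`right` label per row.
#' @param groups lesion-status factor per row.
#' @inheritParams mtpc
#' @return an `mtpc_result`.
#' @export
pooled_residual_mtpc <- function(curves, hemisphere, groups,
                                 densities = default_kappas(),
                                 n_perm = 5000L, alpha = 0.05, seed = 1L,
                                 subject = NULL, lesion_sides = NULL) {
  curves <- as.matrix(curves)
  hemisphere <- factor(hemisphere)
  cell_means <- rowsum(curves, hemisphere) /
    as.numeric(table(hemisphere))
  resid <- curves - cell_means[as.integer(hemisphere), , drop = FALSE]
  mtpc(resid, groups, densities = densities, n_perm = n_perm, alpha = alpha,
       seed = seed, subject = subject, side = hemisphere,
       lesion_sides = lesion_sides)
}

#' Mass-univariate node-strength tests with Bonferroni correction
#'
#' Fits the lesion-status mixed model per region on node strengths and flags
#' regions whose omnibus p-value clears the Bonferroni threshold
#' `alpha / n_regions` (0.05/41 for the default parcellation).
#'
#' @param strengths matrix of node strengths: one row per hemisphere
#'   observation, one column per region.
#' @param obs observation metadata (columns `subject`, `side`,
#'   `lesion_status`) matching the rows.
#' @param alpha nominal level before correction.
#' @return data.frame per region: `region`, `lambda2`, `p`, `neglog10p`,
#'   `p_bonf_threshold`, `significant`.
#' @export
mass_univariate_nodes <- function(strengths, obs, alpha = 0.05) {
  strengths <- as.matrix(strengths)
  stopifnot(nrow(strengths) == nrow(obs))
  regions <- colnames(strengths)
  if (is.null(regions)) regions <- paste0("region_", seq_len(ncol(strengths)))
  thr <- alpha / ncol(strengths)
  res <- lapply(seq_len(ncol(strengths)), function(j) {
    o <- obs
    o$value <- strengths[, j]
    m1 <- quiet_lmer(value ~ side + lesion_status + (1 | subject), o)
    m0 <- quiet_lmer(value ~ side + (1 | subject), o)
    lrt <- stats::anova(m0, m1)
    p <- lrt$`Pr(>Chisq)`[2]
    data.frame(region = regions[j], lambda2 = lrt$Chisq[2], p = p,
               neglog10p = -log10(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonf_threshold <- thr
  out$significant <- out$p < thr
  out
}

#' Linear regression of a clinical score on a network metric
#'
#' Ordinary least squares of `score` on `metric`, with Pearson correlation
#' and the two-sided p-value of the slope.
#'
#' @param metric numeric vector (per subject).
#' @param score numeric vector (per subject, same length).
#' @return list with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
clinical_regression <- function(metric, score) {
  keep <- stats::complete.cases(metric, score)
  metric <- metric[keep]; score <- score[keep]
  if (length(metric) < 3) stop("need at least 3 complete subject pairs")
  if (stats::var(metric) == 0 || stats::var(score) == 0)
    stop("zero variance in metric or score")
  fit <- stats::lm(score ~ metric)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(metric, score),
       p = sm$coefficients[2, 4],
       n = length(metric))
}
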