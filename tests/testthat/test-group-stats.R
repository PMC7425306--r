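simulate_null_obs <- function(n_pat = 17, n_ctrl = 21, seed = 1) {
  set.seed(seed)
  subj <- data.frame(
    id = sprintf("S%02d", seq_len(n_pat + n_ctrl)),
    group = c(rep("patient", n_pat), rep("control", n_ctrl)),
    lesion_side = c(rep(c("left", "right"), length.out = n_pat),
                    rep(NA, n_ctrl)),
    stringsAsFactors = FALSE)
  base <- rnorm(n_pat + n_ctrl, 10, 0.5)   # subject random effect
  vals <- cbind(left = base + rnorm(n_pat + n_ctrl, 0, 0.7),
                right = base + rnorm(n_pat + n_ctrl, 0, 0.7))
  hemisphere_observations(vals, subj)
}

test_that("lesion-model omnibus test is calibrated under the null", {
  rej <- vapply(1:200, function(s) {
    m <- fit_lesion_model(simulate_null_obs(seed = s))
    m$p_omnibus < 0.05
  }, logical(1))
  rate <- mean(rej)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("a planted ipsilesional deficit is separated post hoc", {
  hits <- vapply(1:50, function(s) {
    obs <- simulate_null_obs(seed = 1000 + s)
    sd_w <- 0.7
    obs$value[obs$lesion_status == "ipsilesional"] <-
      obs$value[obs$lesion_status == "ipsilesional"] - 2 * sd_w
    m <- fit_lesion_model(obs)
    ph <- m$posthoc
    ipsi_rows <- grepl("ipsilesional", ph$contrast)
    all(ph$p.value[ipsi_rows] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted fixed effects are recovered within 2 SE", {
  hits <- vapply(1:40, function(s) {
    obs <- simulate_null_obs(seed = 2000 + s)
    obs$value[obs$lesion_status == "ipsilesional"] <-
      obs$value[obs$lesion_status == "ipsilesional"] - 1.5
    m <- fit_lesion_model(obs)
    fe <- lme4::fixef(m$model)
    se <- sqrt(diag(as.matrix(vcov(m$model))))
    est <- fe[["lesion_statusipsilesional"]]
    abs(est - (-1.5)) < 2 * se[["lesion_statusipsilesional"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate constant input is flagged, not fitted", {
  obs <- simulate_null_obs(seed = 3)
  obs$value <- 5
  expect_warning(m <- fit_lesion_model(obs), "degenerate")
  expect_true(m$degenerate)
})

test_that("MTPC finds no clusters on constant curves", {
  curves <- matrix(1, 20, 13)
  groups <- rep(c("a", "b"), each = 10)
  res <- mtpc(curves, groups, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_false(res$significant)
})

test_that("MTPC detects a shift present at every density as one full cluster", {
  set.seed(8)
  curves <- matrix(rnorm(38 * 13), 38, 13)
  groups <- rep(c("a", "b"), c(17, 21))
  curves[groups == "a", ] <- curves[groups == "a", ] + 2
  res <- mtpc(curves, groups, n_perm = 300, seed = 2)
  expect_true(res$significant)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start, default_kappas()[1])
  expect_equal(res$clusters$end, default_kappas()[13])
})

test_that("MTPC is reproducible under a fixed seed", {
  set.seed(9)
  curves <- matrix(rnorm(30 * 13), 30, 13)
  groups <- rep(c("a", "b"), 15)
  r1 <- mtpc(curves, groups, n_perm = 150, seed = 5)
  r2 <- mtpc(curves, groups, n_perm = 150, seed = 5)
  expect_identical(r1$a_crit, r2$a_crit)
  expect_identical(r1$clusters, r2$clusters)
})

test_that("pooled residual MTPC removes side effects but keeps lesion effects", {
  mk <- function(seed, side_shift = 0, lesion_shift = 0) {
    set.seed(seed)
    n <- 38
    subj <- sprintf("S%02d", seq_len(n))
    group <- rep(c("patient", "control"), c(17, 21))
    lesion_side <- c(rep(c("left", "right"), length.out = 17), rep(NA, 21))
    curves <- matrix(rnorm(2 * n * 13, 10, 1), 2 * n, 13)
    hemi <- rep(c("left", "right"), each = n)
    curves[hemi == "left", ] <- curves[hemi == "left", ] + side_shift
    status <- vapply(seq_len(2 * n), function(r) {
      i <- ((r - 1) %% n) + 1
      if (group[i] == "control") "healthy"
      else if (identical(hemi[r], lesion_side[i])) "ipsilesional"
      else "contralesional"
    }, character(1))
    # lesion effect equal in both hemispheres of patients
    curves[status != "healthy", ] <- curves[status != "healthy", ] -
      lesion_shift
    list(curves = curves, hemi = hemi,
         status = factor(status, levels = c("healthy", "contralesional",
                                            "ipsilesional")),
         subject = rep(subj, 2),
         lesion_sides = setNames(lesion_side[1:17], subj[1:17]))
  }
  # side-only effect: confound is removed, no significance
  d <- mk(4, side_shift = 3, lesion_shift = 0)
  r0 <- pooled_residual_mtpc(d$curves, d$hemi, d$status, n_perm = 300,
                             seed = 3, subject = d$subject,
                             lesion_sides = d$lesion_sides)
  expect_false(r0$significant)
  # bilateral lesion effect: detected
  d2 <- mk(5, side_shift = 3, lesion_shift = 2)
  r1 <- pooled_residual_mtpc(d2$curves, d2$hemi, d2$status, n_perm = 300,
                             seed = 3, subject = d2$subject,
                             lesion_sides = d2$lesion_sides)
  expect_true(r1$significant)
})

test_that("mass-univariate node tests respect the Bonferroni guarantee", {
  # null cohorts: expected flagged count per cohort ~ alpha / regions * regions
  set.seed(12)
  n_flag <- vapply(1:10, function(s) {
    obs <- simulate_null_obs(seed = 400 + s)
    strengths <- matrix(rnorm(nrow(obs) * 10, 20, 2), nrow(obs), 10)
    colnames(strengths) <- paste0("r", 1:10)
    sum(mass_univariate_nodes(strengths, obs)$significant)
  }, numeric(1))
  expect_lte(mean(n_flag), 0.2)
})

test_that("a single-node planted deficit is localized to that node", {
  hits <- vapply(1:10, function(s) {
    obs <- simulate_null_obs(seed = 500 + s)
    strengths <- matrix(rnorm(nrow(obs) * 10, 20, 1), nrow(obs), 10)
    colnames(strengths) <- paste0("r", 1:10)
    ipsi <- obs$lesion_status == "ipsilesional"
    strengths[ipsi, 4] <- strengths[ipsi, 4] - 4
    res <- mass_univariate_nodes(strengths, obs)
    res$significant[4] && sum(res$significant) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("clinical regression recovers exact and null relations", {
  x <- c(1, 2, 3, 4, 5)
  # an exact linear relation makes summary.lm warn about the perfect fit
  fit <- suppressWarnings(clinical_regression(x, 2 * x))
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 2)
  # calibration under independence
  set.seed(3)
  rej <- vapply(1:500, function(i) {
    clinical_regression(rnorm(17), rnorm(17))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.09)
  expect_error(clinical_regression(x, rep(1, 5)), "variance")
  expect_error(clinical_regression(c(1, 2), c(1, 2)), "at least 3")
})
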