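test_that("healthy counts are symmetric, nonnegative, zero-diagonal and seeded", {
  parc <- make_parcellation(1)
  a <- sample_healthy_counts(parc, seed = 5)
  expect_identical(a, t(a))
  expect_true(all(a >= 0))
  expect_equal(diag(a), rep(0, 82))
  expect_identical(a, sample_healthy_counts(parc, seed = 5))
  expect_false(identical(a, sample_healthy_counts(parc, seed = 6)))
  # lattice part: expected weight decreases with ring distance
  mu <- connectolesion:::healthy_mu_intra(41)
  expect_true(all(diff(mu[1, 2:21]) < 0 | diff(mu[1, 2:21]) == 0))
  # density after weighting in the intended band
  w <- weights_from_counts(a, parc$volume_mm3, parc)
  dens <- mean(w$weights[upper.tri(w$weights)] > 0)
  expect_gt(dens, 0.4); expect_lt(dens, 0.8)
})

test_that("lesion application is the identity at unit factors / zero noise", {
  parc <- make_parcellation(1)
  cnt <- sample_healthy_counts(parc, seed = 2)
  id_spec <- lesion_spec(ipsilesional_attenuation = 1,
                         ipsilesional_background_attenuation = 1,
                         contralesional_attenuation = 1,
                         long_range_extra_attenuation = 1, noise_sd = 0)
  expect_equal(apply_synthetic_lesion(cnt, parc, id_spec, seed = 1),
               cnt + 0)  # numeric comparison; input is integer storage
})

test_that("target-edge attenuation multiplies counts as specified", {
  parc <- make_parcellation(1)
  cnt <- sample_healthy_counts(parc, seed = 2)
  sp <- lesion_spec(side = "left", target_regions = "thalamus",
                    ipsilesional_attenuation = 0.5,
                    ipsilesional_background_attenuation = 1,
                    contralesional_attenuation = 1,
                    long_range_extra_attenuation = 1, noise_sd = 0)
  out <- apply_synthetic_lesion(cnt, parc, sp, seed = 1)
  th <- which(parc$hemisphere == "left" & parc$name == "thalamus")
  other_left <- setdiff(hemisphere_index(parc, "left"), th)
  expect_equal(out[th, other_left], 0.5 * cnt[th, other_left])
  # non-incident contralesional edges untouched
  ri <- hemisphere_index(parc, "right")
  expect_equal(out[ri, ri], cnt[ri, ri] + 0)
  expect_error(apply_synthetic_lesion(cnt, parc,
                                      within(sp, side <- "up"), seed = 1))
})

test_that("cohorts have the configured composition and clinical structure", {
  coh <- sample_cohort(seed = 3)
  expect_equal(nrow(coh$subjects), 38)
  expect_equal(sum(coh$subjects$group == "patient"), 17)
  expect_equal(sum(coh$subjects$lesion_side == "left", na.rm = TRUE), 8)
  expect_true(all(is.na(coh$subjects$lesion_side[coh$subjects$group ==
                                                   "control"])))
  expect_true(all(coh$subjects$uefm <= 66))
  # grip-strength deficit standardized effect near d = 1
  grip <- coh$subjects$grip_delta_kg[coh$subjects$group == "patient"]
  d <- mean(grip) / sd(grip)
  expect_gt(d, 0.5); expect_lt(d, 2)
  expect_length(coh$counts, 38)
  expect_error(sample_cohort(n_patients = 2, n_left_lesions = 5, seed = 1),
               "exceed")
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  a <- sample_cohort(n_patients = 3, n_controls = 3, n_left_lesions = 2,
                     seed = 42)
  b <- sample_cohort(n_patients = 3, n_controls = 3, n_left_lesions = 2,
                     seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$subjects, b$subjects)
})

test_that("unit factors with zero noise make patient and control draws coincide", {
  id_spec <- lesion_spec(ipsilesional_attenuation = 1,
                         ipsilesional_background_attenuation = 1,
                         contralesional_attenuation = 1,
                         long_range_extra_attenuation = 1, noise_sd = 0)
  coh <- sample_cohort(n_patients = 2, n_controls = 2, n_left_lesions = 1,
                       seed = 5, lesion = id_spec, subject_scale_sd = 0)
  # subject i's counts depend only on seed + i, not on group membership
  parc <- coh$parcellation
  for (i in 1:4)
    expect_equal(coh$counts[[i]], sample_healthy_counts(parc, seed = 5 + i) + 0)
})

test_that("an all-control cohort is valid but group tests are undefined", {
  coh <- sample_cohort(n_patients = 0, n_controls = 5, n_left_lesions = 0,
                       seed = 2)
  expect_equal(nrow(coh$subjects), 5)
  expect_true(all(coh$subjects$group == "control"))
  qv <- cbind(left = rep(1, 5), right = rep(1, 5))
  obs <- hemisphere_observations(qv, coh$subjects)
  expect_error(fit_lesion_model(obs), "levels")
})

test_that("cohort writer round-trips matrices exactly", {
  coh <- sample_cohort(n_patients = 2, n_controls = 2, n_left_lesions = 1,
                       seed = 9)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  expect_length(list.files(dir, pattern = "^counts_.*csv$"), 4)
  expect_true(all(c("nodes.tsv", "subjects.tsv", "manifest.json") %in%
                    list.files(dir)))
  back <- read_cohort(dir)
  for (id in names(coh$counts))
    expect_identical(back$counts[[id]], coh$counts[[id]] + 0)
  expect_equal(back$subjects$id, coh$subjects$id)
  expect_equal(back$params$seed, 9)
  # regeneration from the manifest seed reproduces identical files
  coh2 <- sample_cohort(back$params$n_patients, back$params$n_controls,
                        back$params$n_left_lesions, seed = back$params$seed)
  expect_identical(coh2$counts, coh$counts)
  unlink(dir, recursive = TRUE)
})

test_that("planted severity-score coupling is recovered by regression", {
  coh <- sample_cohort(n_patients = 60, n_controls = 5, n_left_lesions = 30,
                       seed = 21, severity_score_r = 0.8)
  pat <- coh$subjects$group == "patient"
  # severity drives the planted attenuation; grip deficit is coupled at r=0.8
  fit <- clinical_regression(coh$subjects$severity[pat],
                             coh$subjects$grip_delta_kg[pat])
  expect_lt(fit$p, 0.01)
  expect_gt(fit$slope, 0)
  # and the structural metric (ipsilesional q50) carries the association
  parc <- coh$parcellation
  ipsi_q <- vapply(which(pat), function(i) {
    w <- weights_from_counts(symmetrize(coh$counts[[i]]), parc$volume_mm3,
                             parc)
    q50(hemisphere_submatrix(w, coh$subjects$lesion_side[i]))
  }, numeric(1))
  fit2 <- clinical_regression(ipsi_q, coh$subjects$grip_delta_kg[pat])
  expect_lt(fit2$p, 0.01)
  expect_lt(fit2$slope, 0)  # worse deficit, lower ipsilesional q50
})
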