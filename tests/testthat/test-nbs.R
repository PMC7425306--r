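mat_of <- function(vals) {
  # 2x2 matrices whose single pair carries the given value, one per subject
  lapply(vals, function(v) matrix(c(0, v, v, 0), 2, 2))
}

test_that("edgewise t matches the hand-computed pooled-variance statistic", {
  gA <- mat_of(c(1, 2, 3))
  gB <- mat_of(c(4, 5, 6))
  tm <- edge_t_matrix(gA, gB)
  # pooled sd = 1, se = 1 * sqrt(1/3 + 1/3); t = -3 / se
  expect_equal(tm[1, 2], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tm[1, 2], -3.674, tolerance = 1e-3)
  expect_identical(tm, t(tm))
  # identical groups give zero; swapping groups negates
  expect_true(all(edge_t_matrix(gA, gA) == 0))
  expect_equal(edge_t_matrix(gB, gA), -tm)
  expect_error(edge_t_matrix(gA[1], gB), "2 subjects")
})

test_that("supra-threshold components follow graph connectivity", {
  tm <- matrix(0, 6, 6)
  expect_length(supra_threshold_components(tm, 3, "A>B"), 0)
  # a 3-edge path
  tm[1, 2] <- tm[2, 1] <- 4; tm[2, 3] <- tm[3, 2] <- 4
  tm[3, 4] <- tm[4, 3] <- 4
  comps <- supra_threshold_components(tm, 3, "A>B")
  expect_length(comps, 1)
  expect_equal(comps[[1]]$extent, 3)
  # two disjoint triangles, deficit direction
  tm2 <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    tm2[p[1], p[2]] <- tm2[p[2], p[1]] <- -4
  comps2 <- supra_threshold_components(tm2, 3, "A<B")
  expect_length(comps2, 2)
  expect_equal(vapply(comps2, function(cp) cp$extent, numeric(1)), c(3, 3))
  # threshold above all |t|
  expect_length(supra_threshold_components(tm2, 5, "A<B"), 0)
})

simulate_groups <- function(seed, n = 12, nA = 6, shift_edges = NULL,
                            shift = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    w <- matrix(0, 12, 12)
    ut <- upper.tri(w)
    w[ut] <- rnorm(sum(ut), 5, 1)
    if (i <= nA && !is.null(shift_edges))
      w[shift_edges] <- w[shift_edges] + shift
    w + t(w)
  })
}

test_that("NBS detects a planted connected deficit subnetwork", {
  # a connected 10-edge star-plus-path on nodes 1..6, shifted down in group A
  idx <- cbind(c(1, 1, 1, 1, 1, 2, 2, 3, 4, 5),
               c(2, 3, 4, 5, 6, 3, 4, 4, 5, 6))
  shift_edges <- idx[, 1] + (idx[, 2] - 1) * 12
  hits <- vapply(1:10, function(s) {
    nets <- simulate_groups(700 + s, n = 38, nA = 17,
                            shift_edges = shift_edges, shift = -3)
    res <- nbs_test(nets[1:17], nets[18:38], t_threshold = 3.1,
                    direction = "A<B", n_perm = 200, seed = s)
    length(res$components) > 0 && res$components[[1]]$fwer_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("max component extent is monotone non-increasing in the threshold", {
  nets <- simulate_groups(99, n = 20, nA = 10)
  extents <- vapply(c(1, 2, 3), function(th) {
    r <- nbs_test(nets[1:10], nets[11:20], t_threshold = th,
                  direction = "A<B", n_perm = 100, seed = 1)
    if (length(r$components)) r$components[[1]]$extent else 0L
  }, integer(1))
  expect_true(all(diff(extents) <= 0))
})

test_that("NBS permutation nulls are seed-reproducible and inputs validated", {
  nets <- simulate_groups(5, n = 10, nA = 5)
  r1 <- nbs_test(nets[1:5], nets[6:10], n_perm = 120, seed = 7)
  r2 <- nbs_test(nets[1:5], nets[6:10], n_perm = 120, seed = 7)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  expect_error(nbs_test(nets[1:5], nets[6:10], n_perm = 0), "positive")
  expect_equal(r1$edgewise_p, 2 * pt(-3.1, 8))
})

test_that("a single-threshold sweep reduces to nbs_test", {
  nets <- simulate_groups(6, n = 10, nA = 5)
  sw <- nbs_threshold_sweep(nets[1:5], nets[6:10], thresholds = 2.5,
                            direction = "A<B", n_perm = 150, seed = 3)
  single <- nbs_test(nets[1:5], nets[6:10], t_threshold = 2.5,
                     direction = "A<B", n_perm = 150, seed = 3)
  expect_equal(sw$best_threshold, 2.5)
  expect_equal(sw$summary$max_extent,
               if (length(single$components))
                 single$components[[1]]$extent else 0L)
})
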