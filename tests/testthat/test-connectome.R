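test_that("weights follow count / summed-volume and zero out the diagonal", {
  counts <- matrix(c(0, 100, 50, 100, 0, 0, 50, 0, 0), 3, 3)
  vols <- c(40, 60, 25)
  cw <- weights_from_counts(counts, vols)
  expect_equal(cw$weights[1, 2], 1.0)          # 100 / (40 + 60)
  expect_equal(cw$weights[1, 3], 50 / 65)
  expect_equal(cw$weights[2, 3], 0)
  expect_equal(diag(cw$weights), rep(0, 3))
  counts2 <- matrix(c(0, 50, 50, 0), 2, 2)
  expect_equal(weights_from_counts(counts2, c(25, 25))$weights[1, 2], 1.0)
  expect_error(weights_from_counts(counts, c(40, -1, 25)), "positive")
  expect_error(weights_from_counts(counts, c(40, 60)), "match")
})

test_that("symmetrize averages with the transpose and is idempotent", {
  raw <- matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE)
  s <- symmetrize(raw)
  expect_equal(s, matrix(c(0, 3, 3, 0), 2, 2))
  expect_equal(symmetrize(s), s)
  set.seed(5)
  r <- matrix(rnorm(25), 5, 5)
  expect_equal(symmetrize(symmetrize(r)), symmetrize(r))
  expect_error(symmetrize(matrix(1, 2, 3)), "square")
})

test_that("group average is the element-wise mean and preserves symmetry", {
  parc <- make_parcellation(1)
  a <- connectome(matrix(c(0, 2, 2, 0), 2, 2), NULL, "whole_brain")
  b <- connectome(matrix(c(0, 4, 4, 0), 2, 2), NULL, "whole_brain")
  expect_equal(group_average(list(a))$weights, a$weights)
  avg <- group_average(list(a, b))
  expect_equal(avg$weights[1, 2], 3)
  expect_equal(avg$weights, t(avg$weights))
  expect_error(group_average(list()), "at least one")
})

test_that("density mask retains exactly round(kappa * P) pairs, nested", {
  set.seed(2)
  ref <- matrix(0, 41, 41)
  ref[upper.tri(ref)] <- sample(seq_len(820))   # distinct weights
  ref <- ref + t(ref)
  m50 <- density_mask(ref, 0.5)
  expect_equal(sum(m50[upper.tri(m50)]), 410)
  # brute force: the retained pairs are exactly the 410 largest
  vals <- ref[upper.tri(ref)]
  expect_true(all(vals[m50[upper.tri(m50)] == 1] >= sort(vals,
                                                         decreasing = TRUE)[410]))
  # boundary and small case
  small <- matrix(0, 4, 4)
  small[upper.tri(small)] <- c(6, 5, 4, 3, 2, 1)
  small <- small + t(small)
  expect_equal(sum(density_mask(small, 0.5)[upper.tri(small)]), 3)
  expect_equal(sum(density_mask(small, 1)[upper.tri(small)]), 6)
  # sweep of 13 nested masks
  kappas <- default_kappas()
  expect_length(kappas, 13)
  masks <- lapply(kappas, density_mask, reference = ref)
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i]] <= masks[[i + 1]]))
  expect_error(density_mask(ref, 0), "kappa")
  expect_error(density_mask(ref, 1.2), "kappa")
})

test_that("density mask breaks ties deterministically", {
  tied <- matrix(1, 6, 6); diag(tied) <- 0
  m1 <- density_mask(tied, 0.4)
  m2 <- density_mask(tied, 0.4)
  expect_identical(unclass(m1), unclass(m2))
  expect_equal(sum(m1[upper.tri(m1)]), 6)  # round(0.4 * 15)
})

test_that("apply_mask zeroes outside the mask and matches its density", {
  set.seed(3)
  w <- matrix(0, 10, 10)
  w[upper.tri(w)] <- runif(45, 0.1, 1)
  w <- w + t(w)
  m <- density_mask(w, 0.4)
  out <- apply_mask(w, m)
  expect_equal(sum(out[upper.tri(out)] > 0), round(0.4 * 45))
  expect_equal(apply_mask(w, matrix(1, 10, 10) - diag(10)), w)
  expect_true(all(apply_mask(w, matrix(0, 10, 10)) == 0))
  expect_error(apply_mask(w, matrix(1, 5, 5)), "dimension")
})

test_that("hemisphere submatrices partition the whole brain", {
  parc <- make_parcellation(1)
  cnt <- sample_healthy_counts(parc, seed = 1)
  wb <- weights_from_counts(cnt, parc$volume_mm3, parc)
  lh <- hemisphere_submatrix(wb, "left")
  rh <- hemisphere_submatrix(wb, "right")
  expect_equal(nrow(lh$weights), 41)
  expect_equal(nrow(rh$weights), 41)
  expect_setequal(c(hemisphere_index(parc, "left"),
                    hemisphere_index(parc, "right")), seq_len(82))
  expect_equal(lh$weights, t(lh$weights))
  # block extraction is the principal submatrix
  idx <- hemisphere_index(parc, "left")
  expect_equal(lh$weights, wb$weights[idx, idx])
  expect_error(hemisphere_submatrix(lh, "left"), "whole-brain")
})

test_that("matrix CSV writer round-trips exactly", {
  set.seed(9)
  w <- matrix(0, 12, 12)
  w[upper.tri(w)] <- ifelse(runif(66) < 0.6, rlnorm(66), 0)
  w <- w + t(w)
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(w, f)
  expect_identical(read_matrix_csv(f), w)
  unlink(f)
})
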