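test_that("q50 is the median of nonzero pair weights", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 2; w[1, 4] <- w[4, 1] <- 3
  expect_equal(q50(w), 2)
  w[2, 3] <- w[3, 2] <- 4
  expect_equal(q50(w), 2.5)
  u <- matrix(0.7, 5, 5); diag(u) <- 0
  expect_equal(q50(u), 0.7)
  expect_error(q50(matrix(0, 3, 3)), "nonzero")
})

test_that("node strength sums incident weights (handshake identity)", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5; w[1, 3] <- w[3, 1] <- 1.5
  expect_equal(node_strength(w), c(2.0, 0.5, 1.5))
  set.seed(4)
  r <- random_toy_graph(8, seed = 4)
  expect_equal(sum(node_strength(r)), 2 * sum(r[upper.tri(r)]))
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(node_strength(iso)[3], 0)
})

test_that("global efficiency matches closed forms", {
  for (wgt in c(0.5, 1, 2)) {
    cm <- matrix(wgt, 6, 6); diag(cm) <- 0
    expect_equal(global_efficiency(cm), wgt)
  }
  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1; path[2, 3] <- path[3, 2] <- 1
  expect_equal(global_efficiency(path), (1 + 1 + 0.5) / 3)
})

test_that("Onnela clustering matches hand-worked examples", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_onnela(tri), 1.0)
  tri2 <- tri
  tri2[1, 2] <- tri2[2, 1] <- 0.125
  expect_equal(clustering_onnela(tri2), 0.5)
  tree <- matrix(0, 4, 4)
  tree[1, 2] <- tree[2, 1] <- 1; tree[2, 3] <- tree[3, 2] <- 1
  tree[2, 4] <- tree[4, 2] <- 1
  expect_equal(clustering_onnela(tree), 0)
})

test_that("modularity matches closed forms and stays within bounds", {
  two <- matrix(0, 8, 8)
  two[1:4, 1:4] <- 1; two[5:8, 5:8] <- 1; diag(two) <- 0
  res <- modularity_louvain(two, seed = 1)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  full <- matrix(1, 7, 7); diag(full) <- 0
  res2 <- modularity_louvain(full, seed = 1)
  expect_equal(res2$Q, 0)
  expect_equal(length(unique(res2$membership)), 1)
  for (s in 1:5) {
    r <- random_toy_graph(9, seed = s + 20)
    expect_lte(modularity_louvain(r, seed = 1)$Q, 1)
  }
})

test_that("efficiency and clustering agree with brute force to 1e-10", {
  for (s in 1:50) {
    n <- sample(4:10, 1)
    w <- random_toy_graph(n, p = 0.55, seed = s)
    expect_equal(global_efficiency(w), brute_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(clustering_onnela(w), brute_clustering(w),
                 tolerance = 1e-10)
  }
})

test_that("Louvain modularity attains the exhaustive-partition optimum", {
  for (s in 1:20) {
    n <- sample(5:8, 1)
    w <- random_toy_graph(n, p = 0.6, seed = 100 + s)
    expect_equal(modularity_louvain(w, seed = 1)$Q, brute_modularity(w),
                 tolerance = 1e-10)
  }
})

test_that("efficiency is monotone non-decreasing under edge additions", {
  set.seed(11)
  for (s in 1:10) {
    w <- random_toy_graph(8, p = 0.4, seed = 300 + s)
    zero <- which(upper.tri(w) & w == 0)
    if (length(zero) == 0) next
    e0 <- global_efficiency(w)
    w2 <- w
    add <- zero[sample.int(length(zero), 1)]
    w2[add] <- 0.8
    w2 <- pmax(w2, t(w2))
    expect_gte(global_efficiency(w2), e0 - 1e-12)
  }
})

test_that("metric scaling behaviour: invariances and linearity", {
  w <- random_toy_graph(9, seed = 77)
  k <- 3.7
  expect_equal(clustering_onnela(k * w), clustering_onnela(w))
  expect_equal(modularity_louvain(k * w, seed = 2)$Q,
               modularity_louvain(w, seed = 2)$Q, tolerance = 1e-10)
  expect_equal(q50(k * w), k * q50(w))
  expect_equal(node_strength(k * w), k * node_strength(w))
  expect_equal(global_efficiency(k * w), k * global_efficiency(w))
  # normalized metrics are scale-invariant too (same seed, scaled input)
  sp <- null_spec(n_nulls = 20, seed = 5)
  nulls1 <- null_ensemble(w, sp)
  nulls2 <- null_ensemble(k * w, sp)
  e1 <- normalize_metric(global_efficiency(w),
                         sapply(nulls1, global_efficiency))
  e2 <- normalize_metric(global_efficiency(k * w),
                         sapply(nulls2, global_efficiency))
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("normalize_metric handles identity, zero and empty cases", {
  expect_equal(normalize_metric(2, c(2, 2, 2)), 1.0)
  expect_equal(normalize_metric(0, c(1, 3)), 0)
  expect_error(normalize_metric(1, numeric(0)), "empty")
  expect_error(normalize_metric(1, c(0, 0)), "zero")
})

test_that("density sweep returns one row per density with nested edges", {
  parc <- make_parcellation(1)
  w <- weights_from_counts(sample_healthy_counts(parc, seed = 3),
                           parc$volume_mm3, parc)
  lh <- hemisphere_submatrix(w, "left")
  kappas <- c(0.2, 0.5, 0.8)
  sw <- density_sweep(lh, lh, kappas = kappas,
                      spec = null_spec(n_nulls = 5, seed = 2))
  expect_equal(nrow(sw$global), 3)
  expect_equal(sw$global$kappa, kappas)
  expect_length(sw$strength, 41)
  # single-density sweep
  sw1 <- density_sweep(lh, lh, kappas = 0.5,
                       spec = null_spec(n_nulls = 5, seed = 2))
  expect_equal(nrow(sw1$global), 1)
})
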