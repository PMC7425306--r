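# Independent brute-force oracles for the graph metrics, used to validate the
# package implementations on small graphs. Deliberately naive and separate
# from the package code paths.

# all-pairs shortest paths by naive Dijkstra from every source, on lengths 1/w
brute_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  len <- ifelse(w > 0, 1 / w, Inf)
  acc <- 0
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    visited <- rep(FALSE, n)
    for (step in seq_len(n)) {
      u <- which(!visited)[which.min(dist[!visited])]
      if (!is.finite(dist[u])) break
      visited[u] <- TRUE
      for (v in which(!visited))
        if (dist[u] + len[u, v] < dist[v]) dist[v] <- dist[u] + len[u, v]
    }
    ok <- is.finite(dist) & dist > 0
    acc <- acc + sum(1 / dist[ok])
  }
  acc / (n * (n - 1))
}

# Onnela weighted clustering by explicit triangle enumeration
brute_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  cw <- w / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n))
      for (l in seq_len(n))
        if (j != i && l != i && j != l)
          acc <- acc + (cw[i, j] * cw[i, l] * cw[j, l])^(1 / 3)
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

# enumerate all set partitions of n items (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# maximum Newman-Girvan weighted modularity by exhaustive partition search
brute_modularity <- function(w) {
  n <- nrow(w)
  m2 <- sum(w)
  s <- rowSums(w)
  best <- -Inf
  for (memb in all_partitions(n)) {
    q <- 0
    for (cc in unique(memb)) {
      idx <- memb == cc
      q <- q + sum(w[idx, idx]) / m2 - (sum(s[idx]) / m2)^2
    }
    if (q > best) best <- q
  }
  best
}

# random symmetric weighted toy graph (guaranteed at least one edge)
random_toy_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    vals <- ifelse(runif(sum(ut)) < p, round(runif(sum(ut), 0.1, 2), 3), 0)
    w[ut] <- vals
    w <- w + t(w)
    if (sum(w) > 0) return(w)
  }
}

# tiny cohort for pipeline-level tests (small but with planted deficit)
tiny_cohort <- function(seed = 1, n_patients = 6, n_controls = 7) {
  sample_cohort(n_patients = n_patients, n_controls = n_controls,
                n_left_lesions = ceiling(n_patients / 2), seed = seed)
}
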