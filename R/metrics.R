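#' Median connectivity strength (q50)
#'
#' Median of the nonzero upper-triangle weights of a network. Zero entries of
#' the sparse matrix are absent connections, not zero-strength ones, so they
#' are excluded.
#'
#' @param c [connectome()] or symmetric matrix.
#' @return a single number.
#' @export
q50 <- function(c) {
  w <- as_weights(c)
  v <- w[upper.tri(w)]
  v <- v[v > 0]
  if (length(v) == 0) stop("network has no nonzero edges")
  stats::median(v)
}

#' Node strength
#'
#' Sum of edge weights incident to each node.
#'
#' @param c [connectome()] or symmetric matrix.
#' @return numeric vector, one value per node.
#' @export
node_strength <- function(c) {
  rowSums(as_weights(c))
}

as_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted global efficiency
#'
#' Mean of inverse shortest-path lengths over ordered node pairs, where path
#' lengths are summed reciprocal weights (strong connections are short).
#' Disconnected pairs have infinite distance and contribute 0. All-pairs
#' distances are computed in compiled code (Floyd-Warshall).
#'
#' @param c [connectome()] or symmetric matrix.
#' @return a single number; 0 for an edgeless network.
#' @export
global_efficiency <- function(c) {
  w <- as_weights(c)
  if (nrow(w) < 2 || all(w == 0)) return(0)
  global_efficiency_cpp(w)
}

#' Weighted global clustering coefficient (Onnela)
#'
#' Mean over nodes of the Onnela geometric-mean triangle intensity: weights
#' are scaled by the network maximum, and
#' `c_i = sum_{jk} (w_ij w_ik w_jk)^(1/3) / (k_i (k_i - 1))`
#' with `k_i` the binary degree. Nodes with degree < 2 contribute 0. The
#' max-weight scaling makes the coefficient invariant to a global rescaling
#' of all weights.
#'
#' @param c [connectome()] or symmetric matrix.
#' @return a single number in [0, 1].
#' @export
clustering_onnela <- function(c) {
  w <- as_weights(c)
  if (max(w) == 0) return(0)
  clustering_onnela_cpp(w)
}

# Newman-Girvan weighted modularity of a membership vector.
modularity_value <- function(w, membership, gamma = 1) {
  m2 <- sum(w)                       # 2m, total weight counted both ways
  if (m2 == 0) stop("network has zero total weight")
  s <- rowSums(w)
  comms <- unique(membership)
  q <- 0
  for (cc in comms) {
    idx <- membership == cc
    q <- q + sum(w[idx, idx]) / m2 - gamma * (sum(s[idx]) / m2)^2
  }
  q
}

# Greedy single-node refinement of a partition: repeatedly move nodes to the
# neighbouring community with the largest modularity gain until a local
# optimum. Gain of moving i from community a to b (strengths S before move):
#   dQ = 2 (w_ib - w_ia') / m2 - 2 gamma s_i (S_b - S_a + s_i) / m2^2
# with m2 = sum(w), w_ia' the weight from i into a excluding i itself.
refine_partition <- function(w, membership, gamma = 1, aggressive = TRUE) {
  n <- nrow(w)
  m2 <- sum(w)
  s <- rowSums(w)
  memb <- as.integer(factor(membership))
  repeat {
    improved <- FALSE
    n_comm <- max(memb)
    s_comm <- as.numeric(rowsum(s, memb, reorder = TRUE)[, 1])
    # single-node moves; aggressive mode also offers a fresh singleton
    repeat {
      moved <- FALSE
      for (i in seq_len(n)) {
        cur <- memb[i]
        wi <- numeric(n_comm + 1)
        agg <- rowsum(w[i, ], memb)
        wi[as.integer(rownames(agg))] <- agg[, 1]
        cand <- setdiff(which(wi[seq_len(n_comm)] > 0), cur)
        if (aggressive) cand <- c(cand, n_comm + 1L)
        if (length(cand) == 0) next
        s_cand <- c(s_comm, 0)[cand]
        gain <- 2 * (wi[cand] - wi[cur]) / m2 -
          2 * gamma * s[i] * (s_cand - s_comm[cur] + s[i]) / m2^2
        j <- which.max(gain)
        if (gain[j] > 1e-12) {
          b <- cand[j]
          if (b > n_comm) { n_comm <- n_comm + 1L; s_comm <- c(s_comm, 0) }
          s_comm[cur] <- s_comm[cur] - s[i]
          s_comm[b] <- s_comm[b] + s[i]
          memb[i] <- b
          moved <- TRUE
          improved <- TRUE
        }
      }
      if (!moved) break
    }
    if (!aggressive) break
    # community merges: dQ(a, b) = 2 W_ab / m2 - 2 gamma S_a S_b / m2^2
    memb <- as.integer(factor(memb))
    n_comm <- max(memb)
    if (n_comm < 2) break
    W_cc <- rowsum(t(rowsum(w, memb)), memb)      # community x community
    s_comm <- as.numeric(rowsum(s, memb)[, 1])
    gain <- 2 * W_cc / m2 - 2 * gamma * outer(s_comm, s_comm) / m2^2
    diag(gain) <- -Inf
    best <- which.max(gain)
    if (gain[best] > 1e-12) {
      ab <- arrayInd(best, dim(gain))
      memb[memb == ab[2]] <- ab[1]
      memb <- as.integer(factor(memb))
      improved <- TRUE
    }
    if (!improved) break
  }
  as.integer(factor(memb))
}

#' Weighted modularity via Louvain with restarts
#'
#' Runs seeded Louvain community detection several times (igraph's
#' implementation visits vertices in random order, so restarts explore
#' different local optima), refines each candidate partition by greedy
#' single-node moves, and returns the best modularity found.
#'
#' @param c [connectome()] or symmetric matrix with nonzero total weight.
#' @param gamma resolution parameter (1 = classic Newman-Girvan).
#' @param n_restarts number of seeded Louvain restarts.
#' @param seed integer seed.
#' @return list with elements `Q` (best modularity) and `membership`
#'   (integer community labels).
#' @export
modularity_louvain <- function(c, gamma = 1, n_restarts = 20L, seed = 1L) {
  w <- as_weights(c)
  if (sum(w) == 0) stop("network has zero total weight")
  g <- as_igraph(w)
  best_q <- -Inf
  best_m <- NULL
  withr_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                    resolution = gamma)
      memb <- igraph::membership(cl)
      qv <- modularity_value(w, memb, gamma)
      if (qv > best_q) { best_q <- qv; best_m <- memb }
    }
    # refinement of the best restart and of an all-singletons start; the
    # aggressive variant (splits and merges) is reserved for small graphs,
    # where the extra moves are what reaches the global optimum
    aggr <- nrow(w) <= 12
    for (start in list(best_m, seq_len(nrow(w)))) {
      memb <- refine_partition(w, start, gamma, aggressive = aggr)
      qv <- modularity_value(w, memb, gamma)
      if (qv > best_q) { best_q <- qv; best_m <- memb }
    }
    # the trivial one-community partition is always a candidate (Q = 0 at
    # gamma 1); guards against splits with negative Q on unstructured graphs
    q1 <- modularity_value(w, rep(1L, nrow(w)), gamma)
    if (q1 > best_q) { best_q <- q1; best_m <- rep(1L, nrow(w)) }
    # on very small graphs an exhaustive depth-2 local search is affordable
    # and escapes the pairwise local optima greedy refinement can settle in:
    # every single-node relocation and every simultaneous two-node
    # relocation is evaluated exactly, the best improvement applied
    if (nrow(w) <= 12) {
      n <- nrow(w)
      # global two-community scan: evaluate every bipartition exactly and
      # refine the best one; deeper partitions are reached by the split and
      # merge lookaheads of the loop below
      best_bi_q <- -Inf
      best_bi <- NULL
      for (code in seq_len(2^(n - 1) - 1)) {
        mm <- 1L + as.integer(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
        qb <- modularity_value(w, mm, gamma)
        if (qb > best_bi_q) { best_bi_q <- qb; best_bi <- mm }
      }
      bi_ref <- refine_partition(w, best_bi, gamma)
      qb <- modularity_value(w, bi_ref, gamma)
      if (qb > best_q) { best_q <- qb; best_m <- bi_ref }
      repeat {
        # best single or simultaneous double relocation, evaluated exactly
        n_comm <- max(best_m)
        targets <- seq_len(min(n_comm + 1L, n))
        moves <- expand.grid(i = seq_len(n), t = targets)
        moves <- moves[best_m[moves$i] != moves$t, , drop = FALSE]
        cand_q <- best_q
        cand_m <- NULL
        for (u in seq_len(nrow(moves))) {
          m1 <- best_m
          m1[moves$i[u]] <- moves$t[u]
          q1 <- modularity_value(w, m1, gamma)
          if (q1 > cand_q + 1e-12) { cand_q <- q1; cand_m <- m1 }
          for (v in seq_len(nrow(moves))) {
            if (v <= u || moves$i[v] == moves$i[u]) next
            m2 <- m1
            m2[moves$i[v]] <- moves$t[v]
            q2 <- modularity_value(w, m2, gamma)
            if (q2 > cand_q + 1e-12) { cand_q <- q2; cand_m <- m2 }
          }
        }
        # merge lookahead: tentatively merge community pairs and refine
        comms <- unique(best_m)
        for (a in comms) for (b in comms) {
          if (a >= b) next
          mm <- best_m
          mm[mm == b] <- a
          mm <- refine_partition(w, mm, gamma)
          qm <- modularity_value(w, mm, gamma)
          if (qm > cand_q + 1e-12) { cand_q <- qm; cand_m <- mm }
        }
        # split lookahead: exhaustively bipartition each community and refine
        for (a in comms) {
          members <- which(best_m == a)
          k <- length(members)
          if (k < 2) next
          new_lab <- max(best_m) + 1L
          for (code in seq_len(2^(k - 1) - 1)) {
            sel <- members[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
            mm <- best_m
            mm[sel] <- new_lab
            mm <- refine_partition(w, mm, gamma)
            qm <- modularity_value(w, mm, gamma)
            if (qm > cand_q + 1e-12) { cand_q <- qm; cand_m <- mm }
          }
        }
        if (is.null(cand_m)) break
        best_q <- cand_q
        best_m <- as.integer(factor(cand_m))
      }
    }
  })
  list(Q = best_q, membership = as.integer(best_m))
}

#' Specification of a metric-normalization null ensemble
#'
#' @param n_nulls number of null networks.
#' @param n_iter_per_edge attempted degree-preserving double-edge swaps per
#'   edge when randomizing the binary topology.
#' @param n_swap_per_edge weight-swap descent proposals per edge when
#'   matching the strength sequence.
#' @param n_swap_cap upper bound on the total number of swap proposals per
#'   surrogate; the descent reaches its quality plateau well below
#'   `n_swap_per_edge * E` on networks with more than ~1000 edges, so the
#'   cap trades no measurable strength accuracy for speed there.
#' @param seed integer seed.
#' @return a list of class `null_spec`.
#' @export
null_spec <- function(n_nulls = 1000L, n_iter_per_edge = 10L,
                      n_swap_per_edge = 50L, n_swap_cap = 25000L,
                      seed = 1L) {
  stopifnot(n_nulls >= 1, n_iter_per_edge >= 1, n_swap_per_edge >= 0)
  structure(list(n_nulls = as.integer(n_nulls),
                 n_iter_per_edge = as.integer(n_iter_per_edge),
                 n_swap_per_edge = as.integer(n_swap_per_edge),
                 n_swap_cap = as.integer(n_swap_cap),
                 seed = as.integer(seed)),
            class = "null_spec")
}

swap_budget <- function(spec, n_edges) {
  min(spec$n_swap_per_edge * n_edges, spec$n_swap_cap)
}

#' Degree-, strength- and weight-preserving null networks
#'
#' Builds randomized surrogates of a weighted network in two steps: (1) the
#' binary topology is randomized by Maslov-Sneppen double-edge swaps, which
#' preserve every node's degree exactly; (2) the original multiset of edge
#' weights is re-assigned to the new edges by sequential rank matching
#' against the residual strength sequence followed by a stochastic weight-swap
#' descent, so the strength sequence is preserved approximately and the
#' weight distribution exactly.
#'
#' @param c [connectome()] or symmetric matrix with at least 2 edges.
#' @param spec a [null_spec()].
#' @return list of `spec$n_nulls` symmetric matrices.
#' @export
null_ensemble <- function(c, spec = null_spec()) {
  w <- as_weights(c)
  n <- nrow(w)
  ut <- upper.tri(w)
  el <- which(ut & w > 0, arr.ind = TRUE)
  if (nrow(el) < 2) stop("need at least 2 edges to randomize")
  storage.mode(el) <- "integer"
  # work on max-normalized weights so the assignment's floating-point
  # decisions, and hence the surrogates, are exactly scale-equivariant
  mx <- max(w)
  weights <- w[el] / mx
  s_target <- rowSums(w) / mx
  n_edges <- nrow(el)
  withr_seed(spec$seed, {
    lapply(seq_len(spec$n_nulls), function(k) {
      el2 <- ms_rewire_cpp(el, n, spec$n_iter_per_edge * n_edges)
      wn <- assign_weights_cpp(el2, weights, s_target, n,
                               swap_budget(spec, n_edges)) * mx
      m <- matrix(0, n, n)
      m[el2] <- wn
      m[el2[, c(2, 1)]] <- wn
      m
    })
  })
}

# fast fused path: efficiency and clustering of spec$n_nulls surrogates,
# computed in compiled code; returns a 2-column matrix
null_metric_samples <- function(w, spec) {
  n <- nrow(w)
  ut <- upper.tri(w)
  el <- which(ut & w > 0, arr.ind = TRUE)
  if (nrow(el) < 2) stop("need at least 2 edges to randomize")
  storage.mode(el) <- "integer"
  mx <- max(w)
  res <- withr_seed(spec$seed,
                    null_metrics_cpp(el, w[el] / mx, rowSums(w) / mx, n,
                                     spec$n_iter_per_edge * nrow(el),
                                     swap_budget(spec, nrow(el)),
                                     spec$n_nulls))
  res[, 1] <- res[, 1] * mx     # efficiency scales with the weights
  res                           # clustering is scale-invariant
}

#' Normalize a metric against a null ensemble
#'
#' @param metric_value observed value.
#' @param null_values vector of the same metric on null networks.
#' @return ratio `metric_value / mean(null_values)`.
#' @export
normalize_metric <- function(metric_value, null_values) {
  if (length(null_values) == 0) stop("null ensemble is empty")
  nm <- mean(null_values)
  if (nm == 0) stop("null mean is zero; normalized metric undefined")
  metric_value / nm
}

#' Global graph parameters of one network, with null normalization
#'
#' Computes q50, raw and null-normalized global efficiency and clustering,
#' and modularity for a single (typically thresholded) network.
#'
#' @param c [connectome()] or symmetric matrix.
#' @param spec [null_spec()] for the normalization ensemble.
#' @param gamma,n_restarts passed to [modularity_louvain()].
#' @return one-row data.frame with columns `q50`, `efficiency_raw`,
#'   `clustering_raw`, `modularity`, `efficiency_norm`, `clustering_norm`.
#' @export
global_metrics <- function(c, spec = null_spec(n_nulls = 100L),
                           gamma = 1, n_restarts = 20L) {
  w <- as_weights(c)
  e_raw <- global_efficiency(w)
  c_raw <- clustering_onnela(w)
  q <- modularity_louvain(w, gamma = gamma, n_restarts = n_restarts,
                          seed = spec$seed)$Q
  nm <- null_metric_samples(w, spec)
  e_null <- nm[, 1]
  c_null <- nm[, 2]
  data.frame(
    q50 = q50(w),
    efficiency_raw = e_raw,
    clustering_raw = c_raw,
    modularity = q,
    efficiency_norm = normalize_metric(e_raw, e_null),
    clustering_norm = normalize_metric(c_raw, c_null)
  )
}

#' Default density grid
#'
#' The 20% to 80% proportional-threshold sweep in steps of 5%.
#' @return numeric vector of 13 densities.
#' @export
default_kappas <- function() seq(0.20, 0.80, by = 0.05)

#' Density sweep of global graph parameters
#'
#' For each density kappa, derives a sparsity mask from the reference network
#' (the healthy group average), applies it to the subject network and computes
#' the global graph parameters with null normalization. Node strengths are
#' computed once at a fixed local-analysis density (default 50%).
#'
#' @param c subject [connectome()].
#' @param reference reference [connectome()] of the same scope and dimension.
#' @param kappas density grid (default [default_kappas()]).
#' @param spec [null_spec()].
#' @param local_kappa density for the node-strength computation.
#' @return list with `global` (data.frame, one row per kappa with a `kappa`
#'   column) and `strength` (numeric vector of node strengths at
#'   `local_kappa`).
#' @export
density_sweep <- function(c, reference, kappas = default_kappas(),
                          spec = null_spec(n_nulls = 100L),
                          local_kappa = 0.5) {
  w <- as_weights(c)
  ref <- as_weights(reference)
  if (!all(dim(w) == dim(ref)))
    stop("reference and subject connectome dimensions differ")
  rows <- lapply(seq_along(kappas), function(i) {
    k <- kappas[i]
    masked <- apply_mask(w, density_mask(ref, k))
    sp_i <- spec
    sp_i$seed <- spec$seed + i
    gm <- global_metrics(masked, spec = sp_i)
    cbind(kappa = k, gm)
  })
  strength <- node_strength(apply_mask(w, density_mask(ref, local_kappa)))
  list(global = do.call(rbind, rows), strength = strength)
}
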