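#' Watts-Strogatz configuration
#'
#' @param n_nodes number of nodes (default 41, one hemisphere's regions).
#' @param k desired mean degree; must be even and < n_nodes (default 10,
#'   matching the average degree of empirical hemispheric networks near
#'   density 0.27).
#' @param rewire_p probability of rewiring each ring-lattice edge into a
#'   random shortcut (default 0.25).
#' @param weight_scheme `"distance_decay"` (weight = 1 / lattice offset of
#'   the slot, shortcuts inherit the weight of the slot they replace) or
#'   `"uniform"` (all weights 1).
#' @param seed integer seed.
#' @return list of class `ws_config`.
#' @export
ws_config <- function(n_nodes = 41L, k = 10L, rewire_p = 0.25,
                      weight_scheme = c("distance_decay", "uniform"),
                      seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  if (k %% 2 != 0 || k >= n_nodes) stop("k must be even and < n_nodes")
  if (rewire_p < 0 || rewire_p > 1) stop("rewire_p must be in [0, 1]")
  structure(list(n_nodes = as.integer(n_nodes), k = as.integer(k),
                 rewire_p = rewire_p, weight_scheme = weight_scheme,
                 seed = as.integer(seed)),
            class = "ws_config")
}

#' Generate one weighted Watts-Strogatz network
#'
#' Builds a ring lattice in which every node connects to its `k/2` nearest
#' neighbours on each side, then visits each lattice edge once and, with
#' probability `rewire_p`, rewires its far endpoint to a uniformly random
#' node that is not already a neighbour (no self-loops, no duplicate edges).
#' Rewiring moves edges but never deletes them, so the edge count is exactly
#' `n k / 2` and the mean degree exactly `k`. Under the default
#' `distance_decay` scheme an edge's weight is the reciprocal of its original
#' lattice offset; a shortcut keeps the weight of the slot it replaced.
#'
#' @param cfg a [ws_config()].
#' @return list of class `ws_network`: `weights` (symmetric matrix),
#'   `edges` (edge list with columns node1, node2, weight, slot_offset),
#'   `cfg`.
#' @export
ws_generate <- function(cfg = ws_config()) {
  n <- cfg$n_nodes; k <- cfg$k
  offsets <- seq_len(k / 2)
  node1 <- rep(seq_len(n), times = length(offsets))
  off <- rep(offsets, each = n)
  node2 <- ((node1 - 1 + off) %% n) + 1
  wgt <- if (cfg$weight_scheme == "distance_decay") 1 / off else rep(1, n * k / 2)
  adj <- matrix(FALSE, n, n)
  adj[cbind(node1, node2)] <- TRUE
  adj <- adj | t(adj)
  withr_seed(cfg$seed, {
    for (e in seq_along(node1)) {
      if (stats::runif(1) < cfg$rewire_p) {
        u <- node1[e]; v <- node2[e]
        candidates <- which(!adj[u, ])
        candidates <- setdiff(candidates, u)
        if (length(candidates) == 0) next
        w_new <- candidates[sample.int(length(candidates), 1)]
        adj[u, v] <- adj[v, u] <- FALSE
        adj[u, w_new] <- adj[w_new, u] <- TRUE
        node2[e] <- w_new
      }
    }
  })
  wm <- matrix(0, n, n)
  wm[cbind(node1, node2)] <- wgt
  wm[cbind(node2, node1)] <- wgt
  structure(list(weights = wm,
                 edges = data.frame(node1 = node1, node2 = node2,
                                    weight = wgt, slot_offset = off),
                 cfg = cfg),
            class = "ws_network")
}

#' Lesion-simulation configuration
#'
#' @param n_intact,n_lesioned arm sizes (defaults 21 and 17, matching the
#'   study's controls and patients).
#' @param q fraction of long-range connections removed (default 0.5).
#' @param long_range_cutoff ring distance beyond which an edge counts as
#'   long-range; default `k/2`, i.e. anything outside the lattice
#'   neighbourhood, which captures rewired shortcuts and nothing of the
#'   untouched lattice.
#' @param n_nulls null-ensemble size for metric normalization.
#' @param seed integer seed.
#' @return list of class `lesion_sim_config`.
#' @export
lesion_sim_config <- function(n_intact = 21L, n_lesioned = 17L, q = 0.5,
                              long_range_cutoff = NULL, n_nulls = 1000L,
                              seed = 1L) {
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  structure(list(n_intact = as.integer(n_intact),
                 n_lesioned = as.integer(n_lesioned), q = q,
                 long_range_cutoff = long_range_cutoff,
                 n_nulls = as.integer(n_nulls), seed = as.integer(seed)),
            class = "lesion_sim_config")
}

# ring distance of every edge's endpoints (realized, so shortcuts count by
# where they actually land)
edge_ring_distance <- function(net) {
  n <- net$cfg$n_nodes
  ring_distance(net$edges$node1, net$edges$node2, n)
}

#' Remove long-range connections from a Watts-Strogatz network
#'
#' Identifies the edges whose realized ring distance exceeds the cutoff and
#' deletes `round(q * count)` of them uniformly at random (round half away
#' from zero). Short-range edges are never touched.
#'
#' @param net a [ws_generate()] network.
#' @param cfg a [lesion_sim_config()].
#' @param seed integer seed for the removal draw.
#' @return a `ws_network` with the surviving edges.
#' @export
lesion_long_range <- function(net, cfg = lesion_sim_config(), seed = 1L) {
  cutoff <- if (is.null(cfg$long_range_cutoff)) net$cfg$k / 2
            else cfg$long_range_cutoff
  d <- edge_ring_distance(net)
  long_idx <- which(d > cutoff)
  if (length(long_idx) == 0) {
    warning("no long-range edges beyond cutoff; returning network unchanged")
    return(net)
  }
  n_remove <- round_half_up(cfg$q * length(long_idx))
  removed <- if (n_remove > 0) {
    withr_seed(seed, sample(long_idx, n_remove))
  } else integer(0)
  keep <- setdiff(seq_len(nrow(net$edges)), removed)
  edges <- net$edges[keep, , drop = FALSE]
  n <- net$cfg$n_nodes
  wm <- matrix(0, n, n)
  wm[cbind(edges$node1, edges$node2)] <- edges$weight
  wm[cbind(edges$node2, edges$node1)] <- edges$weight
  structure(list(weights = wm, edges = edges, cfg = net$cfg),
            class = "ws_network")
}

#' Watts-Strogatz lesion experiment
#'
#' Generates `n_intact + n_lesioned` network realizations, removes a fraction
#' `q` of long-range connections from the lesioned arm, and computes per
#' realization the normalized global efficiency and clustering (against
#' degree-, strength- and weight-preserving nulls) plus modularity. Arms are
#' compared per metric with Welch two-sample t-tests.
#'
#' @param ws a [ws_config()] (its seed field is ignored; per-realization
#'   seeds derive from `seed`).
#' @param lesion a [lesion_sim_config()].
#' @param seed integer master seed.
#' @param n_restarts Louvain restarts for the modularity computation.
#' @return list of class `lesion_sim_result`: `table` (data.frame:
#'   realization, arm, efficiency_norm, clustering_norm, modularity) and
#'   `tests` (data.frame per metric: t, p, direction of the lesioned-arm
#'   mean relative to intact).
#' @export
run_lesion_experiment <- function(ws = ws_config(),
                                  lesion = lesion_sim_config(),
                                  seed = 1L, n_restarts = 20L) {
  n_tot <- lesion$n_intact + lesion$n_lesioned
  arm <- c(rep("intact", lesion$n_intact), rep("lesioned", lesion$n_lesioned))
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    cfg_i <- ws
    cfg_i$seed <- seed + i
    net <- ws_generate(cfg_i)
    if (arm[i] == "lesioned")
      net <- lesion_long_range(net, lesion, seed = seed + 10000L + i)
    w <- net$weights
    nm <- null_metric_samples(w, null_spec(n_nulls = lesion$n_nulls,
                                           seed = seed + 20000L + i))
    e_norm <- normalize_metric(global_efficiency(w), nm[, 1])
    c_norm <- normalize_metric(clustering_onnela(w), nm[, 2])
    qmod <- modularity_louvain(w, n_restarts = n_restarts,
                               seed = seed + 30000L + i)$Q
    rows[[i]] <- data.frame(realization = i, arm = arm[i],
                            efficiency_norm = e_norm,
                            clustering_norm = c_norm, modularity = qmod,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(
    c("efficiency_norm", "clustering_norm", "modularity"), function(mn) {
      a <- tab[[mn]][tab$arm == "lesioned"]
      b <- tab[[mn]][tab$arm == "intact"]
      tt <- stats::t.test(a, b)
      data.frame(metric = mn, t = unname(tt$statistic), p = tt$p.value,
                 lesioned_minus_intact = mean(a) - mean(b),
                 stringsAsFactors = FALSE)
    }))
  structure(list(table = tab, tests = tests, ws = ws, lesion = lesion,
                 seed = seed),
            class = "lesion_sim_result")
}

#' @export
print.lesion_sim_result <- function(x, ...) {
  cat(sprintf("<lesion_sim> %d intact / %d lesioned, q = %.2f\n",
              x$lesion$n_intact, x$lesion$n_lesioned, x$lesion$q))
  print(x$tests, digits = 3)
  invisible(x)
}
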