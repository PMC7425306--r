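# stack a list of connectomes/matrices into a subjects x pairs matrix over
# the upper triangle; returns the pair index alongside
stack_edges <- function(connectomes) {
  mats <- lapply(connectomes, as_weights)
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != n))
    stop("connectomes have mismatched dimensions")
  ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  x <- do.call(rbind, lapply(mats, function(m) m[upper.tri(m)]))
  list(x = x, pairs = ut, n = n)
}

# pooled-variance two-sample t per column (A minus B); zero-variance columns
# get t = 0
edge_t_columns <- function(x, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  ma <- colMeans(x[is_a, , drop = FALSE])
  mb <- colMeans(x[!is_a, , drop = FALSE])
  va <- colSums(sweep(x[is_a, , drop = FALSE], 2, ma)^2)
  vb <- colSums(sweep(x[!is_a, , drop = FALSE], 2, mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  ifelse(se > 0, (ma - mb) / se, 0)
}

#' Edgewise two-sample t-statistic matrix
#'
#' Pooled-variance two-sample t statistic (group A minus group B) for every
#' node pair. Pairs with zero variance across all subjects (including pairs
#' absent everywhere) get 0.
#'
#' @param groupA,groupB lists of [connectome()] objects or matrices sharing
#'   node order; at least two subjects per group.
#' @return symmetric matrix of t values with zero diagonal.
#' @export
edge_t_matrix <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need at least 2 subjects per group")
  st <- stack_edges(c(groupA, groupB))
  is_a <- c(rep(TRUE, length(groupA)), rep(FALSE, length(groupB)))
  tv <- edge_t_columns(st$x, is_a)
  tm <- matrix(0, st$n, st$n)
  tm[st$pairs] <- tv
  tm + t(tm)
}

# max component extent (edge count) among supra-threshold edges, fast path
max_component_extent <- function(pairs_idx, pairs) {
  if (length(pairs_idx) == 0) return(0L)
  el <- pairs[pairs_idx, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(g)$membership
  max(as.integer(table(comp[el[, 1]])))
}

#' Connected components of supra-threshold edges
#'
#' Binarizes the edgewise statistic at a threshold in the requested
#' direction (`"A>B"` keeps t > threshold, `"A<B"` keeps t < -threshold) and
#' returns the connected components of the surviving edges, largest first.
#'
#' @param t_matrix symmetric t matrix from [edge_t_matrix()].
#' @param t_threshold positive primary threshold.
#' @param direction `"A<B"` (deficit in A) or `"A>B"`.
#' @return list of components; each has `edges` (two-column matrix of node
#'   indices) and `extent` (edge count). Empty list if nothing survives.
#' @export
supra_threshold_components <- function(t_matrix, t_threshold,
                                       direction = c("A<B", "A>B")) {
  direction <- match.arg(direction)
  ut <- which(upper.tri(t_matrix), arr.ind = TRUE)
  tv <- t_matrix[upper.tri(t_matrix)]
  hit <- if (direction == "A>B") tv > t_threshold else tv < -t_threshold
  if (!any(hit)) return(list())
  el <- ut[hit, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[el[, 1]]
  comps <- lapply(unique(comp_of_edge), function(cc) {
    e <- el[comp_of_edge == cc, , drop = FALSE]
    dimnames(e) <- list(NULL, c("node1", "node2"))
    list(edges = e, extent = nrow(e))
  })
  comps[order(-vapply(comps, function(cp) cp$extent, numeric(1)))]
}

#' Network-based statistic (NBS)
#'
#' Two-step cluster-based inference on edgewise connectivity: edges whose
#' two-sample t statistic exceeds a primary threshold are kept and their
#' connected components measured by extent (edge count); the family-wise
#' error of each observed component is the proportion of group-label
#' permutations whose maximal component extent is at least as large
#' (add-one correction).
#'
#' @param groupA,groupB lists of connectomes/matrices (A = patients for a
#'   deficit contrast).
#' @param t_threshold primary threshold (default 3.1).
#' @param direction `"A<B"` for a deficit in group A, or `"A>B"`.
#' @param n_perm number of permutations.
#' @param alpha reporting level (stored, not used to truncate output).
#' @param seed integer seed.
#' @return list of class `nbs_result`: `components` (each with `edges`,
#'   `extent`, `fwer_p`), `t_threshold`, `direction`, `null_max_extent`
#'   (vector), `edgewise_p` (informational two-sided tail of the t
#'   distribution at the threshold).
#' @export
nbs_test <- function(groupA, groupB, t_threshold = 3.1,
                     direction = c("A<B", "A>B"), n_perm = 5000L,
                     alpha = 0.05, seed = 1L) {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("n_perm must be positive")
  if (n_perm < 100) warning("n_perm < 100 gives unstable FWER estimates")
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need at least 2 subjects per group")
  st <- stack_edges(c(groupA, groupB))
  n_a <- length(groupA)
  n_tot <- n_a + length(groupB)
  is_a <- c(rep(TRUE, n_a), rep(FALSE, n_tot - n_a))
  # drop zero-variance edges from testing
  keep <- apply(st$x, 2, stats::var) > 0
  x <- st$x[, keep, drop = FALSE]
  pairs <- st$pairs[keep, , drop = FALSE]
  sgn <- if (direction == "A>B") 1 else -1
  tv <- edge_t_columns(x, is_a)
  comps <- supra_threshold_components({
    tm <- matrix(0, st$n, st$n); tm[pairs] <- tv; tm + t(tm)
  }, t_threshold, direction)
  null_max <- integer(n_perm)
  withr_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm_a <- is_a[sample.int(n_tot)]
      tp <- edge_t_columns(x, perm_a)
      hit <- which(sgn * tp > t_threshold)
      null_max[p] <- max_component_extent(hit, pairs)
    }
  })
  components <- lapply(comps, function(cp) {
    cp$fwer_p <- (sum(null_max >= cp$extent) + 1) / (n_perm + 1)
    cp
  })
  df2 <- n_tot - 2
  structure(list(components = components, t_threshold = t_threshold,
                 direction = direction, null_max_extent = null_max,
                 n_perm = n_perm, alpha = alpha,
                 edgewise_p = 2 * stats::pt(-abs(t_threshold), df2)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs> t > %.2f (%s), %d component(s)\n", x$t_threshold,
              x$direction, length(x$components)))
  for (cp in x$components)
    cat(sprintf("  extent %d edges, FWER p = %.4f\n", cp$extent, cp$fwer_p))
  invisible(x)
}

#' NBS over a range of primary thresholds
#'
#' Runs [nbs_test()] for each threshold and reports the threshold that
#' maximizes the statistical significance of the largest component (smallest
#' FWER p; ties broken toward the larger, more conservative threshold).
#'
#' @inheritParams nbs_test
#' @param thresholds vector of primary thresholds (default 1 to 5 by 0.1).
#' @return list with `summary` (data.frame: threshold, max extent, fwer_p),
#'   `best_threshold` and `best` (the `nbs_result` at the best threshold).
#' @export
nbs_threshold_sweep <- function(groupA, groupB,
                                thresholds = seq(1, 5, by = 0.1),
                                direction = c("A<B", "A>B"),
                                n_perm = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  runs <- lapply(thresholds, function(th)
    nbs_test(groupA, groupB, t_threshold = th, direction = direction,
             n_perm = n_perm, seed = seed))
  summ <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    data.frame(threshold = thresholds[i],
               max_extent = if (length(r$components)) r$components[[1]]$extent
                            else 0L,
               fwer_p = if (length(r$components)) r$components[[1]]$fwer_p
                        else NA_real_)
  }))
  cand <- which(!is.na(summ$fwer_p))
  best_i <- if (length(cand)) {
    pmin_ <- min(summ$fwer_p[cand])
    max(cand[summ$fwer_p[cand] == pmin_])  # ties -> larger threshold
  } else length(thresholds)
  list(summary = summ, best_threshold = thresholds[best_i],
       best = runs[[best_i]])
}
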