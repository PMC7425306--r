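#' Weighted structural connectome
#'
#' A connectome couples a symmetric, nonnegative, zero-diagonal weight matrix
#' with its node table and a scope flag saying whether it covers the whole
#' brain (82 nodes) or a single hemisphere (41 nodes).
#'
#' @param weights symmetric numeric matrix, zero diagonal.
#' @param nodes data.frame of node metadata (one row per matrix row), as
#'   produced by [make_parcellation()] or a hemispheric subset of it.
#' @param scope one of `"whole_brain"`, `"left_hemisphere"`,
#'   `"right_hemisphere"`.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, nodes, scope = c("whole_brain",
                                                 "left_hemisphere",
                                                 "right_hemisphere")) {
  scope <- match.arg(scope)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  if (!is.null(nodes) && nrow(nodes) != nrow(weights))
    stop("node table does not match matrix dimension")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 0)
    stop("weights must be exactly symmetric; use symmetrize() first")
  diag(weights) <- 0
  dimnames(weights) <- NULL
  structure(list(weights = weights, nodes = nodes, scope = scope),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %s, %d nodes, %d/%d nonzero pairs (density %.3f)\n",
              x$scope, n, nz, n * (n - 1) / 2, nz / (n * (n - 1) / 2)))
  invisible(x)
}

#' Extract the weight matrix
#'
#' Returns the plain numeric weight matrix of a [connectome()], or coerces
#' any matrix-like input.
#'
#' @param x a `connectome` or matrix.
#' @return numeric matrix.
#' @export
as_weights <- function(x) {
  if (inherits(x, "connectome")) x$weights else as.matrix(x)
}

#' Symmetrize a square matrix
#'
#' Averages a matrix with its own transpose. Idempotent; leaves symmetric
#' input unchanged.
#'
#' @param raw square numeric matrix.
#' @return symmetric matrix `(raw + t(raw)) / 2`.
#' @export
symmetrize <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("input must be a square matrix")
  (raw + t(raw)) / 2
}

#' Volume-normalized connection weights from streamline counts
#'
#' Converts a symmetric streamline-count matrix into connection weights by
#' dividing each count by the summed volumes of the two endpoint regions:
#' `w(s, t) = counts(s, t) / (volume(s) + volume(t))`. The diagonal is zeroed.
#'
#' @param counts symmetric nonnegative matrix of streamline counts.
#' @param volumes positive numeric vector of node volumes (mm^3), one per row.
#' @param nodes optional node table to attach.
#' @param scope scope flag for the resulting connectome.
#' @return a [connectome()].
#' @export
weights_from_counts <- function(counts, volumes, nodes = NULL,
                                scope = "whole_brain") {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (length(volumes) != nrow(counts))
    stop("volumes length must match matrix dimension")
  if (any(volumes <= 0)) stop("volumes must be positive")
  if (max(abs(counts - t(counts))) > 0)
    stop("counts must be symmetric; symmetrize() them first")
  denom <- outer(volumes, volumes, `+`)
  w <- counts / denom
  diag(w) <- 0
  connectome(w, nodes, scope)
}

#' Element-wise average of a set of connectomes
#'
#' @param connectomes non-empty list of [connectome()] objects sharing node
#'   order and scope.
#' @return the group-average [connectome()].
#' @export
group_average <- function(connectomes) {
  if (length(connectomes) == 0) stop("need at least one connectome")
  scopes <- vapply(connectomes, function(c) c$scope, character(1))
  if (length(unique(scopes)) != 1) stop("connectomes have mismatched scopes")
  mats <- lapply(connectomes, as_weights)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1) stop("connectomes have mismatched dimensions")
  avg <- Reduce(`+`, mats) / length(mats)
  connectome(avg, connectomes[[1]]$nodes, scopes[1])
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Proportional-threshold sparsity mask from a reference network
#'
#' Ranks the off-diagonal node pairs of a reference network (the healthy
#' group average, in the intended use) by weight and retains exactly
#' `round(kappa * P)` strongest pairs, where `P = n(n-1)/2`. Ties are broken
#' deterministically by (row, column) order so that masks from one reference
#' are nested across densities. The count is rounded half away from zero.
#'
#' @param reference [connectome()] or symmetric matrix to rank.
#' @param kappa target density in (0, 1].
#' @return binary symmetric matrix of class `sparsity_mask` with attribute
#'   `density = kappa`.
#' @export
density_mask <- function(reference, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0 || kappa > 1)
    stop("kappa must be a single value in (0, 1]")
  w <- as_weights(reference)
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[upper.tri(w)]
  keep_n <- round_half_up(kappa * nrow(ut))
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(keep_n)]
  mask <- matrix(0, n, n)
  mask[ut[keep, , drop = FALSE]] <- 1
  mask <- mask + t(mask)
  structure(mask, class = c("sparsity_mask", class(mask)), density = kappa)
}

#' Apply a sparsity mask to a connectome
#'
#' @param c a [connectome()] or matrix.
#' @param m binary mask from [density_mask()].
#' @return object of the same kind as `c` with weights outside the mask zeroed.
#' @export
apply_mask <- function(c, m) {
  w <- as_weights(c)
  if (!all(dim(w) == dim(m))) stop("mask dimension does not match connectome")
  masked <- w * unclass(m)
  if (inherits(c, "connectome")) connectome(masked, c$nodes, c$scope) else masked
}

#' Extract one hemisphere's intrahemispheric network
#'
#' Takes the 41x41 principal submatrix over the nodes of one hemisphere,
#' preserving node order; this drops all interhemispheric (transcallosal)
#' connections, mirroring intrahemispheric tracking with a midline exclusion.
#'
#' @param c whole-brain [connectome()].
#' @param side `"left"` or `"right"`.
#' @return hemispheric [connectome()].
#' @export
hemisphere_submatrix <- function(c, side = c("left", "right")) {
  side <- match.arg(side)
  if (!inherits(c, "connectome") || c$scope != "whole_brain")
    stop("hemisphere_submatrix() needs a whole-brain connectome")
  idx <- hemisphere_index(c$nodes, side)
  connectome(c$weights[idx, idx], c$nodes[idx, , drop = FALSE],
             paste0(side, "_hemisphere"))
}

#' Read / write a connectivity matrix as headerless CSV
#'
#' Matrices are written with full precision (decimal text) so that a write
#' followed by a read reproduces the numbers exactly.
#'
#' @param w matrix or [connectome()].
#' @param path file path.
#' @return `read_matrix_csv` returns a plain numeric matrix.
#' @export
write_matrix_csv <- function(w, path) {
  w <- as_weights(w)
  lines <- apply(w, 1L, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
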