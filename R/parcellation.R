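#' Desikan-Killiany cortical region names
#'
#' The 34 cortical labels of the FreeSurfer Desikan-Killiany atlas, used as
#' the per-hemisphere cortical parcellation of the synthetic connectomes.
#' @keywords internal
dk_cortical_names <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
    "insula")
}

#' Subcortical region names
#' @keywords internal
subcortical_names <- function() {
  c("thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala")
}

#' Build the default 82-node parcellation
#'
#' Creates a symmetric two-hemisphere parcellation with 41 nodes per
#' hemisphere: the 34 Desikan-Killiany cortical regions, six subcortical
#' grey-matter nuclei and one brainstem-level node carrying the descending
#' motor tracts. Each hemisphere lists the same region-name sequence, so
#' homotopic pairs line up by index. Region volumes (mm^3) are drawn from
#' log-normal distributions (larger for cortical than subcortical regions)
#' under the given seed, and are identical across hemispheres only by chance
#' -- each node gets its own draw.
#'
#' @param seed integer seed for the volume draws.
#' @return A data.frame with one row per node and columns \code{name},
#'   \code{hemisphere} (\code{"left"}/\code{"right"}), \code{class}
#'   (\code{"cortical"}, \code{"subcortical"}, \code{"brainstem"}) and
#'   \code{volume_mm3}. Left-hemisphere nodes come first; 82 rows in total.
#' @examples
#' parc <- make_parcellation(seed = 1)
#' table(parc$hemisphere)
#' @export
make_parcellation <- function(seed = 1L) {
  cort <- dk_cortical_names()
  sub <- subcortical_names()
  region <- c(cort, sub, "brainstem")
  cls <- c(rep("cortical", length(cort)), rep("subcortical", length(sub)),
           "brainstem")
  stopifnot(length(region) == 41L)
  out <- data.frame(
    name = rep(region, 2L),
    hemisphere = rep(c("left", "right"), each = length(region)),
    class = rep(cls, 2L),
    stringsAsFactors = FALSE
  )
  withr_seed(seed, {
    meanlog <- ifelse(out$class == "cortical", log(9000),
                      ifelse(out$class == "subcortical", log(3500), log(2500)))
    out$volume_mm3 <- stats::rlnorm(nrow(out), meanlog = meanlog, sdlog = 0.35)
  })
  out
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Node indices of one hemisphere
#' @param parc parcellation data.frame from [make_parcellation()].
#' @param side `"left"` or `"right"`.
#' @return integer vector of row indices.
#' @keywords internal
hemisphere_index <- function(parc, side) {
  side <- match.arg(side, c("left", "right"))
  which(parc$hemisphere == side)
}
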