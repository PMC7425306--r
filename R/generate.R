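#' Lesion specification for the synthetic cohort generator
#'
#' Describes a planted subcortical-type lesion: a set of target regions on
#' the lesioned side whose connections are attenuated strongly, a milder
#' diffuse attenuation of the remaining ipsilesional connections, a still
#' milder contralesional attenuation, and an extra attenuation of the longest
#' tercile of ipsilesional connections (emulating preferential damage to
#' long-range fibre tracts).
#'
#' Attenuation factors multiply streamline counts; 1 means no effect. The
#' default values were fixed once by calibration simulations (see the
#' package vignette) so that a default cohort shows a clearly detectable
#' ipsilesional deficit at n = 17 vs 21.
#'
#' @param side `"left"` or `"right"`.
#' @param target_regions region names taking the full ipsilesional hit;
#'   defaults to a cortico-subcortical motor set.
#' @param ipsilesional_attenuation factor for edges incident to target
#'   regions on the lesioned side.
#' @param ipsilesional_background_attenuation milder factor for all other
#'   ipsilesional edges.
#' @param contralesional_attenuation factor for contralesional
#'   intrahemispheric edges; must be >= `ipsilesional_attenuation`.
#' @param long_range_extra_attenuation additional factor applied to the
#'   longest tercile (by ring embedding distance) of ipsilesional edges.
#' @param noise_sd sdlog of the multiplicative log-normal noise (mean 1)
#'   applied after attenuation; 0 disables noise.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(side = "left",
                        target_regions = c("precentral", "postcentral",
                                           "superiorparietal",
                                           "superiortemporal", "insula",
                                           "caudate", "putamen", "pallidum",
                                           "thalamus"),
                        ipsilesional_attenuation = 0.45,
                        ipsilesional_background_attenuation = 0.80,
                        contralesional_attenuation = 0.92,
                        long_range_extra_attenuation = 0.75,
                        noise_sd = 0.1) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(ipsilesional_attenuation > 0, ipsilesional_attenuation <= 1,
            contralesional_attenuation > 0, contralesional_attenuation <= 1,
            long_range_extra_attenuation > 0,
            long_range_extra_attenuation <= 1,
            ipsilesional_background_attenuation > 0,
            ipsilesional_background_attenuation <= 1,
            noise_sd >= 0)
  if (contralesional_attenuation < ipsilesional_attenuation)
    stop("contralesional attenuation must be milder (>=) than ipsilesional")
  structure(list(side = side,
                 target_regions = target_regions,
                 ipsilesional_attenuation = ipsilesional_attenuation,
                 ipsilesional_background_attenuation =
                   ipsilesional_background_attenuation,
                 contralesional_attenuation = contralesional_attenuation,
                 long_range_extra_attenuation = long_range_extra_attenuation,
                 noise_sd = noise_sd),
            class = "lesion_spec")
}

# ring distance between within-hemisphere node positions 1..n on a cycle
ring_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# expected streamline-count profile between two within-hemisphere positions:
# exponential decay with ring distance (lattice part), a same-module bonus
# (4 contiguous modules), a weak background, and a hub profile for the
# subcortical nuclei, whose projections (thalamo-cortical, striato-cortical)
# reach the whole hemisphere regardless of embedding distance
healthy_mu_intra <- function(n_per_hemi = 41L, base = 120, decay = 4,
                             modular = 15, background = 0.5,
                             hub_idx = integer(0), hub_strength = 35) {
  pos <- seq_len(n_per_hemi)
  d <- outer(pos, pos, ring_distance, n = n_per_hemi)
  module <- ceiling(pos / ceiling(n_per_hemi / 4))
  same_mod <- outer(module, module, `==`)
  mu <- base * exp(-d / decay) + modular * same_mod + background
  if (length(hub_idx) > 0) {
    mu[hub_idx, ] <- mu[hub_idx, ] + hub_strength
    mu[, hub_idx] <- mu[, hub_idx] + hub_strength
  }
  diag(mu) <- 0
  mu
}

# expected interhemispheric profile: strong homotopic connections, weak
# elsewhere with mild distance decay between ring positions
healthy_mu_inter <- function(n_per_hemi = 41L, homotopic = 60,
                             base = 2, decay = 4, background = 0.2) {
  pos <- seq_len(n_per_hemi)
  d <- outer(pos, pos, ring_distance, n = n_per_hemi)
  mu <- base * exp(-d / decay) + background
  diag(mu) <- homotopic
  mu
}

#' Sample a healthy whole-brain streamline-count matrix
#'
#' Draws one subject's symmetric 82x82 count matrix. Nodes of each hemisphere
#' are embedded on a ring (in node-table order); expected counts decay with
#' ring distance and carry a modular same-block bonus, producing small-world,
#' modular networks. Homotopic interhemispheric connections are strongest.
#' Counts are negative binomial around the expected profile (dispersion such
#' that `var = mu + mu^2 / nb_size`).
#'
#' @param parc parcellation from [make_parcellation()].
#' @param seed integer seed.
#' @param nb_size negative-binomial size parameter (smaller = more
#'   overdispersed); default 2 corresponds to a quadratic overdispersion
#'   coefficient of 0.5.
#' @return symmetric nonnegative integer matrix, zero diagonal.
#' @export
sample_healthy_counts <- function(parc, seed = 1L, nb_size = 2) {
  n_h <- sum(parc$hemisphere == "left")
  n <- nrow(parc)
  stopifnot(n == 2L * n_h)
  mu <- matrix(0, n, n)
  li <- hemisphere_index(parc, "left")
  ri <- hemisphere_index(parc, "right")
  hub_idx <- which(parc$class[li] == "subcortical")
  intra <- healthy_mu_intra(n_h, hub_idx = hub_idx)
  mu[li, li] <- intra
  mu[ri, ri] <- intra
  mu[li, ri] <- healthy_mu_inter(n_h)
  mu[ri, li] <- t(mu[li, ri])
  ut <- upper.tri(mu)
  counts <- matrix(0, n, n)
  withr_seed(seed, {
    counts[ut] <- stats::rnbinom(sum(ut), mu = mu[ut], size = nb_size)
  })
  counts + t(counts)
}

# per-node ring position within its own hemisphere (1..41)
ring_positions <- function(parc) {
  pos <- integer(nrow(parc))
  for (side in c("left", "right")) {
    idx <- hemisphere_index(parc, side)
    pos[idx] <- seq_along(idx)
  }
  pos
}

#' Plant a lesion into a healthy count matrix
#'
#' Applies the attenuation factors of a [lesion_spec()] to a symmetric count
#' matrix: edges incident to target regions on the lesioned side get the full
#' ipsilesional attenuation; other ipsilesional intrahemispheric edges the
#' milder background factor; contralesional intrahemispheric edges the
#' contralesional factor; interhemispheric edges are treated like the
#' ipsilesional class of their lesioned-side endpoint (target vs background).
#' The longest tercile of ipsilesional intrahemispheric edges (by ring
#' embedding distance) is additionally multiplied by the long-range factor.
#' Finally, mean-one multiplicative log-normal noise is added (seeded) and
#' the matrix re-symmetrized.
#'
#' @param counts symmetric count matrix from [sample_healthy_counts()].
#' @param parc parcellation.
#' @param spec [lesion_spec()].
#' @param seed integer seed for the noise.
#' @return symmetric nonnegative matrix (no longer integer).
#' @export
apply_synthetic_lesion <- function(counts, parc, spec, seed = 1L) {
  counts <- as.matrix(counts)
  if (max(abs(counts - t(counts))) > 0) stop("counts must be symmetric")
  if (!spec$side %in% c("left", "right")) stop("lesion side must be left/right")
  n <- nrow(counts)
  ipsi <- hemisphere_index(parc, spec$side)
  contra <- hemisphere_index(parc, setdiff(c("left", "right"), spec$side))
  target <- which(parc$hemisphere == spec$side &
                    parc$name %in% spec$target_regions)
  fac <- matrix(1, n, n)
  # ipsilesional intrahemispheric edges
  fac[ipsi, ipsi] <- spec$ipsilesional_background_attenuation
  fac[target, ipsi] <- spec$ipsilesional_attenuation
  fac[ipsi, target] <- spec$ipsilesional_attenuation
  # contralesional intrahemispheric edges
  fac[contra, contra] <- spec$contralesional_attenuation
  # interhemispheric edges follow the lesioned-side endpoint's class
  fac[ipsi, contra] <- spec$ipsilesional_background_attenuation
  fac[contra, ipsi] <- spec$ipsilesional_background_attenuation
  fac[target, contra] <- spec$ipsilesional_attenuation
  fac[contra, target] <- spec$ipsilesional_attenuation
  # extra attenuation of the longest tercile of ipsilesional edges
  pos <- ring_positions(parc)
  n_h <- length(ipsi)
  dmat <- outer(pos, pos, ring_distance, n = n_h)
  ipsi_pair <- matrix(FALSE, n, n)
  ipsi_pair[ipsi, ipsi] <- TRUE
  ut <- upper.tri(counts)
  ip_ut <- which(ut & ipsi_pair)
  cutoff <- stats::quantile(dmat[ip_ut], 2 / 3, names = FALSE)
  long <- ut & ipsi_pair & dmat > cutoff
  fac[long | t(long)] <- fac[long | t(long)] * spec$long_range_extra_attenuation
  out <- counts * fac
  if (spec$noise_sd > 0) {
    noise <- matrix(1, n, n)
    withr_seed(seed, {
      noise[ut] <- stats::rlnorm(sum(ut),
                                 meanlog = -spec$noise_sd^2 / 2,
                                 sdlog = spec$noise_sd)
    })
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    out <- out * noise
  }
  diag(out) <- 0
  symmetrize(out)
}

#' Sample a full synthetic cohort
#'
#' Generates a study cohort: healthy-count connectomes for every subject,
#' planted lesions for the patients (left-sided in `n_left_lesions` of them),
#' and clinical scores. Patient grip-strength deficit is log-normal with a
#' standardized effect near Cohen's d = 1 versus zero; the upper-extremity
#' Fugl-Meyer score (UEFM, max 66) is concentrated near ceiling. A per-patient
#' lesion severity in (0, 1) scales the target attenuation; its correlation
#' with the grip deficit is `severity_score_r` (default 0: structural damage
#' and clinical score are unrelated, the study's null clinical association).
#'
#' All randomness derives from `seed` via documented per-subject offsets, so
#' a fixed seed reproduces the cohort bit for bit.
#'
#' @param n_patients,n_controls,n_left_lesions cohort composition.
#' @param seed integer master seed.
#' @param lesion baseline [lesion_spec()] (its `side` field is overridden
#'   per patient).
#' @param severity_score_r correlation between lesion severity and grip
#'   deficit, in [-1, 1].
#' @param subject_scale_sd sdlog of a per-subject global log-normal scaling
#'   of all counts (emulating between-subject differences in overall
#'   streamline yield); applied to patients and controls alike.
#' @return list of class `cohort` with elements `parcellation`, `subjects`
#'   (data.frame), `counts` (named list of matrices) and `params`.
#' @export
sample_cohort <- function(n_patients = 17L, n_controls = 21L,
                          n_left_lesions = 8L, seed = 1L,
                          lesion = lesion_spec(),
                          severity_score_r = 0,
                          subject_scale_sd = 0.12) {
  if (n_left_lesions > n_patients)
    stop("n_left_lesions cannot exceed n_patients")
  n_tot <- n_patients + n_controls
  parc <- make_parcellation(seed = seed)
  ids <- sprintf("S%02d", seq_len(n_tot))
  group <- c(rep("patient", n_patients), rep("control", n_controls))
  side <- rep(NA_character_, n_tot)
  if (n_patients > 0)
    side[seq_len(n_patients)] <- c(rep("left", n_left_lesions),
                                   rep("right", n_patients - n_left_lesions))

  # clinical scores and lesion severity (Gaussian copula for the coupling)
  severity <- rep(NA_real_, n_tot)
  grip <- numeric(n_tot)
  uefm <- rep(66L, n_tot)
  withr_seed(seed + 900L, {
    if (n_patients > 0) {
      z1 <- stats::rnorm(n_patients)
      z2 <- stats::rnorm(n_patients)
      severity[seq_len(n_patients)] <- stats::pnorm(z1)
      u <- stats::pnorm(severity_score_r * z1 +
                          sqrt(1 - severity_score_r^2) * z2)
      grip[seq_len(n_patients)] <- stats::qlnorm(u, meanlog = log(7),
                                                 sdlog = 0.8)
      at_ceiling <- stats::runif(n_patients) < 0.55
      drop <- 1L + stats::rnbinom(n_patients, size = 2, mu = 5)
      uefm[seq_len(n_patients)] <- ifelse(at_ceiling, 66L,
                                          pmax(0L, 66L - drop))
    }
    if (n_controls > 0)
      grip[n_patients + seq_len(n_controls)] <-
        abs(stats::rnorm(n_controls, 0, 1.5))
  })

  counts <- vector("list", n_tot)
  names(counts) <- ids
  scale_i <- withr_seed(seed + 800L,
                        stats::rlnorm(n_tot, 0, subject_scale_sd))
  for (i in seq_len(n_tot)) {
    healthy <- sample_healthy_counts(parc, seed = seed + i) * scale_i[i]
    if (group[i] == "patient") {
      sev <- severity[i]
      sp <- lesion
      sp$side <- side[i]
      # severity in (0,1) scales the target *deficit* (1 - attenuation), so
      # a unit attenuation factor stays the identity for every severity
      sp$ipsilesional_attenuation <-
        max(0, 1 - (1 - lesion$ipsilesional_attenuation) * (0.4 + 1.2 * sev))
      counts[[i]] <- apply_synthetic_lesion(healthy, parc, sp,
                                            seed = seed + 1000L + i)
    } else {
      counts[[i]] <- healthy
    }
  }
  subjects <- data.frame(id = ids, group = group, lesion_side = side,
                         grip_delta_kg = grip, uefm = uefm,
                         severity = severity, stringsAsFactors = FALSE)
  structure(list(parcellation = parc, subjects = subjects, counts = counts,
                 params = list(seed = seed, n_patients = n_patients,
                               n_controls = n_controls,
                               n_left_lesions = n_left_lesions,
                               lesion = unclass(lesion),
                               severity_score_r = severity_score_r,
                               subject_scale_sd = subject_scale_sd)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d patients / %d controls), %d nodes\n",
              nrow(x$subjects), sum(x$subjects$group == "patient"),
              sum(x$subjects$group == "control"), nrow(x$parcellation)))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' Writes one headerless matrix CSV per subject (`counts_<id>.csv`, row order
#' = node order), `nodes.tsv`, `subjects.tsv` and `manifest.json` (seed and
#' generator parameters). `read_cohort()` reads the set back losslessly.
#'
#' @param cohort a [sample_cohort()] result.
#' @param directory output directory (created if missing).
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns a `cohort` object.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$counts))
    write_matrix_csv(cohort$counts[[id]],
                     file.path(directory, paste0("counts_", id, ".csv")))
  parc <- cohort$parcellation
  utils::write.table(parc, file.path(directory, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$subjects, file.path(directory, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$params, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  parc <- utils::read.delim(file.path(directory, "nodes.tsv"),
                            stringsAsFactors = FALSE)
  subjects <- utils::read.delim(file.path(directory, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  subjects$lesion_side <- as.character(subjects$lesion_side)
  params <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                simplifyVector = TRUE)
  counts <- lapply(subjects$id, function(id)
    read_matrix_csv(file.path(directory, paste0("counts_", id, ".csv"))))
  names(counts) <- subjects$id
  structure(list(parcellation = parc, subjects = subjects, counts = counts,
                 params = params),
            class = "cohort")
}
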