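#' Planted community structure of the 16 areas
#'
#' Two nested partitions used by the default coupling spec: a coarse 3-group
#' level (occipital; ventral temporal; dorsal + MT cluster) and a finer
#' 5-group level (posterior occipital; anterior occipital; inferotemporal;
#' MT cluster; dorsal/parietal).
#'
#' @param level `"three"` or `"five"`.
#' @return Named list of character vectors of area labels.
#' @export
planted_communities <- function(level = c("three", "five")) {
  level <- match.arg(level)
  if (level == "three") {
    list(occipital = c("V1", "V2", "V3"),
         ventral   = c("V4", "V4A", "OTd", "PITv", "PITd", "OTS"),
         dorsal    = c("V3A/DP", "CIP", "LIP", "MT", "MST", "FST", "V4t"))
  } else {
    list(post_occipital = c("V1", "V2", "V3"),
         ant_occipital  = c("V4", "V4A", "OTd"),
         inferotemporal = c("PITd", "PITv", "OTS"),
         mt_cluster     = c("MT", "MST", "FST", "V4t"),
         dorsal         = c("V3A/DP", "CIP", "LIP"))
  }
}

#' Latent coupling specification for the rest-data generator
#'
#' Builds the covariance of the latent signals assigned to every
#' (hemisphere, area, quadrant, eccentricity-band) cell. The correlation
#' between two cells is the product of four factors: an area-level template
#' (1 on the diagonal; `adjacent_r` for cortical neighbors; a community value
#' for areas sharing a planted group; `distal_r` otherwise, taking the largest
#' applicable value), a quadrant factor (`quadrant_mismatch` when both cells
#' carry quadrant labels that disagree), an eccentricity factor
#' `exp(-(db)^2 / (2 * gradient_width^2))` in band units, and a hemisphere
#' factor (`homotopic_gain` for cross-hemisphere pairs, so 0 decouples the
#' hemispheres entirely). The resulting matrix is projected to the nearest
#' positive-semidefinite correlation matrix by eigenvalue clipping.
#'
#' @param n_ecc_bands Eccentricity bands (must match the parcellation).
#' @param homotopic_gain Cross-hemisphere attenuation in `[0, 1]`; 0 yields
#'   independent hemispheres.
#' @param adjacent_r Latent correlation between cortical neighbors.
#' @param communities List of community levels, each
#'   `list(groups = <named list of areas>, r = <within-group correlation>)`.
#'   Defaults to the nested five-in-three structure of
#'   [planted_communities()].
#' @param distal_r Baseline latent correlation between unrelated areas.
#' @param quadrant_mismatch Multiplier applied when dorsal meets ventral.
#' @param gradient_width Eccentricity coupling falloff, in bands.
#' @param noise_sd White-noise standard deviation added per voxel (latents
#'   have unit variance).
#' @param ar1 AR(1) coefficient applied to latents and noise (0 = white).
#' @param smooth_fwhm_mm Optional spatial Gaussian smoothing FWHM (0 = none).
#' @param adjacency Area adjacency table, see [default_area_adjacency()].
#' @param area_r Optional 16 x 16 area-level correlation template replacing
#'   the adjacency/community construction (e.g.,
#'   [hierarchy_area_template()]); quadrant, eccentricity, and hemisphere
#'   factors still apply.
#' @param latent_cov Optional full covariance override (cells in
#'   [latent_cell_table()] order). Must be symmetric positive-semidefinite
#'   with strictly positive diagonal.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_ecc_bands = 8,
                          homotopic_gain = 0.9,
                          adjacent_r = 0.5,
                          communities = list(
                            list(groups = planted_communities("five"), r = 0.45),
                            list(groups = planted_communities("three"), r = 0.30)),
                          distal_r = 0.1,
                          quadrant_mismatch = 0.6,
                          gradient_width = 1.5,
                          noise_sd = 1,
                          ar1 = 0.3,
                          smooth_fwhm_mm = 0,
                          adjacency = default_area_adjacency(),
                          area_r = NULL,
                          latent_cov = NULL) {
  if (homotopic_gain < 0) abort("homotopic_gain must be >= 0")
  if (gradient_width <= 0) abort("gradient_width must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  cells <- latent_cell_table(n_ecc_bands)

  if (is.null(latent_cov)) {
    areaR <- area_r %||%
      area_template(adjacent_r, communities, distal_r, adjacency)
    if (!identical(dim(areaR), c(16L, 16L))) {
      abort("area_r must be a 16 x 16 area template")
    }
    latent_cov <- cell_covariance(cells, areaR, quadrant_mismatch,
                                  gradient_width, homotopic_gain)
    latent_cov <- nearest_psd_corr(latent_cov)
  } else {
    latent_cov <- as.matrix(latent_cov)
    if (nrow(latent_cov) != nrow(cells) || ncol(latent_cov) != nrow(cells)) {
      abort(sprintf("latent_cov must be %d x %d for %d eccentricity bands",
                    nrow(cells), nrow(cells), n_ecc_bands))
    }
    if (max(abs(latent_cov - t(latent_cov))) > 1e-8) {
      abort("latent_cov must be symmetric")
    }
    if (any(diag(latent_cov) <= 0)) {
      abort("latent_cov diagonal must be strictly positive")
    }
    ev <- eigen(latent_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(ev)) {
      abort("latent_cov must be positive semi-definite")
    }
  }
  structure(
    list(n_ecc_bands = n_ecc_bands, cells = cells, latent_cov = latent_cov,
         homotopic_gain = homotopic_gain, adjacent_r = adjacent_r,
         communities = communities, distal_r = distal_r,
         quadrant_mismatch = quadrant_mismatch,
         gradient_width = gradient_width, noise_sd = noise_sd, ar1 = ar1,
         smooth_fwhm_mm = smooth_fwhm_mm),
    class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf(paste0("<coupling_spec> %d latent cells (%d ecc bands); ",
                     "homotopic_gain %.2f, noise_sd %.2f, ar1 %.2f\n"),
              nrow(x$cells), x$n_ecc_bands, x$homotopic_gain, x$noise_sd,
              x$ar1))
  invisible(x)
}

#' Staggered five-cluster hierarchy template
#'
#' A 16 x 16 area-level correlation template that plants the five-cluster
#' hierarchy directly: between-cluster correlations follow the tier at which
#' the hierarchy separates the clusters (dorsal splits off first, then
#' inferotemporal, then the MT cluster, then posterior from anterior
#' occipital), and within each cluster members attach progressively more
#' weakly to the cluster core (the k-th member couples to all earlier
#' members at `within_base - within_step * (k - 2)`), giving the staggered
#' within-cluster merge heights characteristic of real areal hierarchies.
#' Pass the result to `coupling_spec(area_r = ...)`.
#'
#' @param within_base Correlation of the core pair inside a cluster.
#' @param within_step Attachment decay per additional member.
#' @param tier_r Between-cluster correlations for the four tiers, outermost
#'   first.
#' @return A symmetric 16 x 16 matrix with unit diagonal.
#' @export
hierarchy_area_template <- function(within_base = 0.6, within_step = 0.05,
                                    tier_r = c(0.10, 0.18, 0.26, 0.34)) {
  areas <- visual_areas()
  chains <- list(post_occipital = c("V1", "V2", "V3"),
                 ant_occipital  = c("V4", "V4A", "OTd"),
                 inferotemporal = c("PITd", "PITv", "OTS"),
                 mt_cluster     = c("MT", "MST", "FST", "V4t"),
                 dorsal         = c("V3A/DP", "CIP", "LIP"))
  # tier at which two clusters separate (outermost split first)
  tier_of <- function(g1, g2) {
    if (g1 == g2) return(NA_integer_)
    if ("dorsal" %in% c(g1, g2)) return(1L)
    if ("inferotemporal" %in% c(g1, g2)) return(2L)
    if ("mt_cluster" %in% c(g1, g2)) return(3L)
    4L
  }
  grp <- setNames(rep(names(chains), lengths(chains)), unlist(chains))
  pos <- unlist(lapply(chains, seq_along))
  names(pos) <- unlist(chains)
  R <- matrix(NA_real_, 16, 16, dimnames = list(areas, areas))
  for (a in areas) for (b in areas) {
    R[a, b] <- if (a == b) 1 else if (grp[a] == grp[b]) {
      within_base - within_step * (max(pos[a], pos[b]) - 2)
    } else {
      tier_r[tier_of(grp[a], grp[b])]
    }
  }
  (R + t(R)) / 2
}

# 16x16 area-level correlation template
area_template <- function(adjacent_r, communities, distal_r, adjacency) {
  areas <- visual_areas()
  R <- matrix(distal_r, 16, 16, dimnames = list(areas, areas))
  for (lev in communities) {
    for (grp in lev$groups) {
      grp <- intersect(grp, areas)
      R[grp, grp] <- pmax(R[grp, grp], lev$r)
    }
  }
  for (k in seq_len(nrow(adjacency))) {
    a <- adjacency$area_a[k]; b <- adjacency$area_b[k]
    R[a, b] <- max(R[a, b], adjacent_r)
    R[b, a] <- R[a, b]
  }
  diag(R) <- 1
  R
}

cell_covariance <- function(cells, areaR, quadrant_mismatch, gradient_width,
                            homotopic_gain) {
  n <- nrow(cells)
  Ra <- areaR[cells$area, cells$area]
  qlab <- cells$quadrant
  qmis <- outer(qlab, qlab, function(a, b) {
    ifelse(a != "none" & b != "none" & a != b, quadrant_mismatch, 1)
  })
  db <- outer(cells$ecc_band, cells$ecc_band, "-")
  ecc <- exp(-db^2 / (2 * gradient_width^2))
  hem <- outer(cells$hemisphere, cells$hemisphere, function(a, b) {
    ifelse(a == b, 1, min(homotopic_gain, 1))
  })
  C <- Ra * qmis * ecc * hem
  diag(C) <- 1
  C
}

# eigenvalue clipping onto the PSD cone, rescaled to unit diagonal
nearest_psd_corr <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  P <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(P), .Machine$double.eps))
  P <- P / outer(d, d)
  (P + t(P)) / 2
}

#' Serialize a coupling spec to YAML
#'
#' The constructor parameters (not the expanded covariance) are written, so
#' the file stays small and human-editable; [read_coupling_spec_yaml()]
#' rebuilds the covariance.
#'
#' @param spec A [coupling_spec()].
#' @param path File path.
#' @export
write_coupling_spec_yaml <- function(spec, path) {
  payload <- list(
    n_ecc_bands = spec$n_ecc_bands,
    homotopic_gain = spec$homotopic_gain,
    adjacent_r = spec$adjacent_r,
    communities = lapply(spec$communities, function(l)
      list(groups = l$groups, r = l$r)),
    distal_r = spec$distal_r,
    quadrant_mismatch = spec$quadrant_mismatch,
    gradient_width = spec$gradient_width,
    noise_sd = spec$noise_sd,
    ar1 = spec$ar1,
    smooth_fwhm_mm = spec$smooth_fwhm_mm)
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_coupling_spec_yaml
#' @export
read_coupling_spec_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  coupling_spec(
    n_ecc_bands = p$n_ecc_bands, homotopic_gain = p$homotopic_gain,
    adjacent_r = p$adjacent_r,
    communities = lapply(p$communities, function(l)
      list(groups = l$groups, r = l$r)),
    distal_r = p$distal_r, quadrant_mismatch = p$quadrant_mismatch,
    gradient_width = p$gradient_width, noise_sd = p$noise_sd, ar1 = p$ar1,
    smooth_fwhm_mm = p$smooth_fwhm_mm)
}
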