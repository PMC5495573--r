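#' V1 eccentricity bands
#'
#' Splits one hemisphere's V1 voxels (eccentricity <= `max_ecc`) into
#' `n_bins` equal cortical-distance intervals along the eccentricity axis.
#'
#' @param parc Parcellation.
#' @param n_bins Number of bands (default 8).
#' @param max_ecc Largest included eccentricity, degrees (default 10).
#' @param hemi Hemisphere of the V1 seed.
#' @return Named list of voxel-row indices (into the parcellation/dataset),
#'   one per band, with attribute `bin_center_deg` (mean eccentricity per
#'   band).
#' @export
v1_eccentricity_bins <- function(parc, n_bins = 8, max_ecc = 10,
                                 hemi = "left") {
  rows <- which(parc$hemisphere == hemi & parc$area == "V1" &
                  parc$eccentricity_deg <= max_ecc)
  if (length(rows) == 0) abort("no V1 voxels within max_ecc")
  cd <- parc$cortical_distance[rows]
  # equal cortical-distance intervals over the selected span
  br <- seq(min(cd), max(cd), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(cd, br, rightmost.closed = TRUE), 1), n_bins)
  bins <- split(rows, factor(bin, levels = seq_len(n_bins)))
  sizes <- vapply(bins, length, integer(1))
  if (any(sizes == 0)) {
    abort(sprintf("band(s) %s are empty; try fewer bins",
                  paste(which(sizes == 0), collapse = ", ")))
  }
  names(bins) <- paste0("bin", seq_len(n_bins))
  attr(bins, "bin_center_deg") <- vapply(bins, function(ix)
    mean(parc$eccentricity_deg[ix]), numeric(1))
  bins
}

#' Correlation curves against the V1 eccentricity bands
#'
#' Per subsample iteration, each band is subsampled to the smallest band's
#' size, band mean series are computed, and each target voxel's series is
#' correlated with every band mean; r is averaged across iterations. The
#' result is one correlation curve (length `n_bins`) per target voxel.
#'
#' @param ds A preprocessed [fmri_dataset()].
#' @param bins Band list from [v1_eccentricity_bins()].
#' @param target_voxels Row indices of the voxels to correlate (default: all
#'   rows).
#' @param n_iter Subsample iterations (default 100).
#' @param seed Integer seed.
#' @return Matrix `targets x n_bins` of Pearson r, with the band centers
#'   (degrees) in attribute `bin_center_deg` and target rows in attribute
#'   `target_voxels`.
#' @export
bin_correlation_curves <- function(ds, bins, target_voxels = NULL,
                                   n_iter = 100, seed = 1) {
  target_voxels <- target_voxels %||% seq_len(nrow(ds$data))
  mats <- subsample_group_means(ds, drop_flagged(ds, bins), n_iter, seed)
  V <- ds$data[target_voxels, , drop = FALSE]
  r <- t(iter_corr(mats, list(V)))          # targets x bins
  rownames(r) <- target_voxels
  attr(r, "bin_center_deg") <- attr(bins, "bin_center_deg")
  attr(r, "target_voxels") <- target_voxels
  r
}

#' Select voxels explained by the eccentricity bands
#'
#' Regresses each voxel's series on the band mean series (plus intercept)
#' and keeps voxels whose omnibus F exceeds `f_thresh`. Collinear band
#' columns are dropped with a warning.
#'
#' @inheritParams bin_correlation_curves
#' @param f_thresh Omnibus F cutoff (default 20).
#' @return Logical mask over the dataset rows, with per-voxel F in attribute
#'   `f_stat`.
#' @export
select_by_regression <- function(ds, bins, f_thresh = 20) {
  means <- t(vapply(bins, function(ix)
    colMeans(ds$data[ix, , drop = FALSE]), numeric(ncol(ds$data))))
  X <- cbind(1, t(means))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warn(sprintf("dropped %d collinear band regressor(s)",
                 ncol(X) - qrX$rank))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  p <- ncol(X) - 1            # slope terms
  n <- ncol(ds$data)
  Q <- qr.Q(qrX)
  Y <- t(ds$data)
  Yc <- sweep(Y, 2, colMeans(Y))
  fitted <- Q %*% (t(Q) %*% Y)
  rss <- colSums((Y - fitted)^2)
  tss <- colSums(Yc^2)
  mss <- pmax(tss - rss, 0)
  f <- (mss / p) / (rss / (n - p - 1))
  f[tss == 0] <- 0
  mask <- f > f_thresh
  attr(mask, "f_stat") <- f
  mask
}

#' Fit a Gaussian peak to one correlation curve
#'
#' Least-squares fit of `A0 + A1 * exp(-((x - B1) / C1)^2)` over band index
#' `x = 1..n`, giving the preferred eccentricity band `B1`. Initialization:
#' `A0 = min`, `A1 = max - min`, `B1 = argmax`, `C1 = 2`; bounds keep `B1`
#' inside `[0.5, n + 0.5]` and `C1` in `(0.3, 20]` to prevent degenerate
#' flat fits. The fit passes when the curve value at the band nearest the
#' peak reaches `r_thresh`.
#'
#' @param curve Numeric vector of per-band correlations (>= 4 finite
#'   entries).
#' @param r_thresh Minimum r at the peak band (default 0.15).
#' @param bin_center_deg Optional band centers for the degree conversion.
#' @return An object of class `ecc_fit` with elements `A0`, `A1`, `B1`,
#'   `C1`, `r_at_peak_bin`, `passed`, `converged`, `ecc_deg`.
#' @export
fit_gaussian_peak <- function(curve, r_thresh = 0.15,
                              bin_center_deg = NULL) {
  x <- seq_along(curve)
  ok <- is.finite(curve)
  if (sum(ok) < 4) abort("need at least 4 finite curve entries")
  start <- list(A0 = min(curve[ok]), A1 = diff(range(curve[ok])),
                B1 = x[ok][which.max(curve[ok])], C1 = 2)
  if (start$A1 == 0) start$A1 <- 1e-6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A0 + A1 * exp(-((xx - B1) / C1)^2),
      data = data.frame(y = curve[ok], xx = x[ok]),
      start = start,
      lower = c(A0 = -2, A1 = 0, B1 = 0.5, C1 = 0.3),
      upper = c(A0 = 2, A1 = 4, B1 = length(curve) + 0.5, C1 = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(A0 = NA_real_, A1 = NA_real_, B1 = NA_real_, C1 = NA_real_,
                r_at_peak_bin = NA_real_, passed = FALSE, converged = FALSE,
                ecc_deg = NA_real_, diagnostic = "fit did not converge")
    return(structure(out, class = "ecc_fit"))
  }
  cf <- as.list(coef(fit))
  peak_bin <- min(max(round(cf$B1), 1L), length(curve))
  r_peak <- curve[peak_bin]
  ecc <- if (!is.null(bin_center_deg)) {
    stats::approx(x, bin_center_deg, xout = cf$B1, rule = 2)$y
  } else NA_real_
  structure(list(A0 = cf$A0, A1 = cf$A1, B1 = cf$B1, C1 = cf$C1,
                 r_at_peak_bin = r_peak,
                 passed = is.finite(r_peak) && r_peak >= r_thresh,
                 converged = TRUE, ecc_deg = ecc, diagnostic = NULL),
            class = "ecc_fit")
}

#' @export
print.ecc_fit <- function(x, ...) {
  cat(sprintf("<ecc_fit> B1 = %.2f bins (%.2f deg), A1 = %.3f, passed = %s\n",
              x$B1, x$ecc_deg, x$A1, x$passed))
  invisible(x)
}

#' @export
tidy.ecc_fit <- function(x, ...) {
  tibble(term = c("A0", "A1", "B1", "C1"),
         estimate = c(x$A0, x$A1, x$B1, x$C1))
}

#' @export
glance.ecc_fit <- function(x, ...) {
  tibble(B1 = x$B1, ecc_deg = x$ecc_deg, r_at_peak_bin = x$r_at_peak_bin,
         passed = x$passed, converged = x$converged)
}

#' Fit Gaussian peaks for many voxels
#'
#' Applies [fit_gaussian_peak()] to every row of a curve matrix from
#' [bin_correlation_curves()].
#'
#' @param curves Matrix targets x bands.
#' @param r_thresh Peak-band threshold.
#' @return Tibble with `voxel_id`, `A0`, `A1`, `B1`, `C1`,
#'   `r_at_peak_bin`, `ecc_deg`, `passed`, `converged`.
#' @export
fit_gaussian_peaks <- function(curves, r_thresh = 0.15) {
  centers <- attr(curves, "bin_center_deg")
  ids <- attr(curves, "target_voxels") %||% seq_len(nrow(curves))
  rows <- lapply(seq_len(nrow(curves)), function(i) {
    f <- tryCatch(fit_gaussian_peak(curves[i, ], r_thresh, centers),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(tibble(A0 = NA_real_, A1 = NA_real_, B1 = NA_real_,
                    C1 = NA_real_, r_at_peak_bin = NA_real_,
                    ecc_deg = NA_real_, passed = FALSE, converged = FALSE))
    }
    tibble(A0 = f$A0, A1 = f$A1, B1 = f$B1, C1 = f$C1,
           r_at_peak_bin = f$r_at_peak_bin, ecc_deg = f$ecc_deg,
           passed = f$passed, converged = f$converged)
  })
  dplyr::bind_cols(tibble(voxel_id = ids), dplyr::bind_rows(rows))
}

#' Mean absolute deviation between two eccentricity maps
#'
#' Per area group, the mean absolute difference (degrees) between two
#' per-voxel eccentricity maps on their common finite voxels. V1 — the seed
#' area itself — is excluded by default.
#'
#' @param map_a,map_b Named numeric vectors (names = voxel ids) or vectors
#'   aligned to the parcellation rows, in degrees.
#' @param parc Parcellation.
#' @param area_groups Named list of area-label vectors defining the groups;
#'   defaults to occipital, MT cluster, inferotemporal, and dorsal/parietal
#'   groups.
#' @param exclude Areas excluded everywhere (default `"V1"`).
#' @return Tibble with `group`, `n_voxels`, `mad_deg`, plus an `overall`
#'   row.
#' @export
map_deviation <- function(map_a, map_b, parc,
                          area_groups = list(
                            occipital = c("V1", "V2", "V3", "V4"),
                            mt_cluster = c("MT", "MST", "FST", "V4t"),
                            inferotemporal = c("V4A", "OTd", "PITv", "PITd",
                                               "OTS"),
                            dorsal_parietal = c("V3A/DP", "CIP", "LIP")),
                          exclude = "V1") {
  align <- function(m) {
    if (!is.null(names(m))) m[as.character(parc$voxel_id)]
    else if (length(m) == nrow(parc)) m
    else abort("maps must align with the parcellation voxels")
  }
  a <- align(map_a); b <- align(map_b)
  keep <- is.finite(a) & is.finite(b) & !(parc$area %in% exclude)
  if (!any(keep)) abort("no common finite voxels after exclusions")
  dev <- abs(a - b)
  per_group <- purrr::map_dfr(names(area_groups), function(g) {
    sel <- keep & parc$area %in% setdiff(area_groups[[g]], exclude)
    tibble(group = g, n_voxels = sum(sel),
           mad_deg = if (any(sel)) mean(dev[sel]) else NA_real_)
  })
  dplyr::bind_rows(per_group,
                   tibble(group = "overall", n_voxels = sum(keep),
                          mad_deg = mean(dev[keep])))
}
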