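#' Fourier phase map of a phase-encoded run
#'
#' Per run, takes the discrete Fourier transform of each voxel's
#' mean-normalized series and reads out the amplitude and phase of the
#' harmonic at the stimulus frequency (`cycles_per_run` cycles per run).
#' Phases are rotated backward by the hemodynamic lag
#' (`2 * pi * lag_s / cycle period`). Response significance is an F ratio:
#' power at the stimulus bin over the mean power across noise bins —
#' excluding DC, the slowest bins (1-2 cycles/run), the stimulus bin and its
#' neighbors, and the 2f/3f harmonics — with `(2, 2 * K)` degrees of
#' freedom for `K` noise bins. Runs are combined by averaging their complex
#' spectra.
#'
#' @param ds An [fmri_dataset()] whose runs share one length.
#' @param cycles_per_run Stimulus cycles per run.
#' @param lag_s Hemodynamic lag correction in seconds (default 4).
#' @param exclude_bins Extra noise-bin exclusions (cycles/run units).
#' @return A tibble of class `phase_map` with columns `voxel_id`,
#'   `amplitude`, `phase_rad`, `f_ratio`, `p`; attributes record the
#'   paradigm timing (`cycles_per_run`, `period_s`, `lag_s`, `df`).
#' @export
fourier_phase_map <- function(ds, cycles_per_run, lag_s = 4,
                              exclude_bins = NULL) {
  N <- unique(ds$run_lengths)
  if (length(N) != 1) abort("all runs must share one length")
  if (cycles_per_run >= N / 2) {
    abort("cycles_per_run must be below the Nyquist bin")
  }
  period_s <- N * ds$tr_s / cycles_per_run
  idx <- run_index(ds)
  spec <- NULL
  for (ix in idx) {
    X <- ds$data[, ix, drop = FALSE]
    m <- rowMeans(X)
    # mean-normalize where the mean is usable; otherwise just demean
    ok <- abs(m) > 1e-8
    Xn <- X - m
    Xn[ok, ] <- X[ok, , drop = FALSE] / m[ok] - 1
    S <- t(stats::mvfft(t(Xn)))          # voxels x freq bins
    spec <- if (is.null(spec)) S else spec + S
  }
  spec <- spec / length(idx)
  k <- cycles_per_run + 1L               # bin index (DC is column 1)
  half <- floor(N / 2)
  excl <- unique(c(0:2, cycles_per_run + c(-1, 0, 1),
                   2 * cycles_per_run, 3 * cycles_per_run, exclude_bins))
  noise_bins <- setdiff(seq_len(half - 1), excl) + 1L
  K <- length(noise_bins)
  power <- abs(spec)^2
  f_ratio <- power[, k] / rowMeans(power[, noise_bins, drop = FALSE])
  amp <- 2 * abs(spec[, k]) / N
  phase <- (-Arg(spec[, k]) - 2 * pi * lag_s / period_s) %% (2 * pi)
  out <- tibble(voxel_id = ds$voxel_ids, amplitude = amp,
                phase_rad = phase, f_ratio = f_ratio,
                p = pf(f_ratio, 2, 2 * K, lower.tail = FALSE))
  attr(out, "cycles_per_run") <- cycles_per_run
  attr(out, "period_s") <- period_s
  attr(out, "lag_s") <- lag_s
  attr(out, "df") <- c(2, 2 * K)
  class(out) <- c("phase_map", class(out))
  out
}

#' Combine forward and reverse phase maps
#'
#' Reverse-run phases are negated (mod `2 * pi`) to match the forward
#' convention, then combined with the forward phases by circular mean;
#' amplitudes and F ratios are averaged and p recomputed at the forward
#' map's degrees of freedom.
#'
#' @param fwd,rev `phase_map` tibbles over the same voxels.
#' @return A `phase_map` tibble.
#' @export
combine_directions <- function(fwd, rev) {
  if (!identical(fwd$voxel_id, rev$voxel_id)) {
    abort("forward and reverse maps must cover the same voxels")
  }
  phi_r <- (-rev$phase_rad) %% (2 * pi)
  z <- exp(1i * fwd$phase_rad) + exp(1i * phi_r)
  phase <- Arg(z) %% (2 * pi)
  df <- attr(fwd, "df")
  f_ratio <- (fwd$f_ratio + rev$f_ratio) / 2
  out <- tibble(voxel_id = fwd$voxel_id,
                amplitude = (fwd$amplitude + rev$amplitude) / 2,
                phase_rad = phase, f_ratio = f_ratio,
                p = pf(f_ratio, df[1], df[2], lower.tail = FALSE))
  for (a in c("cycles_per_run", "period_s", "lag_s", "df")) {
    attr(out, a) <- attr(fwd, a)
  }
  class(out) <- c("phase_map", class(out))
  out
}

#' Decode stimulus values from response phases
#'
#' Inverts the linear phase-to-stimulus mapping of the paradigm: for
#' `eccentricity` (and `polar`) the cycle sweeps the degree range linearly;
#' for `sf_sweep` the phase indexes the descending 8-step spatial-frequency
#' ladder, interpolated on a log scale.
#'
#' @param pm A `phase_map`.
#' @param paradigm `"eccentricity"`, `"polar"`, or `"sf_sweep"`.
#' @param paradigm_params `min_deg`/`max_deg` (eccentricity/polar sweep
#'   range, defaults 0-10 degrees of eccentricity or 0-360 of polar angle)
#'   or `sf_ladder` (cycles/degree).
#' @return The `phase_map` with a `decoded_value` column appended (degrees,
#'   or cycles/degree for the sweep).
#' @export
decode_phase <- function(pm, paradigm = c("eccentricity", "polar",
                                          "sf_sweep"),
                         paradigm_params = list()) {
  paradigm <- match.arg(paradigm)
  p <- paradigm_params
  frac <- pm$phase_rad / (2 * pi)
  decoded <- if (paradigm == "eccentricity") {
    min_deg <- p$min_deg %||% 0
    max_deg <- p$max_deg %||% 10
    min_deg + frac * (max_deg - min_deg)
  } else if (paradigm == "polar") {
    min_deg <- p$min_deg %||% 0
    max_deg <- p$max_deg %||% 360
    min_deg + frac * (max_deg - min_deg)
  } else {
    ladder <- p$sf_ladder %||% c(3, 2, 1, 0.8, 0.5, 0.4, 0.2, 0.1)
    pos <- frac * length(ladder) + 0.5
    exp(stats::approx(seq_along(ladder), log(ladder), xout = pos,
                      rule = 2)$y)
  }
  pm$decoded_value <- decoded
  pm
}

#' GLM contrast on a block-design dataset
#'
#' Ordinary least squares per voxel on condition boxcars convolved with the
#' MION kernel, plus per-run intercept, linear drift, and (optionally)
#' motion regressors. Data are converted to percent signal change per run
#' before fitting, so betas and contrasts are in percent units.
#'
#' @param ds An [fmri_dataset()] from a block design.
#' @param design List with `conditions`, `block_len_s`, `rest_len_s`
#'   (defaults come from the dataset's `block_design` attribute when
#'   present).
#' @param contrast Named numeric condition weights (e.g.,
#'   `c(curved = 1, rectilinear = -1)`).
#' @param nuis Optional [nuisance_set()] providing motion columns.
#' @return Tibble with `voxel_id`, `beta_contrast` (percent signal change),
#'   `t`, `p`, and attribute `conditions`.
#' @export
glm_contrast <- function(ds, design = attr(ds, "block_design"), contrast,
                         nuis = NULL) {
  if (is.null(design)) abort("no design supplied or attached to the dataset")
  cond <- design$conditions
  if (is.null(names(contrast)) || !all(names(contrast) %in% cond)) {
    abort("contrast must be named with condition labels")
  }
  w <- setNames(numeric(length(cond)), cond)
  w[names(contrast)] <- contrast
  idx <- run_index(ds)
  Xs <- list(); Ys <- list()
  for (r in seq_along(idx)) {
    n <- length(idx[[r]])
    task <- block_regressors(cond, design$block_len_s,
                             design$rest_len_s %||% design$block_len_s,
                             n, ds$tr_s)
    drift <- scale(seq_len(n), center = TRUE, scale = FALSE)
    Zr <- matrix(0, n, 2 * length(idx), dimnames = NULL)
    Zr[, 2 * r - 1] <- 1
    Zr[, 2 * r] <- drift
    mot <- if (!is.null(nuis)) nuisance_matrix(nuis, r, n)
    Xs[[r]] <- cbind(task, Zr, mot)
    Y <- ds$data[, idx[[r]], drop = FALSE]
    m <- rowMeans(Y)
    if (any(abs(m) < 1e-12)) abort("zero-mean run: cannot scale to % change")
    Ys[[r]] <- t(100 * (Y / m - 1))
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  B <- qr.coef(qrX, Y)                       # coefficients x voxels
  res <- Y - X %*% B
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfree
  cw <- c(w, numeric(ncol(X) - length(cond)))
  XtXinv_c <- solve(qr.R(qrX), solve(t(qr.R(qrX)), cw))
  var_scale <- sum(cw * XtXinv_c)
  est <- as.numeric(t(B) %*% cw)
  se <- sqrt(sigma2 * var_scale)
  tstat <- est / se
  tibble(voxel_id = ds$voxel_ids, beta_contrast = est, t = tstat,
         p = 2 * pt(abs(tstat), dfree, lower.tail = FALSE))
}

#' Linear tuning-versus-eccentricity fits per area
#'
#' Groups a per-voxel map (preferred spatial frequency, contrast beta, ...)
#' into eccentricity bins of `bin_deg` degrees within the central `max_deg`
#' degrees, drops bins with fewer than `min_voxels` voxels, and fits a line
#' to the bin means against the bin centers, one fit per area. Areas with
#' two or more dropped/empty bins are excluded (with a warning naming
#' them).
#'
#' @param values Numeric per-voxel map aligned to the parcellation rows.
#' @param parc Parcellation.
#' @param bin_deg Bin width, degrees (default 1).
#' @param max_deg Central extent, degrees (default 8).
#' @param min_voxels Minimum voxels per bin (default 5).
#' @return Tibble with `area`, `slope`, `intercept`, `bins_used`; excluded
#'   areas are listed in attribute `excluded_areas`.
#' @export
tuning_vs_eccentricity <- function(values, parc, bin_deg = 1, max_deg = 8,
                                   min_voxels = 5) {
  if (length(values) != nrow(parc)) {
    abort("values must align with the parcellation voxels")
  }
  breaks <- seq(0, max_deg, by = bin_deg)
  centers <- head(breaks, -1) + bin_deg / 2
  n_bins <- length(centers)
  fits <- list(); excluded <- character(0)
  for (a in unique(parc$area)) {
    sel <- parc$area == a & parc$eccentricity_deg < max_deg &
      is.finite(values)
    bin <- findInterval(parc$eccentricity_deg[sel], breaks,
                        rightmost.closed = TRUE)
    counts <- tabulate(bin, n_bins)
    usable <- counts >= min_voxels
    if (sum(!usable) >= 2) {
      excluded <- c(excluded, a)
      next
    }
    if (sum(usable) < 2) {
      excluded <- c(excluded, a)
      next
    }
    means <- vapply(which(usable), function(b)
      mean(values[sel][bin == b]), numeric(1))
    fit <- stats::lm(means ~ centers[usable])
    fits[[a]] <- tibble(area = a, slope = coef(fit)[2],
                        intercept = coef(fit)[1],
                        bins_used = sum(usable))
  }
  if (length(excluded) > 0) {
    warn(paste0("excluded (>= 2 unusable eccentricity bins): ",
                paste(excluded, collapse = ", ")))
  }
  out <- dplyr::bind_rows(fits)
  attr(out, "excluded_areas") <- excluded
  out
}
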