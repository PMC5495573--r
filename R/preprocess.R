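#' Bundle nuisance regressors
#'
#' Holds the per-run nuisance series used for residualization: six rigid-body
#' motion parameters (3 translations mm, 3 rotations deg) with their temporal
#' first differences, a ventricle signal, and a white-matter signal. All
#' series must match their run's length; derivatives are computed here
#' (backward difference, first sample 0).
#'
#' @param motion List (one element per run) of T x 6 matrices, or NULL.
#' @param ventricle,white_matter Lists of length-T numeric vectors, or NULL.
#' @return An object of class `nuisance_set`; regressor matrix per run via
#'   the internal assembler used by [regress_nuisance()].
#' @export
nuisance_set <- function(motion = NULL, ventricle = NULL,
                         white_matter = NULL) {
  structure(list(motion = motion, ventricle = ventricle,
                 white_matter = white_matter),
            class = "nuisance_set")
}

#' Read a nuisance TSV (one column per regressor) for a single run
#'
#' Columns named `trans_*`/`rot_*` are taken as motion, `ventricle` and
#' `white_matter` as tissue signals.
#'
#' @param paths Character vector of per-run TSV paths.
#' @return A `nuisance_set`.
#' @export
read_nuisance_tsv <- function(paths) {
  tabs <- lapply(paths, utils::read.delim, sep = "\t")
  motion <- lapply(tabs, function(d) {
    as.matrix(d[, grepl("^(trans|rot)_", names(d)), drop = FALSE])
  })
  pick <- function(col) lapply(tabs, function(d) d[[col]])
  nuisance_set(
    motion = if (ncol(motion[[1]]) > 0) motion,
    ventricle = if ("ventricle" %in% names(tabs[[1]])) pick("ventricle"),
    white_matter = if ("white_matter" %in% names(tabs[[1]])) pick("white_matter"))
}

# regressor matrix for run r (without intercept); NULL when empty
nuisance_matrix <- function(nuis, r, run_len) {
  cols <- list()
  if (!is.null(nuis$motion)) {
    m <- as.matrix(nuis$motion[[r]])
    if (nrow(m) != run_len) abort(sprintf("motion length mismatch in run %d", r))
    dm <- apply(m, 2, function(v) c(0, diff(v)))
    cols$motion <- m
    cols$motion_deriv <- dm
  }
  for (nm in c("ventricle", "white_matter")) {
    if (!is.null(nuis[[nm]])) {
      v <- nuis[[nm]][[r]]
      if (length(v) != run_len) abort(sprintf("%s length mismatch in run %d", nm, r))
      cols[[nm]] <- matrix(v, ncol = 1)
    }
  }
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

#' Drop initial volumes of every run
#'
#' Removes the first `n_tr` timepoints of each run to avoid scanner-onset
#' transients; run boundaries are updated.
#'
#' @param ds An [fmri_dataset()].
#' @param n_tr Volumes to drop per run (default 5).
#' @return The trimmed dataset.
#' @export
trim_initial <- function(ds, n_tr = 5) {
  if (n_tr < 0) abort("n_tr must be >= 0")
  short <- which(ds$run_lengths <= n_tr)
  if (length(short) > 0) {
    abort(sprintf("run(s) %s have <= %d timepoints and cannot be trimmed",
                  paste(short, collapse = ", "), n_tr))
  }
  if (n_tr == 0) return(add_provenance(ds, "trim_initial", list(n_tr = 0)))
  out <- map_runs(ds, function(X, r) X[, -seq_len(n_tr), drop = FALSE])
  add_provenance(out, "trim_initial", list(n_tr = n_tr))
}

#' Clip extreme deviations (despike)
#'
#' Per voxel and run, samples deviating from the run mean by more than
#' `sd_thresh` standard deviations are clipped to the threshold boundary;
#' everything else is untouched. Constant series pass through unchanged.
#'
#' @param ds An [fmri_dataset()].
#' @param sd_thresh Deviation threshold in SD units (default 2.5).
#' @return The despiked dataset.
#' @export
despike <- function(ds, sd_thresh = 2.5) {
  out <- map_runs(ds, function(X, r) {
    m <- rowMeans(X)
    s <- apply(X, 1, sd)
    lo <- m - sd_thresh * s
    hi <- m + sd_thresh * s
    pmin(pmax(X, lo), hi)
  })
  add_provenance(out, "despike", list(sd_thresh = sd_thresh))
}

#' Band-pass filter in time
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass applied per
#' run and voxel, retaining `f_low`-`f_high` Hz. The default band is the
#' conventional resting-state window 0.01-0.1 Hz.
#'
#' @param ds An [fmri_dataset()].
#' @param f_low,f_high Pass-band edges in Hz.
#' @param order Butterworth order (per direction).
#' @return The filtered dataset (runs keep their length).
#' @export
bandpass <- function(ds, f_low = 0.01, f_high = 0.1, order = 4) {
  if (f_low >= f_high) abort("f_low must be < f_high")
  nyq <- 1 / (2 * ds$tr_s)
  if (f_high >= nyq) abort("f_high must be below the Nyquist frequency")
  filt <- signal::butter(order, c(f_low, f_high) / nyq, type = "pass")
  min_len <- 2 / (f_low * ds$tr_s)
  if (any(ds$run_lengths < min_len)) {
    warn(sprintf("run(s) shorter than %g TR: band edge %g Hz is poorly resolved",
                 min_len, f_low))
  }
  out <- map_runs(ds, function(X, r) {
    # remove the DC level before filtering: it is outside the pass band and
    # would otherwise drive a large shared edge transient through filtfilt
    m <- rowMeans(X)
    t(apply(X - m, 1, function(v) signal::filtfilt(filt, v)))
  })
  add_provenance(out, "bandpass",
                 list(f_low = f_low, f_high = f_high, order = order))
}

#' Remove linear and quadratic trends
#'
#' Per run and voxel, the least-squares second-order polynomial in time is
#' subtracted; residuals are orthogonal to `{1, t, t^2}`.
#'
#' @param ds An [fmri_dataset()].
#' @return The detrended dataset.
#' @export
detrend <- function(ds) {
  out <- map_runs(ds, function(X, r) {
    tt <- seq_len(ncol(X))
    B <- cbind(1, tt, tt^2)
    Q <- qr.Q(qr(B))
    X - (X %*% Q) %*% t(Q)
  })
  add_provenance(out, "detrend", list(order = 2))
}

#' Regress out nuisance signals
#'
#' Per run, residualizes every voxel against the mean-centered nuisance
#' regressors (motion, motion derivatives, ventricle, white matter) plus an
#' intercept. Rank-deficient columns are dropped with a warning. The global
#' mean signal is deliberately not among the regressors.
#'
#' @param ds An [fmri_dataset()].
#' @param nuis A [nuisance_set()]; an empty set leaves the data unchanged
#'   (up to mean removal by the intercept).
#' @param demean Keep the intercept column (default TRUE).
#' @return The residual dataset.
#' @export
regress_nuisance <- function(ds, nuis = nuisance_set(), demean = TRUE) {
  out <- map_runs(ds, function(X, r) {
    Z <- nuisance_matrix(nuis, r, ncol(X))
    if (is.null(Z) && !demean) return(X)
    Z <- if (is.null(Z)) NULL else scale(Z, center = TRUE, scale = FALSE)
    B <- cbind(intercept = if (demean) rep(1, ncol(X)), Z)
    qrB <- qr(B)
    if (qrB$rank < ncol(B)) {
      keep <- qrB$pivot[seq_len(qrB$rank)]
      warn(sprintf("run %d: dropped %d rank-deficient nuisance column(s)",
                   r, ncol(B) - qrB$rank))
      qrB <- qr(B[, keep, drop = FALSE])
    }
    Q <- qr.Q(qrB)
    X - (X %*% Q) %*% t(Q)
  })
  add_provenance(out, "regress_nuisance",
                 list(regressors = names(Filter(Negate(is.null), unclass(nuis)))))
}

#' Normalize each voxel's run to its mean
#'
#' Per voxel and run, the series is divided by its temporal mean. After
#' filtering/detrending the raw mean is near zero, so when a baseline matrix
#' is attached (as [run_preprocess()] does before filtering) the stored
#' pre-filter mean `m0` is used instead and the output is `1 + x / m0`,
#' which is the same affine map and leaves Pearson correlations untouched.
#' Voxels whose usable mean magnitude is below `tol` are flagged in the
#' `flagged_voxels` attribute and excluded from downstream seed averages.
#'
#' @param ds An [fmri_dataset()].
#' @param tol Minimum usable mean magnitude.
#' @return The normalized dataset (per-run voxel means 1 for clean voxels).
#' @export
normalize_to_mean <- function(ds, tol = 1e-6) {
  baseline <- attr(ds, "baseline_mean")   # voxels x runs, set by run_preprocess
  idx <- run_index(ds)
  flagged <- logical(nrow(ds$data))
  out <- ds
  for (r in seq_along(idx)) {
    X <- ds$data[, idx[[r]], drop = FALSE]
    m <- rowMeans(X)
    use_baseline <- abs(m) < tol & !is.null(baseline)
    m0 <- if (is.null(baseline)) m else ifelse(abs(m) < tol, baseline[, r], m)
    bad <- abs(m0) < tol
    flagged <- flagged | bad
    m0[bad] <- 1                      # placeholder; voxel is flagged anyway
    Xn <- ifelse(matrix(use_baseline, nrow(X), ncol(X)), 1 + X / m0, X / m0)
    out$data[, idx[[r]]] <- Xn
  }
  if (any(flagged)) {
    warn(sprintf("%d voxel(s) flagged: mean magnitude below %g", sum(flagged),
                 tol))
  }
  attr(out, "flagged_voxels") <- which(flagged)
  add_provenance(out, "normalize_to_mean", list(tol = tol))
}

#' Full rest-scan preprocessing pipeline
#'
#' Applies, in order: [trim_initial()], [despike()], [bandpass()],
#' [detrend()], [regress_nuisance()], [normalize_to_mean()]. Pre-filter
#' voxel means (captured after despiking) are stored so the final
#' normalization has a meaningful denominator. Set
#' `cfg$nuisance_before_filter = TRUE` to run the regression before the
#' band-pass instead. The applied steps and parameters are recorded in the
#' dataset's provenance.
#'
#' @param ds An [fmri_dataset()].
#' @param nuis A [nuisance_set()] (empty set = no nuisance regression beyond
#'   mean removal).
#' @param cfg Optional list overriding `n_trim`, `sd_thresh`, `f_low`,
#'   `f_high`, `nuisance_before_filter`.
#' @return The fully preprocessed dataset.
#' @export
run_preprocess <- function(ds, nuis = nuisance_set(), cfg = list()) {
  p <- modifyList(list(n_trim = 5, sd_thresh = 2.5, f_low = 0.01,
                       f_high = 0.1, nuisance_before_filter = FALSE), cfg)
  out <- trim_initial(ds, p$n_trim)
  out <- despike(out, p$sd_thresh)
  idx <- run_index(out)
  attr(out, "baseline_mean") <-
    vapply(idx, function(ix) rowMeans(out$data[, ix, drop = FALSE]),
           numeric(nrow(out$data)))
  if (isTRUE(p$nuisance_before_filter)) {
    out <- regress_nuisance(out, nuis)
    out <- bandpass(out, p$f_low, p$f_high)
    out <- detrend(out)
  } else {
    out <- bandpass(out, p$f_low, p$f_high)
    out <- detrend(out)
    out <- regress_nuisance(out, nuis)
  }
  normalize_to_mean(out)
}
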