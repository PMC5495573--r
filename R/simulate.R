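# Gaussian smoothing weights over the voxel coordinate cloud. Rows are
# normalized so smoothing is a kernel-weighted average; weights beyond
# 3.5 sigma are dropped.
smoothing_weights <- function(parc, fwhm_mm) {
  if (fwhm_mm <= 0) abort("fwhm_mm must be > 0")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  xyz <- cbind(parc$x, parc$y, parc$z)
  d2 <- as.matrix(stats::dist(xyz))^2
  W <- exp(-d2 / (2 * sigma^2))
  W[d2 > (3.5 * sigma)^2] <- 0
  W / rowSums(W)
}

# recursive AR(1) filter along time, applied to columns of a T x k matrix
ar1_filter <- function(X, ar1) {
  if (ar1 == 0) return(X)
  apply(X, 2, function(col) as.numeric(stats::filter(col, ar1,
                                                     method = "recursive")))
}

#' Simulate two-hemisphere resting-state data
#'
#' Draws the latent cell signals from the coupling spec's covariance
#' (optionally AR(1)-filtered in time), assigns each voxel the latent of its
#' (hemisphere, area, quadrant, eccentricity-band) cell, adds i.i.d. Gaussian
#' voxel noise, optionally smooths each timepoint spatially, and offsets the
#' whole series by `baseline` so that mean-normalization is meaningful.
#'
#' @param parc A [make_parcellation()] parcellation.
#' @param spec A [coupling_spec()]; its band count must match `parc`.
#' @param n_runs Number of runs.
#' @param run_len Timepoints per run (>= 20).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param tr_s Repetition time, seconds.
#' @param baseline Additive signal offset (arbitrary units).
#' @return An [fmri_dataset()].
#' @export
simulate_rest <- function(parc, spec, n_runs = 1, run_len = 150, seed = 1,
                          tr_s = 2, baseline = 100) {
  if (run_len < 20) abort("run_len must be >= 20")
  if (!inherits(spec, "coupling_spec")) abort("spec must be a coupling_spec")
  if (spec$n_ecc_bands != attr(parc, "n_ecc_bands")) {
    abort("spec and parcellation disagree on the number of eccentricity bands")
  }
  cell_idx <- match(latent_cells(parc), spec$cells$cell)
  if (anyNA(cell_idx)) abort("parcellation contains cells unknown to the coupling spec")
  U <- chol(spec$latent_cov + diag(1e-10, nrow(spec$latent_cov)))
  W <- if (spec$smooth_fwhm_mm > 0) smoothing_weights(parc, spec$smooth_fwhm_mm)
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    Z <- matrix(rnorm(run_len * nrow(spec$cells)), run_len)
    lat <- ar1_filter(Z %*% U, spec$ar1)           # T x cells
    D <- t(lat)[cell_idx, , drop = FALSE]          # voxels x T
    if (spec$noise_sd > 0) {
      eps <- matrix(rnorm(nrow(parc) * run_len, sd = spec$noise_sd),
                    nrow(parc))
      D <- D + t(ar1_filter(t(eps), spec$ar1))
    }
    if (!is.null(W)) D <- W %*% D
    D
  })
  ds <- fmri_dataset(do.call(cbind, runs) + baseline, tr_s = tr_s,
                     run_lengths = rep(run_len, n_runs),
                     voxel_ids = parc$voxel_id)
  add_provenance(ds, "simulate_rest",
                 list(n_runs = n_runs, run_len = run_len, seed = seed))
}

#' Planted stimulus phase for a phase-encoded paradigm
#'
#' Maps each voxel's parcellation labels to the phase (radians in `[0, 2pi)`)
#' at which the periodic stimulus drives it. For `eccentricity`, the ring
#' sweeps 0 to `max_deg` linearly over one cycle; for `polar`, the phase
#' encodes the voxel's quadrant (ventral = upper field at `pi/4` of the
#' hemifield sweep, dorsal = lower field at `3pi/4`, unlabeled areas midway);
#' for `sf_sweep`, preferred spatial frequency follows the descending 8-step
#' ladder `3, 2, 1, 0.8, 0.5, 0.4, 0.2, 0.1` cycles/degree, with foveal
#' voxels preferring the highest frequency.
#'
#' @param parc Parcellation.
#' @param paradigm One of `"eccentricity"`, `"polar"`, `"sf_sweep"`.
#' @param paradigm_params List; `min_deg`/`max_deg` for eccentricity
#'   (defaults 0 and the parcellation maximum), `sf_ladder` for the sweep.
#' @return Numeric vector of phases, one per voxel.
#' @export
encode_stimulus_phase <- function(parc,
                                  paradigm = c("eccentricity", "polar",
                                               "sf_sweep"),
                                  paradigm_params = list()) {
  paradigm <- match.arg(paradigm)
  p <- paradigm_params
  if (paradigm == "eccentricity") {
    min_deg <- p$min_deg %||% 0
    max_deg <- p$max_deg %||% attr(parc, "max_ecc_deg") %||% 10
    frac <- (parc$eccentricity_deg - min_deg) / (max_deg - min_deg)
  } else if (paradigm == "polar") {
    frac <- dplyr::case_when(parc$quadrant == "ventral" ~ 0.25,
                             parc$quadrant == "dorsal" ~ 0.75,
                             TRUE ~ 0.5) / 2
  } else {
    ladder <- p$sf_ladder %||% c(3, 2, 1, 0.8, 0.5, 0.4, 0.2, 0.1)
    max_deg <- p$max_deg %||% attr(parc, "max_ecc_deg") %||% 10
    pos <- 1 + (length(ladder) - 1) * parc$eccentricity_deg / max_deg
    frac <- (pos - 0.5) / length(ladder)
  }
  (2 * pi * frac) %% (2 * pi)
}

#' Simulate a phase-encoded mapping run
#'
#' Each voxel responds with a cosine at the cycle frequency whose phase
#' encodes the voxel's planted stimulus value (see
#' [encode_stimulus_phase()]), delayed by the hemodynamic lag. Reverse runs
#' negate the phase progression. The response amplitude is `snr` and the
#' additive white noise has unit standard deviation, so `snr = 0` gives pure
#' noise.
#'
#' @inheritParams simulate_rest
#' @param cycles_per_run Stimulus cycles per run (>= 2).
#' @param direction `"forward"` or `"reverse"`.
#' @param lag_s Hemodynamic lag in seconds (>= 0).
#' @param snr Response amplitude relative to unit noise.
#' @param run_len Timepoints per run; must be a multiple of the cycle length.
#' @param paradigm,paradigm_params Passed to [encode_stimulus_phase()].
#' @return An [fmri_dataset()] with attribute `planted_phase`.
#' @export
simulate_phase_encoded <- function(parc, cycles_per_run = 8,
                                   direction = c("forward", "reverse"),
                                   lag_s = 4, snr = 1, seed = 1,
                                   n_runs = 1, run_len = 160, tr_s = 2,
                                   paradigm = "eccentricity",
                                   paradigm_params = list(),
                                   baseline = 100) {
  direction <- match.arg(direction)
  if (cycles_per_run < 2) abort("cycles_per_run must be >= 2")
  if (lag_s < 0) abort("lag_s must be >= 0")
  if (run_len %% cycles_per_run != 0) {
    abort("run_len must be a multiple of cycles_per_run")
  }
  period_s <- run_len * tr_s / cycles_per_run
  phi <- encode_stimulus_phase(parc, paradigm, paradigm_params)
  tt <- (seq_len(run_len) - 1) * tr_s
  sgn <- if (direction == "forward") 1 else -1
  # voxels x T response; reverse runs negate the phase progression
  resp <- cos(outer(sgn * phi, 2 * pi * (tt - lag_s) / period_s,
                    function(p, w) w - p))
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    snr * resp + matrix(rnorm(nrow(parc) * run_len), nrow(parc))
  })
  ds <- fmri_dataset(do.call(cbind, runs) + baseline, tr_s = tr_s,
                     run_lengths = rep(run_len, n_runs),
                     voxel_ids = parc$voxel_id)
  attr(ds, "planted_phase") <- phi
  add_provenance(ds, "simulate_phase_encoded",
                 list(cycles_per_run = cycles_per_run, direction = direction,
                      lag_s = lag_s, snr = snr, seed = seed,
                      paradigm = paradigm))
}

#' MION hemodynamic response kernel
#'
#' Gamma-variate `t^8.6 * exp(-t / 0.547)` (peak near 4.7 s), peak-normalized
#' and sign-inverted to reflect the polarity of iron-oxide contrast.
#'
#' @param t Time in seconds (vector).
#' @param alpha,beta Gamma-variate shape and scale.
#' @return Kernel values (non-positive).
#' @export
mion_hrf <- function(t, alpha = 8.6, beta = 0.547) {
  h <- ifelse(t <= 0, 0, t^alpha * exp(-t / beta))
  peak <- (alpha * beta)^alpha * exp(-alpha)
  -h / peak
}

# condition boxcars for one run, convolved with the MION kernel.
# Blocks cycle through conditions with rest_len_s gaps.
block_regressors <- function(conditions, block_len_s, rest_len_s, run_len,
                             tr_s, hrf = mion_hrf) {
  block_tr <- block_len_s / tr_s
  rest_tr <- rest_len_s / tr_s
  n_cond <- length(conditions)
  box <- matrix(0, run_len, n_cond, dimnames = list(NULL, conditions))
  t0 <- 0
  k <- 1
  while (t0 + block_tr <= run_len) {
    idx <- seq(t0 + 1, t0 + block_tr)
    box[idx, ((k - 1) %% n_cond) + 1] <- 1
    t0 <- t0 + block_tr + rest_tr
    k <- k + 1
  }
  kern <- hrf(seq(0, 40, by = tr_s))
  apply(box, 2, function(b) {
    full <- stats::convolve(b, rev(kern), type = "open")
    full[seq_len(run_len)]
  })
}

#' Simulate a block-design task dataset
#'
#' Boxcar condition timecourses convolved with the MION kernel, scaled per
#' voxel by `effect_map` (percent signal change), riding on a baseline with
#' white noise. The planted effects are recoverable with [glm_contrast()].
#'
#' @inheritParams simulate_rest
#' @param conditions Character vector of condition names (>= 2).
#' @param block_len_s Stimulus block length, seconds; must be a multiple of
#'   `tr_s`.
#' @param effect_map Numeric matrix voxels x conditions: response amplitude
#'   in percent signal change.
#' @param rest_len_s Neutral-screen gap between blocks, seconds.
#' @param noise_sd Noise standard deviation in percent-of-baseline units.
#' @return An [fmri_dataset()] with attribute `block_design` describing the
#'   paradigm.
#' @export
simulate_block_design <- function(parc, conditions, block_len_s = 20,
                                  effect_map, seed = 1, n_runs = 1,
                                  run_len = 160, tr_s = 2, rest_len_s = 20,
                                  noise_sd = 1, baseline = 100) {
  if (length(conditions) < 2) abort("need at least 2 conditions")
  if (block_len_s %% tr_s != 0) {
    abort("block_len_s must be a multiple of tr_s")
  }
  effect_map <- as.matrix(effect_map)
  if (nrow(effect_map) != nrow(parc) ||
      ncol(effect_map) != length(conditions)) {
    abort("effect_map must be voxels x conditions")
  }
  X <- block_regressors(conditions, block_len_s, rest_len_s, run_len, tr_s)
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    signal_pct <- effect_map %*% t(X)            # voxels x T, percent units
    noise <- matrix(rnorm(nrow(parc) * run_len, sd = noise_sd), nrow(parc))
    baseline * (1 + (signal_pct + noise) / 100)
  })
  ds <- fmri_dataset(do.call(cbind, runs), tr_s = tr_s,
                     run_lengths = rep(run_len, n_runs),
                     voxel_ids = parc$voxel_id)
  attr(ds, "block_design") <- list(conditions = conditions,
                                   block_len_s = block_len_s,
                                   rest_len_s = rest_len_s)
  add_provenance(ds, "simulate_block_design",
                 list(conditions = conditions, seed = seed))
}
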