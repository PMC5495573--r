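#' Smoothed white-noise dataset (instrumentation null)
#'
#' Generates i.i.d. Gaussian noise on the parcellation's voxel grid and
#' smooths each timepoint spatially with a Gaussian kernel of the given
#' FWHM, emulating the intrinsic spatial spread of the fMRI signal with no
#' neural structure at all. Hemisphere blocks in the synthetic layout are
#' separated by far more than the kernel width, so smoothing can never
#' induce cross-hemisphere correlation.
#'
#' @param parc Parcellation.
#' @param n_runs,run_len Run structure.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 3.5).
#' @param seed Integer seed.
#' @param tr_s Repetition time, seconds.
#' @param baseline Additive offset so mean-normalization behaves as for
#'   real data.
#' @return An [fmri_dataset()].
#' @export
simulate_noise_volume <- function(parc, n_runs = 1, run_len = 150,
                                  fwhm_mm = 3.5, seed = 1, tr_s = 2,
                                  baseline = 100) {
  if (fwhm_mm <= 0) abort("fwhm_mm must be > 0")
  W <- smoothing_weights(parc, fwhm_mm)
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    W %*% matrix(rnorm(nrow(parc) * run_len), nrow(parc))
  })
  ds <- fmri_dataset(do.call(cbind, runs) + baseline, tr_s = tr_s,
                     run_lengths = rep(run_len, n_runs),
                     voxel_ids = parc$voxel_id)
  add_provenance(ds, "simulate_noise_volume",
                 list(fwhm_mm = fwhm_mm, seed = seed))
}

# expected correlation between two voxels after kernel smoothing, from the
# actual (row-normalized, truncated) weight matrix: corr = <w_i, w_j> /
# (|w_i||w_j|). Used as the independent oracle in tests.
smoothed_noise_corr <- function(W, i, j) {
  sum(W[i, ] * W[j, ]) / sqrt(sum(W[i, ]^2) * sum(W[j, ]^2))
}

#' Instrumentation/preprocessing correlation null
#'
#' Passes smoothed white noise through the same preprocessing and areal
#' correlation path as real data, `n_reps` times, and summarizes what
#' correlation structure sampling and analysis alone can produce:
#' across-hemisphere area-pair correlations (should be centered on zero) and
#' within-hemisphere correlations split into cortically adjacent versus
#' distal pairs (smoothing induces correlation only between spatial
#' neighbors).
#'
#' @param n_reps Replicates.
#' @param parc Parcellation.
#' @param pipeline_cfg Config list passed to [run_preprocess()].
#' @param seed Integer seed (replicate r uses `seed + r - 1`).
#' @param n_runs,run_len,fwhm_mm Passed to [simulate_noise_volume()].
#' @param n_iter Subsample iterations for the correlation stage.
#' @param adjacency Area adjacency for the within-hemisphere grouping.
#' @param preprocess Apply the preprocessing pipeline (default TRUE).
#' @return A list of class `null_summary`: `summary` tibble (group, mean,
#'   sd, 95% interval, n), `per_rep` tibble, and `fwhm_mm`.
#' @export
run_null_pipeline <- function(n_reps = 5, parc, pipeline_cfg = list(),
                              seed = 1, n_runs = 2, run_len = 150,
                              fwhm_mm = 3.5, n_iter = 20,
                              adjacency = default_area_adjacency(),
                              preprocess = TRUE) {
  reps <- purrr::map_dfr(seq_len(n_reps), function(rep) {
    ds <- simulate_noise_volume(parc, n_runs, run_len, fwhm_mm,
                                seed = seed + rep - 1)
    if (preprocess) ds <- run_preprocess(ds, nuisance_set(), pipeline_cfg)
    ac <- area_matrix(ds, parc, "across_hemi", n_iter = n_iter,
                      seed = seed + rep - 1)
    wi <- area_matrix(ds, parc, "within_hemi", hemi = "left",
                      n_iter = n_iter, seed = seed + rep - 1)
    across <- group_homotopic_pairs(ac, adjacency)
    within <- group_homotopic_pairs(
      new_corr_matrix(wi$values, wi$row_ids, wi$col_ids, wi$df,
                      "within_hemi", wi$thresholds), adjacency) |>
      dplyr::filter(.data$group != "homotopic")
    dplyr::bind_rows(
      dplyr::mutate(across, scope = "across_hemi", rep = rep),
      dplyr::mutate(within, scope = "within_hemi", rep = rep))
  })
  summary <- reps |>
    dplyr::mutate(group = ifelse(.data$scope == "across_hemi",
                                 "across_hemi",
                                 paste0("within_", .data$group))) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = sd(.data$r),
                     q02.5 = quantile(.data$r, 0.025),
                     q97.5 = quantile(.data$r, 0.975),
                     n = dplyr::n(), .groups = "drop")
  structure(list(summary = summary, per_rep = reps, fwhm_mm = fwhm_mm,
                 n_reps = n_reps),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> %d replicate(s), %.1f mm FWHM\n", x$n_reps,
              x$fwhm_mm))
  print(x$summary)
  invisible(x)
}

#' Write a null summary as JSON
#'
#' @param x A `null_summary`.
#' @param path Output path.
#' @export
write_null_summary_json <- function(x, path) {
  jsonlite::write_json(list(fwhm_mm = x$fwhm_mm, n_reps = x$n_reps,
                            summary = x$summary),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
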