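#' Construct an fMRI time-series dataset
#'
#' A lightweight container for a voxels-by-timepoints data matrix with its
#' repetition time and run boundaries. All preprocessing and correlation
#' functions take and return this class.
#'
#' @param data Numeric matrix, voxels x timepoints.
#' @param tr_s Repetition time in seconds (default 2).
#' @param run_lengths Integer vector of timepoints per run; must sum to
#'   `ncol(data)` and every run must have at least 10 timepoints.
#' @param voxel_ids Optional integer voxel ids (defaults to row order).
#' @return An object of class `fmri_dataset`.
#' @export
fmri_dataset <- function(data, tr_s = 2, run_lengths = ncol(data),
                         voxel_ids = NULL) {
  data <- as.matrix(data)
  run_lengths <- as.integer(run_lengths)
  if (sum(run_lengths) != ncol(data)) {
    abort(sprintf("run_lengths sum to %d but data has %d timepoints",
                  sum(run_lengths), ncol(data)))
  }
  if (any(run_lengths < 10)) {
    abort("every run must have at least 10 timepoints")
  }
  if (!is.numeric(tr_s) || tr_s <= 0) abort("tr_s must be a positive number")
  structure(
    list(data = data, tr_s = tr_s, run_lengths = run_lengths,
         voxel_ids = voxel_ids %||% seq_len(nrow(data)),
         provenance = list()),
    class = "fmri_dataset")
}

#' @export
print.fmri_dataset <- function(x, ...) {
  cat(sprintf("<fmri_dataset> %d voxels x %d timepoints, TR %g s, %d run(s) [%s]\n",
              nrow(x$data), ncol(x$data), x$tr_s, length(x$run_lengths),
              paste(x$run_lengths, collapse = ", ")))
  if (length(x$provenance) > 0) {
    cat("  steps:", paste(vapply(x$provenance, `[[`, "", "step"),
                          collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.fmri_dataset <- function(x) dim(x$data)

# column index ranges of each run
run_index <- function(ds) {
  ends <- cumsum(ds$run_lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  Map(seq, starts, ends)
}

# apply fn(matrix_chunk, run_number) per run and stitch the results back
map_runs <- function(ds, fn) {
  idx <- run_index(ds)
  pieces <- lapply(seq_along(idx), function(r) fn(ds$data[, idx[[r]], drop = FALSE], r))
  out <- ds
  out$data <- do.call(cbind, pieces)
  out$run_lengths <- vapply(pieces, ncol, integer(1))
  out
}

add_provenance <- function(ds, step, params = list()) {
  ds$provenance <- c(ds$provenance, list(list(step = step, params = params)))
  ds
}

#' Convert a dataset to a long tibble
#'
#' One row per voxel-timepoint, for plotting or dplyr-style summaries. Use on
#' small datasets only.
#'
#' @param x An `fmri_dataset`.
#' @param ... Unused.
#' @return A tibble with `voxel_id`, `run`, `t`, `time_s`, `value`.
#' @export
as_tibble.fmri_dataset <- function(x, ...) {
  run <- rep(seq_along(x$run_lengths), x$run_lengths)
  tibble(
    voxel_id = rep(x$voxel_ids, times = ncol(x$data)),
    run = rep(run, each = nrow(x$data)),
    t = rep(seq_len(ncol(x$data)), each = nrow(x$data)),
    time_s = rep((seq_len(ncol(x$data)) - 1) * x$tr_s, each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

#' Write / read a dataset as 4-D NIfTI
#'
#' Voxels are placed into the bounding grid of the parcellation's integer-mm
#' coordinates; grid cells with no voxel are zero. A sidecar TSV written next
#' to the image records run lengths so the dataset round-trips.
#'
#' @param ds An `fmri_dataset`.
#' @param parc The matching `parcellation` (row order = dataset row order).
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `write_dataset_nifti` returns `path` invisibly.
#' @export
write_dataset_nifti <- function(ds, parc, path) {
  stopifnot(nrow(parc) == nrow(ds$data))
  # dense-rank the coordinates so every voxel gets its own grid cell even
  # when positions are fractional; the same parcellation indexes the read
  xi <- as.integer(factor(parc$x))
  yi <- as.integer(factor(parc$y))
  zi <- as.integer(factor(parc$z))
  arr <- array(0, dim = c(max(xi), max(yi), max(zi), ncol(ds$data)))
  for (t in seq_len(ncol(ds$data))) {
    arr[cbind(xi, yi, zi, t)] <- ds$data[, t]
  }
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, ds$tr_s))
  RNifti::writeNifti(img, path)
  meta <- data.frame(run = seq_along(ds$run_lengths),
                     run_length = ds$run_lengths, tr_s = ds$tr_s)
  utils::write.table(meta, paste0(path, ".runs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_nifti
#' @export
read_dataset_nifti <- function(path, parc) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- utils::read.delim(paste0(path, ".runs.tsv"), sep = "\t")
  xi <- as.integer(factor(parc$x))
  yi <- as.integer(factor(parc$y))
  zi <- as.integer(factor(parc$z))
  nt <- dim(arr)[4]
  data <- matrix(0, nrow(parc), nt)
  for (t in seq_len(nt)) {
    slice <- arr[, , , t]
    data[, t] <- slice[cbind(xi, yi, zi)]
  }
  fmri_dataset(data, tr_s = meta$tr_s[1], run_lengths = meta$run_length,
               voxel_ids = parc$voxel_id)
}
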