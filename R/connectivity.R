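#' Statistical thresholds for correlation maps
#'
#' @param r_thresh Pearson-r threshold for voxel inclusion (default 0.15).
#' @param alpha Two-tailed significance level.
#' @param fdr_q False-discovery-rate level for voxelwise maps.
#' @return A list of class `stat_thresholds`.
#' @export
stat_thresholds <- function(r_thresh = 0.15, alpha = 1e-4, fdr_q = 1e-4) {
  if (r_thresh < 0 || r_thresh >= 1) abort("r_thresh must be in [0, 1)")
  structure(list(r_thresh = r_thresh, alpha = alpha, fdr_q = fdr_q),
            class = "stat_thresholds")
}

#' Convert a Pearson r to a t statistic
#'
#' `t = r * sqrt(df / (1 - r^2))`, the usual significance conversion for a
#' correlation with `df` degrees of freedom.
#'
#' @param r Pearson correlation(s), `|r| < 1`.
#' @param df Degrees of freedom (>= 1).
#' @return t statistic(s).
#' @examples
#' r_to_t(0.15, 1628)  # 6.12
#' @export
r_to_t <- function(r, df) {
  if (any(abs(r) >= 1)) abort("|r| must be < 1")
  if (any(df < 1)) abort("df must be >= 1")
  r * sqrt(df / (1 - r^2))
}

#' Two-tailed critical t value
#'
#' @param alpha Two-tailed significance level in (0, 1).
#' @param df Degrees of freedom.
#' @return Upper-tail critical value at `alpha / 2`.
#' @examples
#' t_critical(0.05, 782)  # 1.96
#' @export
t_critical <- function(alpha, df) {
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must be in (0, 1)")
  qt(1 - alpha / 2, df)
}

#' Benjamini-Hochberg selection mask
#'
#' Step-up FDR control at level `q`.
#'
#' @param pvals Vector of p values.
#' @param q FDR level.
#' @return Logical mask, TRUE for selected entries; empty input gives an
#'   empty mask.
#' @export
fdr_mask <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  p.adjust(pvals, method = "BH") <= q
}

# --- balanced subsampled group means ---------------------------------------

# groups: named list of row-index vectors into ds$data. Returns a list of
# n_iter matrices (groups x T), each from one subsample of min group size.
# Equal-sized groups make every iteration the full-group mean.
subsample_group_means <- function(ds, groups, n_iter, seed) {
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) {
    abort(paste0("empty group(s): ",
                 paste(names(groups)[sizes == 0], collapse = ", ")))
  }
  m <- min(sizes)
  if (all(sizes == m)) {
    one <- t(vapply(groups, function(ix)
      colMeans(ds$data[ix, , drop = FALSE]), numeric(ncol(ds$data))))
    rownames(one) <- names(groups)
    return(rep(list(one), 1L))      # one iteration suffices: no-op subsample
  }
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    out <- t(vapply(groups, function(ix) {
      sub <- if (length(ix) == m) ix else sample(ix, m)
      colMeans(ds$data[sub, , drop = FALSE])
    }, numeric(ncol(ds$data))))
    rownames(out) <- names(groups)
    out
  })
}

# drop voxels flagged by normalize_to_mean from group index lists
drop_flagged <- function(ds, groups) {
  flagged <- attr(ds, "flagged_voxels")
  if (is.null(flagged) || length(flagged) == 0) return(groups)
  lapply(groups, function(ix) setdiff(ix, flagged))
}

# Pearson r between rows of A (groups x T) and rows of B, averaged as raw r
# over the iteration list(s). B may be a plain matrix (e.g., voxel series).
iter_corr <- function(A_list, B_list) {
  n <- max(length(A_list), length(B_list))
  acc <- NULL
  for (i in seq_len(n)) {
    A <- A_list[[min(i, length(A_list))]]
    B <- B_list[[min(i, length(B_list))]]
    r <- suppressWarnings(cor(t(A), t(B)))
    acc <- if (is.null(acc)) r else acc + r
  }
  acc / n
}

area_groups <- function(ds, parc, hemi, areas = visual_areas()) {
  rows <- which(parc$hemisphere == hemi & parc$area %in% areas)
  split(rows, factor(parc$area[rows], levels = areas))
}

#' Balanced area mean time series
#'
#' For each requested area, voxels are subsampled without replacement to the
#' smallest area's size and averaged; `n_iter` subsamples are drawn so that
#' downstream correlations can be computed per iteration and averaged as raw
#' r. When all areas have equal size the subsample is a no-op and a single
#' iteration is returned.
#'
#' @param ds A preprocessed [fmri_dataset()].
#' @param parc Parcellation matching the dataset rows.
#' @param hemi `"left"` or `"right"`.
#' @param areas Area labels (default all 16).
#' @param n_iter Subsample iterations (default 100).
#' @param seed Integer seed for the subsampling.
#' @return A 3-d array `areas x timepoints x iterations`.
#' @export
area_mean_timeseries <- function(ds, parc, hemi = "left",
                                 areas = visual_areas(), n_iter = 100,
                                 seed = 1) {
  groups <- drop_flagged(ds, area_groups(ds, parc, hemi, areas))
  mats <- subsample_group_means(ds, groups, n_iter, seed)
  arr <- array(unlist(mats),
               dim = c(length(groups), ncol(ds$data), length(mats)),
               dimnames = list(names(groups), NULL, NULL))
  arr
}

# --- correlation matrix container ------------------------------------------

new_corr_matrix <- function(values, row_ids, col_ids, df, scope,
                            thresholds = stat_thresholds()) {
  dimnames(values) <- list(row_ids, col_ids)
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 df = df, scope = scope, thresholds = thresholds),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d x %d (%s), df = %d\n", nrow(x$values),
              ncol(x$values), x$scope, x$df))
  invisible(x)
}

#' Tidy a correlation matrix into long format
#'
#' @param x A `corr_matrix`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `r`, `t`, `df`.
#' @export
tidy.corr_matrix <- function(x, ...) {
  out <- tidyr::expand_grid(row = x$row_ids, col = x$col_ids) |>
    dplyr::arrange(match(.data$row, x$row_ids))
  out$r <- as.vector(t(x$values))
  out$t <- ifelse(abs(out$r) < 1, r_to_t(pmin(pmax(out$r, -1 + 1e-12),
                                              1 - 1e-12), x$df), Inf)
  out$df <- x$df
  out
}

#' @export
glance.corr_matrix <- function(x, ...) {
  tibble(scope = x$scope, n_row = nrow(x$values), n_col = ncol(x$values),
         df = x$df, mean_r = mean(x$values, na.rm = TRUE),
         n_na = sum(is.na(x$values)))
}

#' Write a correlation matrix as TSV
#'
#' @param M A `corr_matrix`.
#' @param path File path.
#' @export
write_corr_matrix_tsv <- function(M, path) {
  df <- data.frame(row_id = M$row_ids, M$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

warn_constant <- function(values) {
  if (anyNA(values)) warn("constant series produced NaN correlation entries")
  values
}

#' Area-by-area correlation matrix
#'
#' Pearson correlations between balanced area mean signals over the
#' concatenated runs. `within_hemi` correlates the 16 areas of `hemi` with
#' each other (symmetric, unit diagonal); `across_hemi` correlates left-area
#' means (rows) with right-area means (columns). Correlations are computed
#' per subsample iteration and averaged as raw r; the recorded degrees of
#' freedom are `T - 2`.
#'
#' @inheritParams area_mean_timeseries
#' @param scope `"within_hemi"` or `"across_hemi"`.
#' @param hemi Hemisphere for the within-hemisphere scope.
#' @param thresholds A [stat_thresholds()].
#' @return A `corr_matrix`.
#' @export
area_matrix <- function(ds, parc, scope = c("within_hemi", "across_hemi"),
                        hemi = "left", thresholds = stat_thresholds(),
                        n_iter = 100, seed = 1) {
  scope <- match.arg(scope)
  df <- ncol(ds$data) - 2L
  if (scope == "within_hemi") {
    g <- drop_flagged(ds, area_groups(ds, parc, hemi))
    mats <- subsample_group_means(ds, g, n_iter, seed)
    vals <- warn_constant(iter_corr(mats, mats))
    M <- new_corr_matrix(vals, names(g), names(g), df, scope, thresholds)
  } else {
    gl <- drop_flagged(ds, area_groups(ds, parc, "left"))
    gr <- drop_flagged(ds, area_groups(ds, parc, "right"))
    # joint subsampling balances all 32 groups to the common minimum size
    both <- c(setNames(gl, paste0("L.", names(gl))),
              setNames(gr, paste0("R.", names(gr))))
    mats <- subsample_group_means(ds, both, n_iter, seed)
    li <- seq_along(gl); ri <- length(gl) + seq_along(gr)
    vals <- warn_constant(
      iter_corr(lapply(mats, function(m) m[li, , drop = FALSE]),
                lapply(mats, function(m) m[ri, , drop = FALSE])))
    M <- new_corr_matrix(vals, names(gl), names(gr), df, scope, thresholds)
  }
  M
}

#' Area-to-contralateral-voxel correlation map
#'
#' Correlates the balanced mean signal of each seed area in `seed_hemi` with
#' every voxel of the opposite hemisphere.
#'
#' @inheritParams area_matrix
#' @param seed_hemi Hemisphere providing the 16 seed areas.
#' @return A `corr_matrix` with 16 rows (seed areas) and one column per
#'   contralateral voxel (column ids are voxel ids).
#' @export
area_voxel_map <- function(ds, parc, seed_hemi = "left",
                           thresholds = stat_thresholds(), n_iter = 100,
                           seed = 1) {
  other <- setdiff(c("left", "right"), seed_hemi)
  g <- drop_flagged(ds, area_groups(ds, parc, seed_hemi))
  mats <- subsample_group_means(ds, g, n_iter, seed)
  vox <- which(parc$hemisphere == other)
  V <- ds$data[vox, , drop = FALSE]
  vals <- warn_constant(iter_corr(mats, list(V)))
  new_corr_matrix(vals, names(g), parc$voxel_id[vox],
                  ncol(ds$data) - 2L, "across_hemi", thresholds)
}
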