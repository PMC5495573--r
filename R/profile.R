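#' Areal correlation profile (second-order similarity)
#'
#' Correlates each seed area's within-hemisphere correlation profile (its row
#' of the 16 x 16 area-by-area matrix, self-correlation of 1 included) with
#' each contralateral voxel's across-hemisphere correlation profile (its
#' column of the 16 x V area-by-voxel matrix). The result is a 16 x V map of
#' profile similarities, masked so that cell (i, v) is reported only where
#' the underlying raw temporal correlation `A[i, v]` exceeds the r threshold.
#'
#' @param W Within-hemisphere 16 x 16 `corr_matrix` (unit diagonal); its
#'   hemisphere must be contralateral to the voxels in `A`.
#' @param A Across-hemisphere 16 x V `corr_matrix` from [area_voxel_map()].
#' @param thresholds A [stat_thresholds()]; `r_thresh` gates the mask.
#' @param method `"pearson"` (default) or `"spearman"` profile correlation.
#' @return An object of class `profile_map`: list with `similarity`
#'   (16 x V, `NA` where masked or degenerate), `raw` (unmasked values),
#'   `mask`, and ids.
#' @export
areal_correlation_profile <- function(W, A,
                                      thresholds = stat_thresholds(),
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(W$row_ids, A$row_ids)) {
    abort("W and A must be indexed by the same seed areas, in the same order")
  }
  if (max(abs(diag(W$values) - 1)) > 1e-8) {
    abort("W must have a unit diagonal (self-correlations included)")
  }
  Wm <- W$values
  Am <- A$values
  if (method == "spearman") {
    Wm <- t(apply(Wm, 1, rank))
    Am <- apply(Am, 2, rank)
  }
  # cor() of the 16-entry profiles, vectorized over voxels
  sim <- suppressWarnings(cor(t(Wm), Am))
  mask <- A$values > thresholds$r_thresh
  out <- sim
  out[!mask] <- NA_real_
  structure(list(similarity = out, raw = sim, mask = mask,
                 seed_ids = W$row_ids, voxel_ids = A$col_ids,
                 thresholds = thresholds, method = method),
            class = "profile_map")
}

#' @export
print.profile_map <- function(x, ...) {
  cat(sprintf("<profile_map> %d seeds x %d voxels; %.1f%% voxels pass r > %g\n",
              nrow(x$similarity), ncol(x$similarity),
              100 * mean(colSums(x$mask) > 0), x$thresholds$r_thresh))
  invisible(x)
}

#' @export
tidy.profile_map <- function(x, ...) {
  tibble(seed = rep(x$seed_ids, times = ncol(x$similarity)),
         voxel_id = rep(x$voxel_ids, each = nrow(x$similarity)),
         similarity = as.vector(x$similarity),
         raw = as.vector(x$raw),
         passed = as.vector(x$mask))
}

#' Best-matching seed area per voxel
#'
#' For each contralateral voxel with at least one unmasked cell, the seed
#' area with the largest profile similarity.
#'
#' @param pm A `profile_map`.
#' @return Tibble with `voxel_id`, `best_area`, `similarity`.
#' @export
profile_argmax <- function(pm) {
  ok <- colSums(!is.na(pm$similarity)) > 0
  idx <- apply(pm$similarity[, ok, drop = FALSE], 2, which.max)
  tibble(voxel_id = pm$voxel_ids[ok],
         best_area = pm$seed_ids[idx],
         similarity = vapply(seq_along(idx), function(j)
           pm$similarity[idx[j], which(ok)[j]], numeric(1)))
}

#' Group across-hemisphere area pairs
#'
#' Symmetrizes the 16 x 16 across-hemisphere matrix over direction (the
#' left-V1/right-MT value is averaged with left-MT/right-V1), then classifies
#' every unordered pair: `homotopic` (same area), `adjacent` (cortical
#' neighbors of a homotopic pair), `distal` (everything else). The 16 + 120
#' values partition all 136 unordered pairs.
#'
#' @param M Across-hemisphere 16 x 16 `corr_matrix`.
#' @param adjacency Edge list from [default_area_adjacency()].
#' @return Tibble with `area_a`, `area_b`, `r`, `group`.
#' @export
group_homotopic_pairs <- function(M, adjacency = default_area_adjacency()) {
  areas <- M$row_ids
  if (!setequal(unique(c(adjacency$area_a, adjacency$area_b)),
                intersect(unique(c(adjacency$area_a, adjacency$area_b)),
                          areas))) {
    abort("adjacency table names areas absent from the matrix")
  }
  pairs <- tidyr::expand_grid(ai = seq_along(areas), bi = seq_along(areas)) |>
    dplyr::filter(.data$ai <= .data$bi)
  pairs |>
    dplyr::mutate(
      area_a = areas[.data$ai], area_b = areas[.data$bi],
      r = (M$values[cbind(.data$ai, .data$bi)] +
             M$values[cbind(.data$bi, .data$ai)]) / 2,
      group = dplyr::case_when(
        .data$area_a == .data$area_b ~ "homotopic",
        areas_adjacent(.data$area_a, .data$area_b, adjacency) ~ "adjacent",
        TRUE ~ "distal")) |>
    dplyr::select("area_a", "area_b", "r", "group")
}

#' Dorsal/ventral quadrant correlation matrix
#'
#' Across-hemisphere correlations between the dorsal and ventral quadrant
#' mean signals of areas V1, V2, V3, V4, V4A (10 left cells x 10 right
#' cells), computed with the same balanced subsampling as [area_matrix()].
#' The companion grouping table classifies each unordered symmetrized cell
#' pair as `corresponding` (dorsal:dorsal or ventral:ventral) or
#' `non_corresponding`, and marks pairs involving the same or cortically
#' adjacent areas so the contrast can be read with adjacent pairs excluded.
#'
#' @inheritParams area_matrix
#' @param adjacency Edge list used for the adjacent-pair flag.
#' @return A list of class `quadrant_result`: `matrix` (10 x 10
#'   `corr_matrix`) and `groups` (tibble with `area_a`, `quad_a`, `area_b`,
#'   `quad_b`, `r`, `correspondence`, `homotopic`, `adjacent_pair`).
#' @export
quadrant_matrix <- function(ds, parc, thresholds = stat_thresholds(),
                            n_iter = 100, seed = 1,
                            adjacency = default_area_adjacency()) {
  qa <- quadrant_areas()
  sel <- parc$area %in% qa
  if (any(parc$quadrant[sel] == "none")) {
    abort("missing quadrant labels on V1-V4A voxels")
  }
  cell_groups <- function(hemi) {
    rows <- which(parc$hemisphere == hemi & sel)
    lab <- paste(parc$area[rows], parc$quadrant[rows], sep = ".")
    lev <- as.vector(t(outer(qa, c("dorsal", "ventral"), paste, sep = ".")))
    split(rows, factor(lab, levels = lev))
  }
  gl <- drop_flagged(ds, cell_groups("left"))
  gr <- drop_flagged(ds, cell_groups("right"))
  both <- c(setNames(gl, paste0("L.", names(gl))),
            setNames(gr, paste0("R.", names(gr))))
  mats <- subsample_group_means(ds, both, n_iter, seed)
  li <- seq_along(gl); ri <- length(gl) + seq_along(gr)
  vals <- warn_constant(
    iter_corr(lapply(mats, function(m) m[li, , drop = FALSE]),
              lapply(mats, function(m) m[ri, , drop = FALSE])))
  M <- new_corr_matrix(vals, names(gl), names(gr), ncol(ds$data) - 2L,
                       "across_hemi", thresholds)

  cells <- names(gl)
  parts <- strsplit(cells, ".", fixed = TRUE)
  area <- vapply(parts, `[[`, "", 1)
  quad <- vapply(parts, `[[`, "", 2)
  groups <- tidyr::expand_grid(ai = seq_along(cells),
                               bi = seq_along(cells)) |>
    dplyr::filter(.data$ai <= .data$bi) |>
    dplyr::mutate(
      area_a = area[.data$ai], quad_a = quad[.data$ai],
      area_b = area[.data$bi], quad_b = quad[.data$bi],
      r = (M$values[cbind(.data$ai, .data$bi)] +
             M$values[cbind(.data$bi, .data$ai)]) / 2,
      correspondence = ifelse(.data$quad_a == .data$quad_b,
                              "corresponding", "non_corresponding"),
      homotopic = .data$area_a == .data$area_b,
      adjacent_pair = .data$area_a == .data$area_b |
        areas_adjacent(.data$area_a, .data$area_b, adjacency)) |>
    dplyr::select("area_a", "quad_a", "area_b", "quad_b", "r",
                  "correspondence", "homotopic", "adjacent_pair")
  structure(list(matrix = M, groups = groups), class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  m <- x$groups |>
    dplyr::group_by(.data$correspondence) |>
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop")
  cat("<quadrant_result> 10 x 10 across-hemisphere quadrant matrix\n")
  print(m)
  invisible(x)
}
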