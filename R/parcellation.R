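#' The 16 retinotopic seed areas
#'
#' Visual field maps across occipital, temporal, and parietal cortex used as
#' seed areas throughout the package: V1-V4A and OTd on the ventral/occipital
#' route, the posterior inferotemporal areas (PITv, PITd, OTS), the MT cluster
#' (MT, MST, FST, V4t), and the dorsal areas V3A/DP, CIP, LIP. Smaller maps
#' that are routinely merged for seed analyses (V3A with DP, CIP1 with CIP2,
#' OTS1 with OTS2) appear as single labels.
#'
#' @return Character vector of the 16 area labels, in canonical
#'   posterior-to-anterior order.
#' @export
visual_areas <- function() {
  c("V1", "V2", "V3", "V4", "V4A", "OTd", "PITv", "PITd", "OTS",
    "MT", "MST", "FST", "V4t", "V3A/DP", "CIP", "LIP")
}

#' Areas carrying dorsal/ventral quadrant labels
#'
#' The posterior areas whose dorsal and ventral halves represent the lower and
#' upper contralateral visual quadrants, and which enter the quadrant
#' (checkerboard) analysis.
#'
#' @return Character vector of area labels.
#' @export
quadrant_areas <- function() c("V1", "V2", "V3", "V4", "V4A")

#' Default adjacency between the 16 seed areas
#'
#' Cortical neighbor relations used to classify area pairs as adjacent versus
#' distal to a homotopic pair. The table ships as a plain TSV in
#' `inst/extdata/area_adjacency.tsv` so it can be inspected, edited, and
#' versioned; this function reads it and returns a symmetric edge list.
#'
#' @param path Optional path to an alternative two-column TSV (`area_a`,
#'   `area_b`).
#' @return A tibble with columns `area_a`, `area_b`, one row per unordered
#'   neighbor pair.
#' @export
default_area_adjacency <- function(path = NULL) {
  path <- path %||% system.file("extdata", "area_adjacency.tsv",
                                package = "protoconn", mustWork = TRUE)
  adj <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("area_a", "area_b") %in% names(adj))) {
    abort("adjacency table must have columns area_a, area_b")
  }
  bad <- setdiff(unique(c(adj$area_a, adj$area_b)), visual_areas())
  if (length(bad) > 0) {
    abort(paste0("unknown area labels in adjacency table: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(adj$area_a == adj$area_b)) abort("self-neighbors are not allowed")
  as_tibble(adj[, c("area_a", "area_b")])
}

#' Test whether two areas are neighbors
#'
#' @param a,b Character vectors of area labels (recycled).
#' @param adjacency Edge list from [default_area_adjacency()].
#' @return Logical vector.
#' @export
areas_adjacent <- function(a, b, adjacency = default_area_adjacency()) {
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")
  keys <- key(adjacency$area_a, adjacency$area_b)
  key(a, b) %in% keys
}

#' Build a synthetic two-hemisphere parcellation
#'
#' Lays out two mirror-symmetric hemispheres of 16 visual areas on a 1 mm
#' voxel grid. Areas are stacked posterior-to-anterior along y in canonical
#' order (so cortical neighbors in the layout are plausible spatial
#' neighbors), hemispheres occupy disjoint x blocks separated by `hemi_gap_mm`
#' so that spatial smoothing can never bridge them. Within every area, voxels
#' span the eccentricity axis evenly in cortical distance; eccentricity runs
#' 0-`max_ecc_deg` degrees linearly in cortical distance (cortical
#' magnification is deliberately not modeled, see the methods vignette).
#' Areas V1-V4A are split into dorsal and ventral quadrants along z.
#'
#' @param n_voxels_per_area Voxels per area per hemisphere (>= 8).
#' @param n_ecc_bands Number of eccentricity bands used for latent-signal
#'   assignment (>= 2).
#' @param seed Integer seed, accepted for interface uniformity; the layout is
#'   deterministic.
#' @param max_ecc_deg Largest represented eccentricity, degrees.
#' @param hemi_gap_mm Gap between the hemisphere blocks along x (mm).
#' @param area_gap_mm Gap between consecutive area blocks along y (mm).
#' @return A tibble of class `parcellation` with columns `voxel_id`,
#'   `hemisphere`, `area`, `quadrant`, `eccentricity_deg`,
#'   `cortical_distance`, `ecc_band`, `x`, `y`, `z`.
#' @examples
#' parc <- make_parcellation(16, 8, seed = 1)
#' nrow(parc)  # 16 areas x 2 hemispheres x 16 voxels = 512
#' @export
make_parcellation <- function(n_voxels_per_area, n_ecc_bands = 8, seed = 1,
                              max_ecc_deg = 10, hemi_gap_mm = 30,
                              area_gap_mm = 2) {
  if (!is.numeric(n_voxels_per_area) || n_voxels_per_area < 8) {
    abort("n_voxels_per_area must be a number >= 8")
  }
  if (!is.numeric(n_ecc_bands) || n_ecc_bands < 2) {
    abort("n_ecc_bands must be a number >= 2")
  }
  n <- as.integer(n_voxels_per_area)
  nb <- as.integer(n_ecc_bands)
  areas <- visual_areas()
  qareas <- quadrant_areas()

  one_area <- function(area, area_idx) {
    i <- seq_len(n)
    # even spacing along the eccentricity (cortical-distance) axis
    cd <- (i - 0.5) / n
    len_y <- max(4, ceiling(n / 4))
    y0 <- (area_idx - 1) * (len_y + area_gap_mm)
    # z alternates voxel-by-voxel so both quadrants cover every band
    xcol <- ((i - 1) %/% 2) %% 2
    zcol <- (i - 1) %% 2
    quadrant <- if (area %in% qareas) {
      ifelse(zcol == 0, "dorsal", "ventral")
    } else {
      rep("none", n)
    }
    tibble(
      area = area,
      quadrant = quadrant,
      eccentricity_deg = max_ecc_deg * cd,
      cortical_distance = cd,
      ecc_band = pmin(ceiling(cd * nb), nb),
      x_local = xcol,
      y = y0 + cd * len_y,
      z = zcol
    )
  }

  block <- dplyr::bind_rows(
    lapply(seq_along(areas), function(k) one_area(areas[k], k))
  )
  both <- dplyr::bind_rows(
    dplyr::mutate(block, hemisphere = "left",
                  x = -(hemi_gap_mm / 2 + .data$x_local)),
    dplyr::mutate(block, hemisphere = "right",
                  x = hemi_gap_mm / 2 + .data$x_local)
  )
  parc <- both |>
    dplyr::mutate(voxel_id = dplyr::row_number()) |>
    dplyr::select("voxel_id", "hemisphere", "area", "quadrant",
                  "eccentricity_deg", "cortical_distance", "ecc_band",
                  "x", "y", "z")
  attr(parc, "n_ecc_bands") <- nb
  attr(parc, "max_ecc_deg") <- max_ecc_deg
  class(parc) <- c("parcellation", class(parc))
  parc
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d voxels, %d areas x 2 hemispheres, %d ecc bands\n",
              nrow(x), length(unique(x$area)), attr(x, "n_ecc_bands")))
  NextMethod()
}

#' Write / read a parcellation as TSV
#'
#' @param parc A [make_parcellation()] tibble.
#' @param path File path.
#' @return `write_parcellation_tsv` returns `path` invisibly;
#'   `read_parcellation_tsv` returns a `parcellation` tibble.
#' @export
write_parcellation_tsv <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation_tsv
#' @param n_ecc_bands Band count to restore (defaults to max of `ecc_band`).
#' @export
read_parcellation_tsv <- function(path, n_ecc_bands = NULL) {
  df <- as_tibble(utils::read.delim(path, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE))
  attr(df, "n_ecc_bands") <- n_ecc_bands %||% max(df$ecc_band)
  attr(df, "max_ecc_deg") <- max(df$eccentricity_deg)
  class(df) <- c("parcellation", class(df))
  df
}

# latent cell labels (hemisphere x area x quadrant x ecc band) for a parcellation
latent_cells <- function(parc) {
  paste(parc$hemisphere, parc$area, parc$quadrant, parc$ecc_band, sep = "|")
}

# the full set of cells in deterministic order
latent_cell_table <- function(n_ecc_bands) {
  areas <- visual_areas()
  rows <- list()
  for (h in c("left", "right")) {
    for (a in areas) {
      quads <- if (a %in% quadrant_areas()) c("dorsal", "ventral") else "none"
      for (q in quads) {
        for (b in seq_len(n_ecc_bands)) {
          rows[[length(rows) + 1]] <-
            tibble(hemisphere = h, area = a, quadrant = q, ecc_band = b)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$cell <- paste(out$hemisphere, out$area, out$quadrant, out$ecc_band,
                    sep = "|")
  out
}
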