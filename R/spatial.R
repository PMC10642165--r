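#' Extract the infiltrative tumour border
#'
#' The infiltrative border is the set of tumour pixels 8-adjacent to a
#' stroma, normal or background pixel. Tumour pixels touching only the
#' field edge are not part of the border: a biopsy cut is not an
#' infiltrative front, so intra-tumoural depth is never measured from it.
#'
#' @param mask a [region_mask()] containing at least one tumour pixel.
#' @return A `border_set`: data.frame of border pixel indices (`row`,
#'   `col`) and centre coordinates (`x_um`, `y_um`). Empty (zero rows)
#'   when the tumour only meets the field edge.
#' @export
extract_infiltrative_border <- function(mask) {
  lab <- mask$labels
  if (!any(lab == 1L)) stop_data("no tumour region in mask")
  nr <- nrow(lab); nc <- ncol(lab)
  # pad with tumour so the field edge never counts as non-tumour
  pad <- matrix(1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  non_tumour <- pad != 1L
  neigh <- matrix(FALSE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      neigh <- neigh | non_tumour[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    }
  }
  idx <- which(lab == 1L & neigh, arr.ind = TRUE)
  out <- data.frame(
    row = idx[, 1], col = idx[, 2],
    x_um = (idx[, 2] - 0.5) * mask$um_per_pixel,
    y_um = (idx[, 1] - 0.5) * mask$um_per_pixel
  )
  class(out) <- c("border_set", "data.frame")
  out
}

#' Depth of each cell from the infiltrative border
#'
#' Computes an exact Euclidean distance transform on the mask grid from the
#' border pixels, converts it to micrometres, and reads each cell's depth
#' at the pixel it falls in. Depth is only defined for intra-tumoural
#' cells; cells outside the tumour get `NA` (flagged, never zero).
#'
#' @param cells a [cell_table()].
#' @param border a `border_set` from [extract_infiltrative_border()].
#' @param mask the [region_mask()] the border was extracted from.
#' @return Numeric vector of per-cell depths in micrometres (`NA` outside
#'   the tumour).
#' @export
distance_to_border <- function(cells, border, mask) {
  if (nrow(border) == 0L) stop_data("empty border: depth undefined")
  dmap <- depth_map_um(mask, border)
  px <- cell_pixels(cells, mask)
  depth <- rep(NA_real_, nrow(cells))
  ok <- !is.na(px[, "row"])
  in_tumour <- ok
  in_tumour[ok] <- mask$labels[px[ok, , drop = FALSE]] == 1L
  depth[in_tumour] <- dmap[px[in_tumour, , drop = FALSE]]
  depth
}

# Distance (um) of every pixel to the nearest border pixel, via exact
# Euclidean distance transform (border pixels are the zero set).
depth_map_um <- function(mask, border) {
  seed <- matrix(1, nrow(mask$labels), ncol(mask$labels))
  seed[cbind(border$row, border$col)] <- 0
  as.matrix(EBImage::distmap(seed, metric = "euclidean")) * mask$um_per_pixel
}

#' Classify intra-tumoural cells into tumour core / tumour margin
#'
#' At threshold `d`, margin (TM) cells lie within `d` of the border
#' (`depth < d`) and core (TC) cells beyond it (`depth >= d`). A depth of
#' exactly `d` — unassigned by the strict inequalities defining the two
#' zones — goes to the core, so the zones always partition the tumour.
#'
#' @param depths per-cell depths from [distance_to_border()].
#' @param d zone threshold in micrometres (conventionally 50, 100 or 150).
#' @return Character vector in `{TC, TM, NA}` (NA outside the tumour).
#' @export
classify_tc_tm <- function(depths, d) {
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop_spec("threshold d must be a single non-negative number")
  }
  ifelse(is.na(depths), NA_character_, ifelse(depths < d, "TM", "TC"))
}

#' Tumour-core / tumour-margin proportion profile
#'
#' For each phenotype and distance band, the fraction of cells in the core
#' and margin zones. Two denominator conventions are supported and the one
#' used is recorded in the output:
#' \describe{
#'   \item{`zone`}{(default) cells of the phenotype in the zone over all
#'     cells in that zone — the zone's phenotype composition.}
#'   \item{`phenotype`}{cells of the phenotype in the zone over all
#'     intra-tumoural cells of that phenotype — so `p_TM + p_TC = 1` per
#'     phenotype and `p_TM` grows with the band width.}
#' }
#' Proportions for an empty zone are `NA` (flagged missing, never 0).
#'
#' @param cells a [cell_table()].
#' @param depths per-cell depths from [distance_to_border()].
#' @param thresholds distance bands in micrometres (default 50/100/150).
#' @param denominator `"zone"` or `"phenotype"`.
#' @return A `data.frame` with columns `phenotype, d_um, zone, count,
#'   denominator_n, proportion, convention`.
#' @export
margin_profile <- function(cells, depths,
                           thresholds = c(50, 100, 150),
                           denominator = c("zone", "phenotype")) {
  denominator <- match.arg(denominator)
  if (any(thresholds < 0)) stop_spec("thresholds must be non-negative")
  keep <- !is.na(depths)
  if (!any(keep)) stop_data("no intra-tumoural cells: margin profile undefined")
  phen <- cells$phenotype[keep]
  dep <- depths[keep]
  phen_levels <- sort(unique(phen))
  rows <- list()
  for (d in thresholds) {
    zone <- classify_tc_tm(dep, d)
    for (z in c("TM", "TC")) {
      in_zone <- zone == z
      n_zone <- sum(in_zone)
      for (p in phen_levels) {
        cnt <- sum(in_zone & phen == p)
        den <- if (denominator == "zone") n_zone else sum(phen == p)
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = p, d_um = d, zone = z, count = cnt,
          denominator_n = den,
          proportion = if (den > 0) cnt / den else NA_real_,
          convention = denominator
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("margin_profile", "data.frame")
  out
}

#' Cell densities per compartment and phenotype
#'
#' Density is the matching cell count divided by the compartment area in
#' mm^2 (pixel count times squared pixel size). Rows for a zero-area
#' compartment are flagged missing rather than reported as zero.
#'
#' @param cells a [cell_table()] with compartments assigned (see
#'   [assign_compartment()]; assigned on the fly when absent).
#' @param mask a [region_mask()].
#' @param compartments,phenotypes subsets to report (defaults: all tissue
#'   compartments, all panel phenotypes present plus absent ones at 0).
#' @return A `data.frame` with columns `compartment, phenotype, count,
#'   area_mm2, density_cells_per_mm2`.
#' @export
compute_density <- function(cells, mask,
                            compartments = c("tumour", "stroma", "normal"),
                            phenotypes = c("CD8", "FoxP3", "CD163", "other")) {
  if (is.null(cells$compartment)) {
    cells <- suppressMessages(assign_compartment(cells, mask))
  }
  rows <- list()
  for (comp in compartments) {
    area <- compartment_area_mm2(mask, comp)
    for (p in phenotypes) {
      cnt <- sum(cells$compartment == comp & cells$phenotype == p)
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = comp, phenotype = p, count = cnt,
        area_mm2 = area,
        density_cells_per_mm2 = if (area > 0) cnt / area else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("density_table", "data.frame")
  out
}

#' Ratio of two cell densities
#'
#' The anti/pro-tumour balance (e.g. CD8 over CD163 density). When the
#' denominator is zero with a positive numerator the ratio is `Inf`
#' (classed "high" at any finite cutoff); when both are zero it is
#' undefined (`NA`).
#'
#' @param density_a,density_b non-negative densities.
#' @return `density_a / density_b` with the conventions above.
#' @export
cell_ratio <- function(density_a, density_b) {
  if (any(density_a < 0, na.rm = TRUE) || any(density_b < 0, na.rm = TRUE)) {
    stop_spec("densities must be non-negative")
  }
  out <- density_a / density_b
  out[density_a == 0 & density_b == 0] <- NA_real_
  out
}

#' Dichotomize values at a fixed cutoff
#'
#' Used for density ratios (cutoff 1) and PD-L1 area positivity
#' (cutoff 1 percent): `"high"` strictly above the cutoff, `"low"` at or
#' below, `NA` stays `NA`.
#'
#' @param x numeric values (may contain `Inf` from [cell_ratio()]).
#' @param cutoff the dichotomization threshold.
#' @return Character vector in `{high, low, NA}`.
#' @export
dichotomize_at <- function(x, cutoff = 1) {
  ifelse(is.na(x), NA_character_, ifelse(x > cutoff, "high", "low"))
}

#' PD-L1 area positivity of a compartment
#'
#' Percentage of the compartment's area whose pixels are marker-positive.
#'
#' @param marker logical (or 0/1) matrix of marker-positive pixels, same
#'   geometry as the mask grid.
#' @param mask a [region_mask()].
#' @param compartment compartment to assess.
#' @return Percentage in `[0, 100]`; `NA` for a zero-area compartment.
#' @export
pdl1_area_positivity <- function(marker, mask, compartment = "tumour") {
  if (!identical(dim(marker), dim(mask$labels))) {
    stop_spec("marker mask geometry does not match region mask")
  }
  code <- compartment_codes()[[match.arg(compartment, names(compartment_codes()))]]
  in_comp <- mask$labels == code
  if (!any(in_comp)) return(NA_real_)
  100 * sum(marker[in_comp] != 0) / sum(in_comp)
}
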