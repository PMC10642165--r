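#' Per-cell spatial table
#'
#' One row per segmented cell with its centroid in micrometres, its
#' phenotype call and (optionally) the tissue compartment it sits in.
#' Phenotypes use the panel vocabulary `CD8`, `FoxP3`, `CD163`, `other`;
#' compartments come from the mask vocabulary.
#'
#' @param cell_id unique cell identifiers (coerced to character).
#' @param x_um,y_um centroid coordinates in micrometres, image convention
#'   (y grows downward), same origin as the region mask.
#' @param phenotype phenotype labels.
#' @param compartment optional compartment labels; derive them from a mask
#'   with [assign_compartment()] when absent.
#' @return A `data.frame` of class `cell_table`.
#' @export
cell_table <- function(cell_id, x_um, y_um, phenotype, compartment = NULL) {
  phen_vocab <- c("CD8", "FoxP3", "CD163", "other")
  comp_vocab <- c("tumour", "stroma", "normal", "background")
  cell_id <- as.character(cell_id)
  n <- length(cell_id)
  if (anyDuplicated(cell_id)) stop_spec("cell_id values must be unique")
  if (length(phenotype) == 1L && n > 1L) phenotype <- rep(phenotype, n)
  if (!is.null(compartment) && length(compartment) == 1L && n > 1L) {
    compartment <- rep(compartment, n)
  }
  if (length(x_um) != n || length(y_um) != n || length(phenotype) != n) {
    stop_spec("cell_table columns must have equal length")
  }
  if (!all(is.finite(x_um)) || !all(is.finite(y_um))) {
    stop_spec("cell coordinates must be finite")
  }
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% phen_vocab)) {
    stop_spec("phenotype must be one of: ", paste(phen_vocab, collapse = ", "))
  }
  out <- data.frame(
    cell_id = cell_id,
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    phenotype = phenotype,
    stringsAsFactors = FALSE
  )
  if (!is.null(compartment)) {
    compartment <- as.character(compartment)
    if (length(compartment) != n || !all(compartment %in% comp_vocab)) {
      stop_spec("compartment must match cell count and the mask vocabulary")
    }
    out$compartment <- compartment
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Map cells to the mask pixel they fall in
#'
#' Returns row/column indices using `floor(coord / um_per_pixel)`; cells
#' outside the grid get `NA` indices.
#'
#' @param cells a [cell_table()].
#' @param mask a [region_mask()].
#' @return A two-column integer matrix (`row`, `col`), one row per cell.
#' @keywords internal
cell_pixels <- function(cells, mask) {
  row <- floor(cells$y_um / mask$um_per_pixel) + 1
  col <- floor(cells$x_um / mask$um_per_pixel) + 1
  bad <- row < 1 | row > nrow(mask$labels) | col < 1 | col > ncol(mask$labels)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Assign compartments to cells from the mask
#'
#' Cells falling on background (or outside the grid) are dropped with a
#' message, mirroring how segmented objects outside annotated tissue are
#' excluded from downstream quantification.
#'
#' @inheritParams cell_pixels
#' @param drop_background drop background/off-grid cells (default `TRUE`).
#' @return The cell table with a filled `compartment` column.
#' @export
assign_compartment <- function(cells, mask, drop_background = TRUE) {
  px <- cell_pixels(cells, mask)
  lab <- rep(NA_integer_, nrow(cells))
  ok <- !is.na(px[, "row"])
  lab[ok] <- mask$labels[px[ok, , drop = FALSE]]
  comp <- names(compartment_codes())[match(lab, compartment_codes())]
  cells$compartment <- comp
  if (drop_background) {
    drop <- is.na(comp) | comp == "background"
    if (any(drop)) {
      message(sum(drop), " cell(s) on background or off-grid excluded")
      cells <- cells[!drop, , drop = FALSE]
    }
  }
  cells
}

#' Read / write a cell table CSV
#'
#' Expected columns: `cell_id, x_um, y_um, phenotype[, compartment]`.
#'
#' @param path CSV path.
#' @return A [cell_table()].
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um", "phenotype")
  if (!all(need %in% names(df))) {
    stop_data("cells CSV must have columns: ", paste(need, collapse = ", "))
  }
  cell_table(df$cell_id, df$x_um, df$y_um, df$phenotype,
             if ("compartment" %in% names(df)) df$compartment)
}

#' @rdname read_cells_csv
#' @param cells a [cell_table()].
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}
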