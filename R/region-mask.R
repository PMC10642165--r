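#' Labelled tissue region mask
#'
#' A `region_mask` couples an integer label grid with its physical scale.
#' Labels follow the fixed vocabulary 0 = background, 1 = tumour,
#' 2 = stroma, 3 = normal epithelium. The grid uses image convention:
#' rows run down the y axis, columns along the x axis, and the physical
#' origin (0, 0) sits at the top-left corner of pixel `[1, 1]`.
#'
#' @param labels integer matrix of region labels in `{0, 1, 2, 3}`.
#' @param um_per_pixel physical side length of one pixel in micrometres.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, um_per_pixel) {
  if (!is.matrix(labels)) stop_spec("labels must be a matrix")
  lab <- as.integer(labels)
  if (anyNA(lab) || any(!lab %in% 0:3)) {
    stop_spec("mask labels must be integers in {0 background, 1 tumour, 2 stroma, 3 normal}")
  }
  if (!is.numeric(um_per_pixel) || length(um_per_pixel) != 1L || um_per_pixel <= 0) {
    stop_spec("um_per_pixel must be a single positive number")
  }
  structure(
    list(labels = matrix(lab, nrow(labels), ncol(labels)),
         um_per_pixel = as.numeric(um_per_pixel)),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  dims <- dim(x$labels)
  cat(sprintf(
    "<region_mask> %d x %d px @ %.3g um/px (%.3g x %.3g um)\n",
    dims[1], dims[2], x$um_per_pixel,
    dims[2] * x$um_per_pixel, dims[1] * x$um_per_pixel
  ))
  tab <- table(factor(x$labels, 0:3, c("background", "tumour", "stroma", "normal")))
  for (nm in names(tab)) cat(sprintf("  %-10s %d px\n", nm, tab[[nm]]))
  invisible(x)
}

#' Compartment label codes
#'
#' @return Named integer vector mapping compartment names to mask codes.
#' @export
compartment_codes <- function() {
  c(background = 0L, tumour = 1L, stroma = 2L, normal = 3L)
}

#' Area of one compartment in square millimetres
#'
#' @param mask a [region_mask()].
#' @param compartment one of `"tumour"`, `"stroma"`, `"normal"`, `"background"`.
#' @return Area in mm^2.
#' @export
compartment_area_mm2 <- function(mask, compartment) {
  code <- compartment_codes()[[match.arg(compartment, names(compartment_codes()))]]
  sum(mask$labels == code) * (mask$um_per_pixel / 1000)^2
}

#' Write / read a region mask as TIFF plus a JSON scale sidecar
#'
#' The mask is stored as an 8-bit grey TIFF holding the raw label codes;
#' the micrometre-per-pixel scale travels in `<path>.json`.
#'
#' @param mask a [region_mask()].
#' @param path output TIFF path.
#' @return `write_mask_tiff` returns `path` invisibly; `read_mask` returns
#'   a [region_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(list(um_per_pixel = mask$um_per_pixel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param um_per_pixel scale override; when `NULL` the sidecar
#'   `<path>.json` must exist.
#' @export
read_mask <- function(path, um_per_pixel = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_spec("unsupported mask format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (is.null(um_per_pixel)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop_data("no um_per_pixel given and sidecar not found: ", sidecar)
    }
    um_per_pixel <- jsonlite::read_json(sidecar)$um_per_pixel
  }
  region_mask(round(img * 255), um_per_pixel)
}

#' Rasterize GeoJSON region polygons into a mask
#'
#' Accepts a GeoJSON FeatureCollection of polygons whose `label` property
#' is one of `tumour`, `stroma`, `normal`, `background`; coordinates are in
#' micrometres in the image frame (x right, y down). Pixels are assigned by
#' even-odd containment of their centres; later features overwrite earlier
#' ones, so list holes/islands after their surroundings.
#'
#' @param path GeoJSON file path.
#' @param um_per_pixel pixel size of the target grid.
#' @param width_um,height_um physical extent of the target grid.
#' @param background_label label for uncovered pixels (default `"stroma"`).
#' @return A [region_mask()].
#' @export
read_mask_geojson <- function(path, um_per_pixel, width_um, height_um,
                              background_label = "stroma") {
  gj <- jsonlite::read_json(path)
  codes <- compartment_codes()
  nx <- max(1L, as.integer(round(width_um / um_per_pixel)))
  ny <- max(1L, as.integer(round(height_um / um_per_pixel)))
  lab <- matrix(codes[[background_label]], ny, nx)
  px <- (seq_len(nx) - 0.5) * um_per_pixel
  py <- (seq_len(ny) - 0.5) * um_per_pixel
  for (feat in gj$features) {
    label <- feat$properties$label
    if (is.null(label) || !label %in% names(codes)) {
      stop_spec("GeoJSON feature lacks a valid 'label' property")
    }
    geom <- feat$geometry
    if (!identical(geom$type, "Polygon")) {
      stop_spec("only Polygon geometries are supported")
    }
    inside <- matrix(FALSE, ny, nx)
    for (ring in geom$coordinates) {
      vx <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      vy <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      inside <- xor(inside, points_in_ring(px, py, vx, vy))
    }
    lab[inside] <- codes[[label]]
  }
  region_mask(lab, um_per_pixel)
}

# Even-odd ray casting for a pixel-centre grid against one polygon ring.
points_in_ring <- function(px, py, vx, vy) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) n <- n - 1L
  inside <- matrix(FALSE, length(py), length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    if (yi != yj) {
      rows <- which((py < yi) != (py < yj))
      if (length(rows)) {
        xcross <- vx[i] + (py[rows] - yi) / (yj - yi) * (vx[j] - vx[i])
        inside[rows, ] <- xor(inside[rows, ], outer(xcross, px, `>`))
      }
    }
    j <- i
  }
  inside
}
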