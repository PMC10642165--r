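# Spatial contexture: border extraction, depth, TC/TM zones, densities.

test_that("infiltrative border is the tumour-nontumour interface", {
  mask <- disc_mask()
  border <- extract_infiltrative_border(mask)
  expect_gt(nrow(border), 0)
  # every border pixel is tumour and 8-adjacent to a non-tumour pixel
  lab <- mask$labels
  for (i in seq_len(nrow(border))) {
    r <- border$row[i]; cc <- border$col[i]
    expect_equal(lab[r, cc], 1L)
    neigh <- lab[max(1, r - 1):min(nrow(lab), r + 1),
                 max(1, cc - 1):min(ncol(lab), cc + 1)]
    expect_true(any(neigh != 1L))
  }

  # tumour filling the whole field touches only the biopsy edge: no border
  full <- region_mask(matrix(1L, 20, 20), 10)
  expect_equal(nrow(extract_infiltrative_border(full)), 0)

  # no tumour at all is an error
  expect_error(extract_infiltrative_border(region_mask(matrix(2L, 5, 5), 10)),
               class = "tmectx_data_error")
})

test_that("border of two disjoint blobs is the union of their perimeters", {
  lab <- matrix(2L, 80, 80)
  d2a <- outer((1:80 - 20)^2, (1:80 - 20)^2, `+`)
  d2b <- outer((1:80 - 60)^2, (1:80 - 60)^2, `+`)
  whole <- lab; whole[d2a <= 100 | d2b <= 100] <- 1L
  only_a <- lab; only_a[d2a <= 100] <- 1L
  only_b <- lab; only_b[d2b <= 100] <- 1L
  key <- function(b) sort(paste(b$row, b$col))
  expect_identical(
    key(extract_infiltrative_border(region_mask(whole, 10))),
    sort(c(key(extract_infiltrative_border(region_mask(only_a, 10))),
           key(extract_infiltrative_border(region_mask(only_b, 10)))))
  )
})

test_that("depth matches analytic distances on a square tumour", {
  lab <- matrix(2L, 140, 140)
  lab[21:120, 21:120] <- 1L # 1000 x 1000 um tumour at 10 um/px
  mask <- region_mask(lab, 10)
  border <- extract_infiltrative_border(mask)
  cells <- cell_table(c("centre", "edge", "outside"),
                      x_um = c(700, 205, 50), y_um = c(700, 700, 50),
                      phenotype = c("CD8", "CD8", "CD8"))
  d <- distance_to_border(cells, border, mask)
  half_diag <- 10 * sqrt(2) / 2
  # border pixel centres sit half a pixel inside the continuous tumour
  # edge, so the centre cell's nearest border point is at 495 um, not 500
  expect_lt(abs(d[1] - 495), half_diag + 1e-9)
  expect_lt(d[2], half_diag + 1e-9) # cell on the border
  expect_true(is.na(d[3]))          # outside tumour: flagged, not zero
})

test_that("grid depth agrees with the exhaustive nearest-point oracle", {
  set.seed(202)
  for (rep in 1:20) {
    mask <- disc_mask(n_px = 40 + sample(0:20, 1),
                      radius_px = 8 + sample(0:6, 1),
                      um_per_pixel = sample(c(5, 10, 20), 1))
    border <- extract_infiltrative_border(mask)
    extent <- nrow(mask$labels) * mask$um_per_pixel
    cells <- cell_table(sprintf("c%d", 1:100),
                        x_um = runif(100, 0, extent - 1e-6),
                        y_um = runif(100, 0, extent - 1e-6),
                        phenotype = "CD8")
    d <- distance_to_border(cells, border, mask)
    oracle <- brute_force_depth(cells, border)
    in_tum <- !is.na(d)
    half_diag <- mask$um_per_pixel * sqrt(2) / 2
    expect_true(all(abs(d[in_tum] - oracle[in_tum]) <= half_diag + 1e-9))
  }
})

test_that("TC/TM classification applies the core-closed tie rule", {
  expect_equal(classify_tc_tm(49.9, 50), "TM")
  expect_equal(classify_tc_tm(50.0, 50), "TC") # exact threshold goes to core
  expect_equal(classify_tc_tm(c(200, 200, 200), 50), rep("TC", 3))
  expect_equal(classify_tc_tm(200, 100), "TC")
  expect_equal(classify_tc_tm(200, 150), "TC")
  expect_true(is.na(classify_tc_tm(NA, 50)))
  expect_error(classify_tc_tm(10, -5), class = "tmectx_spec_error")
})

test_that("zones partition intra-tumoural cells and nest across bands", {
  set.seed(31)
  mask <- disc_mask(n_px = 80, radius_px = 30)
  border <- extract_infiltrative_border(mask)
  cells <- cell_table(sprintf("c%d", 1:400),
                      x_um = runif(400, 0, 799), y_um = runif(400, 0, 799),
                      phenotype = sample(c("CD8", "other"), 400, TRUE))
  d <- distance_to_border(cells, border, mask)
  n_tum <- sum(!is.na(d))
  zones <- lapply(c(50, 100, 150), function(th) classify_tc_tm(d, th))
  for (z in zones) {
    expect_equal(sum(z == "TM", na.rm = TRUE) + sum(z == "TC", na.rm = TRUE),
                 n_tum)
  }
  tm_sets <- lapply(zones, function(z) which(!is.na(z) & z == "TM"))
  expect_true(all(tm_sets[[1]] %in% tm_sets[[2]]))
  expect_true(all(tm_sets[[2]] %in% tm_sets[[3]]))
})

test_that("margin profile matches the hand-counted 6-cell example", {
  cells <- cell_table(sprintf("c%d", 1:6),
                      x_um = 1:6, y_um = 1:6,
                      phenotype = c("CD8", "CD8", "CD8", "other", "other", "other"))
  depths <- c(10, 60, 200, 20, 70, 160)
  prof <- margin_profile(cells, depths, thresholds = 50, denominator = "zone")
  get <- function(p, z) prof$proportion[prof$phenotype == p & prof$zone == z]
  expect_equal(get("CD8", "TM"), 0.5) # TM = {10, 20}: 1 CD8 of 2
  expect_equal(get("CD8", "TC"), 0.5) # TC has 2 CD8 of 4

  # all-CD8 margin
  all_cd8 <- cell_table("x", 1, 1, "CD8")
  p1 <- margin_profile(all_cd8, 10, thresholds = 50)
  expect_equal(p1$proportion[p1$zone == "TM"], 1)
  # empty zone flagged missing, not zero
  expect_true(is.na(p1$proportion[p1$zone == "TC"]))
})

test_that("phenotype-marginal proportions sum to one and grow with the band", {
  set.seed(8)
  cells <- cell_table(sprintf("c%d", 1:200), runif(200), runif(200),
                      sample(c("CD8", "CD163", "other"), 200, TRUE))
  depths <- runif(200, 0, 300)
  prof <- margin_profile(cells, depths, denominator = "phenotype")
  for (p in unique(prof$phenotype)) {
    for (d in c(50, 100, 150)) {
      sub <- prof[prof$phenotype == p & prof$d_um == d, ]
      expect_equal(sum(sub$proportion), 1)
    }
    tm <- prof[prof$phenotype == p & prof$zone == "TM", ]
    tm <- tm[order(tm$d_um), ]
    expect_true(all(diff(tm$proportion) >= 0))
  }
})

test_that("densities are count over area and scale with the mask", {
  # 50 cells on a known 0.5 mm^2 compartment
  lab <- matrix(2L, 100, 100)
  lab[1:50, 1:100] <- 1L # 5000 px at 10 um/px = 0.5 mm^2
  mask <- region_mask(lab, 10)
  set.seed(4)
  cells <- cell_table(sprintf("c%d", 1:50),
                      x_um = runif(50, 0, 999), y_um = runif(50, 0, 499),
                      phenotype = "CD8")
  dens <- compute_density(cells, mask)
  row <- dens[dens$compartment == "tumour" & dens$phenotype == "CD8", ]
  expect_equal(row$count, 50)
  expect_equal(row$area_mm2, 0.5)
  expect_equal(row$density_cells_per_mm2, 100)
  # zero matches, zero-area compartment
  expect_equal(dens$density_cells_per_mm2[dens$phenotype == "FoxP3" &
                                            dens$compartment == "tumour"], 0)
  expect_true(is.na(dens$density_cells_per_mm2[dens$compartment == "normal"][1]))
  # additivity: phenotype counts sum to the compartment total
  tum <- dens[dens$compartment == "tumour", ]
  expect_equal(sum(tum$count), sum(cells$y_um < 500))
  # density = count / area exactly, and scales as 1/area under rescaling
  mask2 <- region_mask(lab, 20) # same grid, 4x area
  cells2 <- cell_table(cells$cell_id, cells$x_um, cells$y_um, cells$phenotype,
                       compartment = rep("tumour", 50))
  dens2 <- compute_density(cells2, mask2)
  row2 <- dens2[dens2$compartment == "tumour" & dens2$phenotype == "CD8", ]
  expect_equal(row2$density_cells_per_mm2, row$density_cells_per_mm2 / 4)
})

test_that("cell ratios follow the high/low conventions", {
  expect_equal(cell_ratio(120, 60), 2)
  expect_true(is.na(cell_ratio(0, 0)))
  expect_equal(cell_ratio(30, 0), Inf)
  expect_error(cell_ratio(-1, 5), class = "tmectx_spec_error")
  expect_equal(dichotomize_at(cell_ratio(30, 60), 1), "low")
  expect_equal(dichotomize_at(cell_ratio(30, 0), 1), "high")
  expect_true(is.na(dichotomize_at(NA, 1)))
})

test_that("PD-L1 area positivity is an exact pixel fraction", {
  mask <- region_mask(matrix(1L, 20, 20), 10)
  none <- matrix(FALSE, 20, 20)
  all_pos <- matrix(TRUE, 20, 20)
  checker <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0)
  expect_equal(pdl1_area_positivity(none, mask, "tumour"), 0)
  expect_equal(pdl1_area_positivity(all_pos, mask, "tumour"), 100)
  expect_equal(pdl1_area_positivity(checker, mask, "tumour"), 50)
  expect_error(pdl1_area_positivity(matrix(TRUE, 5, 5), mask, "tumour"),
               class = "tmectx_spec_error")
})

test_that("stroma outranks tumour density on the immune-excluded archetype", {
  spec <- tissue_spec(
    field_width_um = 800, field_height_um = 800, um_per_pixel = 10,
    tumour_geometry = list(shape = "disc", radius_um = 250)
  )
  dens <- t(vapply(seq_len(40), function(s) {
    tis <- generate_tissue(spec, "myeloid_treg", s)
    d <- compute_density(tis$cells, tis$mask)
    c(tum = d$density_cells_per_mm2[d$compartment == "tumour" & d$phenotype == "CD163"],
      str = d$density_cells_per_mm2[d$compartment == "stroma" & d$phenotype == "CD163"])
  }, c(tum = 0, str = 0)))
  wt <- wilcoxon_test(dens[, "str"], dens[, "tum"])
  expect_lt(wt$p, 0.05)
  expect_gt(median(dens[, "str"]), median(dens[, "tum"]))
})

test_that("masks round-trip through TIFF with their scale sidecar", {
  mask <- disc_mask(n_px = 30, radius_px = 10, um_per_pixel = 12.5)
  path <- tempfile(fileext = ".tiff")
  write_mask_tiff(mask, path)
  back <- read_mask(path)
  expect_identical(back$labels, mask$labels)
  expect_equal(back$um_per_pixel, 12.5)
})

test_that("GeoJSON polygons rasterize to the expected compartments", {
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(label = "tumour"),
      geometry = list(type = "Polygon", coordinates = list(
        list(list(100, 100), list(300, 100), list(300, 300), list(100, 300),
             list(100, 100))
      ))
    ))
  )
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  mask <- read_mask_geojson(path, um_per_pixel = 10, width_um = 400,
                            height_um = 400)
  # 200 x 200 um square of tumour = 20 x 20 px
  expect_equal(sum(mask$labels == 1L), 400)
  expect_equal(compartment_area_mm2(mask, "tumour"), 0.04)
  expect_equal(mask$labels[15, 15], 1L)
  expect_equal(mask$labels[5, 5], 2L)
})
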