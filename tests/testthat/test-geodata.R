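test_that("raster write/read round trip is exact, nodata honoured", {
  g <- grid_spec(3, 3, 29, xmin = 1000, ymax = 2000)
  m <- matrix(c(1, 1, 1, 1, NA, 1, 1, 1, pi), 3, 3)
  r <- value_raster(m, g)
  path <- file.path(withr::local_tempdir(), "r.asc")
  write_raster(r, path)
  r2 <- read_raster(path, type = "value")
  expect_identical(r2$values, m)          # bit-for-bit, including the NA
  expect_equal(sum(is.na(r2$values)), 1L)
  expect_equal(r2$grid$cellsize, 29)
  expect_equal(r2$grid$xmin, 1000)
  expect_equal(r2$grid$ymax, 2000)

  ones <- value_raster(matrix(1, 3, 3), g)
  p2 <- file.path(withr::local_tempdir(), "ones.asc")
  write_raster(ones, p2)
  expect_equal(sum(!is.na(read_raster(p2)$values)), 9)
})

test_that("categorical rasters round trip with legend and overlays", {
  g <- grid_spec(4, 4, 29)
  codes <- matrix(rep(1:2, each = 8), 4, 4)
  ov <- matrix(FALSE, 4, 4); ov[1:2, 1:2] <- TRUE
  cr <- categorical_raster(codes, g, c("1" = "forest", "2" = "water"),
                           overlays = list(park = ov))
  path <- file.path(withr::local_tempdir(), "lulc.asc")
  write_raster(cr, path)
  cr2 <- read_raster(path)
  expect_s3_class(cr2, "categorical_raster")
  expect_identical(cr2$codes, codes)
  expect_equal(unname(cr2$legend[["1"]]), "forest")
  expect_identical(cr2$overlays$park, ov)
})

test_that("read_raster rejects missing files and geographic CRS", {
  expect_error(read_raster("no/such/file.asc"), "not found")
  g <- grid_spec(2, 2, 0.001, crs = "GEOGCS[\"WGS 84\",UNIT[\"degree\",0.017]]")
  path <- file.path(withr::local_tempdir(), "geo.asc")
  write_raster(value_raster(matrix(1, 2, 2), g), path)
  expect_error(read_raster(path), "geographic")
})

test_that("zonal_sum matches the stated examples", {
  g <- grid_spec(3, 3, 29)
  ones <- value_raster(matrix(1, 3, 3), g)
  expect_equal(zonal_sum(ones, matrix(TRUE, 3, 3)), 9)
  vals <- value_raster(matrix(1:9, 3, 3, byrow = TRUE), g)
  top_row <- rowcol_cell(rep(1, 3), 1:3, g)
  expect_equal(zonal_sum(vals, top_row), 6)   # 1 + 2 + 3
  masked <- value_raster(matrix(NA_real_, 3, 3), g)
  expect_equal(zonal_sum(masked, top_row), 0) # all-nodata zone
  expect_error(zonal_sum(ones, 99L), "outside")
})

test_that("zonal_sum equals brute-force summation on random zones", {
  set.seed(7)
  g <- grid_spec(50, 50, 29)
  for (rep in 1:4) {
    m <- matrix(runif(2500), 50, 50)
    m[sample(2500, 100)] <- NA
    r <- value_raster(m, g)
    for (z in 1:25) {
      cells <- sample(2500, sample(1:400, 1))
      brute <- 0
      for (cl in cells) if (!is.na(m[cl])) brute <- brute + m[cl]
      expect_equal(zonal_sum(r, cells), brute)
    }
  }
})

test_that("polygon zones select cells by centre point", {
  g <- grid_spec(4, 4, 10)
  # square covering the centres of the top-left 2x2 block (edges kept off the
  # cell centres: membership is a pure centre-in-polygon test)
  geom <- list(list(cbind(x = c(0, 24, 24, 0), y = c(40, 40, 16, 16))))
  cells <- rasterize_geom(geom, g)
  expect_setequal(cells, rowcol_cell(c(1, 1, 2, 2), c(1, 2, 1, 2), g))
  r <- value_raster(matrix(1:16, 4, 4), g)
  expect_equal(zonal_sum(r, geom), sum(r$values[cells]))
})

test_that("connected components: adjacency semantics and partition", {
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- m[2, 2] <- TRUE                 # touching only diagonally
  expect_equal(connected_components(m, "queen")$n, 1)
  expect_equal(connected_components(m, "rook")$n, 2)
  expect_equal(connected_components(matrix(TRUE, 4, 4))$n, 1)
  expect_equal(lengths(connected_components(matrix(TRUE, 4, 4))$components), 16)
  expect_equal(connected_components(matrix(FALSE, 3, 3))$n, 0)

  set.seed(11)
  for (adj in c("queen", "rook")) for (rep in 1:5) {
    mask <- matrix(runif(400) < 0.45, 20, 20)
    cc <- connected_components(mask, adj)
    # partition: labels cover exactly the mask, components disjoint
    expect_setequal(unlist(cc$components), which(mask))
    expect_equal(sum(lengths(cc$components)), sum(mask))
    expect_false(anyDuplicated(unlist(cc$components)) > 0)
    # same partition as an independent flood fill
    oracle <- oracle_components(mask, adj)
    expect_equal(cc$n, max(oracle))
    relab <- table(cc$labels[mask], oracle[mask])
    expect_true(all(rowSums(relab > 0) == 1), info = "labels map 1:1")
  }
})

test_that("polygonize areas equal cell count x cell area", {
  g <- grid_spec(6, 6, 29)
  single <- polygonize(list(rowcol_cell(2, 2, g)), g)
  expect_equal(geom_area(single$geoms[[1]]), 841)          # 29 x 29
  block <- polygonize(list(rowcol_cell(c(2, 2, 3, 3), c(2, 3, 2, 3), g)), g)
  expect_equal(geom_area(block$geoms[[1]]), 4 * 841)
  expect_length(block$geoms[[1]], 1)                       # one single polygon
  lshape <- polygonize(list(rowcol_cell(c(2, 3, 3), c(2, 2, 3), g)), g)
  expect_equal(geom_area(lshape$geoms[[1]]), 3 * 841)
  expect_length(lshape$geoms[[1]], 1)
  expect_length(lshape$geoms[[1]][[1]], 1)                 # no holes

  set.seed(3)
  for (rep in 1:5) {
    mask <- matrix(runif(144) < 0.4, 12, 12)
    g2 <- grid_spec(12, 12, 29)
    cc <- connected_components(mask)
    layer <- polygonize(cc$components, g2)
    for (i in seq_along(layer$ids)) {
      expect_equal(geom_area(layer$geoms[[i]]) / 29^2,
                   length(cc$components[[i]]), tolerance = 1e-9)
      # round trip: rasterizing the polygon recovers exactly its cells
      expect_setequal(rasterize_geom(layer$geoms[[i]], g2), cc$components[[i]])
    }
  }
})

test_that("polygon layers round trip through GeoJSON", {
  g <- grid_spec(8, 8, 29)
  cc <- connected_components(matrix(runif(64) < 0.4, 8, 8))
  layer <- polygonize(cc$components, g,
                      attrs = data.frame(val = seq_along(cc$components)))
  path <- file.path(withr::local_tempdir(), "layer.geojson")
  write_polygons(layer, path)
  back <- read_polygons(path)
  expect_equal(length(back), length(layer))
  expect_equal(back$attrs$val, layer$attrs$val)
  for (i in seq_along(layer$ids))
    expect_setequal(rasterize_geom(back$geoms[[i]], g), cc$components[[i]])
})

test_that("align_rasters resamples onto the target grid", {
  g <- grid_spec(4, 4, 29)
  r <- value_raster(matrix(runif(16), 4, 4), g)
  expect_identical(align_rasters(r, g), r)  # already aligned: unchanged

  coarse <- grid_spec(2, 2, 58, xmin = 0, ymax = 4 * 29)
  const <- value_raster(matrix(5, 2, 2), coarse)
  fine <- align_rasters(const, g)
  expect_true(all(fine$values == 5))        # constant field stays constant

  # categorical: nearest neighbour only emits codes from the input legend
  src <- categorical_raster(matrix(rep(c(1L, 2L), 8), 4, 4), g,
                            c("1" = "a", "2" = "b"))
  shifted <- grid_spec(4, 4, 29, xmin = 14.5, ymax = 4 * 29 - 14.5)
  out <- align_rasters(src, shifted)
  expect_true(all(out$codes[!is.na(out$codes)] %in% 1:2))
  expect_s3_class(out, "categorical_raster")

  far <- grid_spec(4, 4, 29, xmin = 1e6, ymax = 1e6)
  expect_error(align_rasters(r, far), "disjoint")
})
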