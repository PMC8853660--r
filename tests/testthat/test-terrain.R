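test_that("fill_depressions raises pits to their pour points", {
  g <- grid_spec(5, 5, 29)
  m <- matrix(9, 5, 5)
  m[2:4, 2:4] <- 5
  m[3, 3] <- 1           # single-cell pit inside a ring of 5s
  m[5, 3] <- 2           # low boundary cell the ring drains over
  filled <- fill_depressions(value_raster(m, g))
  expect_equal(filled$values[3, 3], 5)  # raised to the ring's pour level
  expect_true(all(filled$values >= m))

  tilted <- value_raster(outer(1:5, 1:5, function(r, c) r + 2 * c), g)
  expect_equal(fill_depressions(tilted)$values, tilted$values)  # unchanged

  expect_error(fill_depressions(value_raster(matrix(NA_real_, 3, 3),
                                             grid_spec(3, 3))), "no data")
})

test_that("every filled cell keeps a non-ascending exit path", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 25
    dem <- make_dem(sim_config(nrow = n, ncol = n, seed = rep,
                               noise_sd = 8))   # rough terrain, many pits
    filled <- fill_depressions(dem)
    z <- filled$values
    expect_true(all(z >= dem$values))
    # grow the drainable set from the boundary: a cell drains if some
    # neighbour of equal-or-lower elevation drains
    drain <- matrix(FALSE, n, n)
    drain[1, ] <- drain[n, ] <- drain[, 1] <- drain[, n] <- TRUE
    repeat {
      grew <- FALSE
      for (r in 2:(n - 1)) for (c in 2:(n - 1)) {
        if (drain[r, c]) next
        nb <- expand.grid(r = r + (-1:1), c = c + (-1:1))
        ok <- any(drain[cbind(nb$r, nb$c)] & z[cbind(nb$r, nb$c)] <= z[r, c])
        if (ok) { drain[r, c] <- TRUE; grew <- TRUE }
      }
      if (!grew) break
    }
    expect_true(all(drain))
  }
})

test_that("resistance costs are distance-corrected and climb-asymmetric", {
  g <- grid_spec(2, 2, 29)
  flat <- build_resistance(value_raster(matrix(1, 2, 2), g), strategy = "climb")
  i <- rowcol_cell(1, 1, g); j <- rowcol_cell(1, 2, g); d <- rowcol_cell(2, 2, g)
  expect_equal(conductance(flat, i, j), conductance(flat, j, i)) # symmetric
  expect_equal(conductance(flat, i, j), 1 / 29)
  # diagonal moves penalized by the sqrt(2) distance factor
  expect_equal(conductance(flat, i, d), 1 / (29 * sqrt(2)))

  drop1 <- value_raster(matrix(c(1, 1, 0, 0), 2, 2), g)  # 1 m drop to col 2
  s <- build_resistance(drop1, strategy = "climb", k = 1)
  expect_gt(conductance(s, i, j), conductance(s, j, i))  # downhill easier
  expect_equal(1 / conductance(s, j, i), 29 * (1 + 1))   # dist x (1 + k dz)

  bad <- value_raster(matrix(c(1, Inf, 1, 1), 2, 2), g)
  expect_error(build_resistance(bad), "non-finite")
})

test_that("least-cost paths match examples and an explicit-graph oracle", {
  g <- grid_spec(1, 5, 29)
  strip <- build_resistance(value_raster(matrix(5:1, 1, 5), g))
  p <- lcp_path(strip, 1, 5)
  expect_equal(p$cells, 1:5)                # all 5 cells of the strip

  set.seed(17)
  for (rep in 1:6) {
    n <- 9
    dem <- value_raster(matrix(runif(n * n, 0, 30), n, n), grid_spec(n, n, 29))
    dem <- fill_depressions(dem, eps = 1e-6)
    for (strat in c("climb", "downslope")) {
      s <- build_resistance(dem, strategy = strat)
      start <- sample(n * n, 1); goal <- sample(setdiff(seq_len(n * n), start), 1)
      got <- lcp_path(s, start, goal)
      expect_equal(got$cost, oracle_dijkstra(s, start, goal), tolerance = 1e-9)
      expect_false(anyDuplicated(got$cells) > 0)
      expect_equal(got$cells[1], start)
      expect_equal(got$cells[length(got$cells)], goal)
    }
  }
})

test_that("paths are reproducible run to run", {
  dem <- fill_depressions(make_dem(sim_config(nrow = 40, ncol = 40, seed = 9)),
                          eps = 1e-6)
  s <- build_resistance(dem)
  p1 <- lcp_path(s, 1555, 40)
  p2 <- lcp_path(s, 1555, 40)
  expect_identical(p1, p2)
})

test_that("LCP on a noise-free cone matches the D8 steepest-descent trace", {
  dem <- cone_dem(21)
  eps <- fill_depressions(dem, eps = 1e-6)
  rec <- d8_receivers(eps)
  s <- build_resistance(eps)
  g <- dem$grid
  for (start in c(rowcol_cell(1, 1, g), rowcol_cell(1, 11, g),
                  rowcol_cell(15, 21, g))) {
    d8 <- d8_trace(rec, start)
    lcp <- lcp_path(s, start, d8[length(d8)])
    expect_identical(lcp$cells, d8)
  }
})

test_that("sub-basin labels partition the grid and outlets sit lowest", {
  b <- small_bundle()
  sb <- b$subbasins
  labs <- sb$labels[!is.na(b$dem$values)]
  expect_false(anyNA(labs))
  expect_setequal(unlist(lapply(sb$basins, `[[`, "cells")),
                  which(!is.na(b$dem$values)))
  z <- fill_depressions(b$dem, eps = 1e-6)$values
  g <- b$grid
  for (bas in sb$basins) {
    expect_true(bas$outlet %in% bas$cells)
    # outlet is the minimum-elevation cell on the basin's edge (cells on the
    # grid boundary or queen-adjacent to another basin)
    rc <- cell_rowcol(bas$cells, g)
    on_edge <- rc[, "row"] %in% c(1L, g$nrow) | rc[, "col"] %in% c(1L, g$ncol)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                   c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
      r2 <- rc[, "row"] + d[1]; c2 <- rc[, "col"] + d[2]
      ok <- r2 >= 1L & r2 <= g$nrow & c2 >= 1L & c2 <= g$ncol
      nb <- rowcol_cell(r2[ok], c2[ok], g)
      diff_basin <- sb$labels[nb] != sb$labels[bas$cells[ok]]
      on_edge[ok][diff_basin] <- TRUE
    }
    edge_cells <- bas$cells[on_edge]
    expect_true(bas$outlet %in% edge_cells)
    expect_lte(z[bas$outlet], min(z[edge_cells]))
  }
})

test_that("a tilted single-valley plane yields one basin", {
  cfg <- sim_config(nrow = 60, ncol = 60, seed = 2, valley_count = 1,
                    noise_sd = 0.5)
  dem <- make_dem(cfg)
  sb <- make_subbasins(dem, min_cells = 50)
  expect_equal(length(sb$basins), 1)
  o <- sb$basins[[1]]$outlet
  rc <- cell_rowcol(o, dem$grid)
  boundary_cells <- which(row(dem$values) %in% c(1, 60) |
                          col(dem$values) %in% c(1, 60))
  expect_lte(fill_depressions(dem)$values[o],
             min(fill_depressions(dem)$values[boundary_cells]) + 1e-9)
})
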