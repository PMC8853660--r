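#' Synthetic landscape configuration
#'
#' Parameters of the deterministic synthetic input bundle: a pit-fillable DEM
#' with dendritic valleys draining to boundary exits, elevation-zoned LULC
#' with a park overlay, and PA/WF/LA supply rasters with the statistical
#' structure the pipeline assumes (PA clustered on low-elevation farmland; WF
#' positive on all terrestrial cells, scaled into the 19-1200 value range of
#' regional waterflow-infiltration models, multiplied on influential
#' landscape features; LA broad and LULC-driven, spanning terrestrial and
#' aquatic cells). One seed fixes all randomness.
#'
#' @param nrow,ncol Grid shape (default 120 x 120).
#' @param cellsize Cell size in metres (default 29).
#' @param seed Integer seed fixing every random draw.
#' @param relief Total relief in metres from valley mouth to ridge tops.
#' @param valley_count Number of valleys (each with one branch) draining to
#'   separate boundary exits.
#' @param noise_sd Standard deviation (m) of the smooth elevation noise.
#' @param wf_range Target range of WF values after the ILF multiplier.
#' @param ilf_multiplier Multiplier applied to WF values on ILF patches.
#' @param base_elev Elevation (m) of the lowest valley mouth.
#' @param la_table Named LULC value table for the LA model.
#' @param lulc_fractions Target class fractions of the upland pool (cells not
#'   structurally assigned to water/wetland/agriculture by valley position).
#' @param park_fraction Fraction of the grid covered by the park overlay.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(nrow = 120, ncol = 120, cellsize = 29, seed = 1L,
                       relief = 400, valley_count = 2, noise_sd = 1.5,
                       wf_range = c(19, 1200), ilf_multiplier = 3,
                       base_elev = 300,
                       la_table = c(water = 10, wetland = 8, forest = 7,
                                    rock = 6, grassland = 5, shrub = 4.5,
                                    agriculture = 4, residential = 2, urban = 1),
                       lulc_fractions = c(residential = 0.04, urban = 0.01,
                                          grassland = 0.12, shrub = 0.10,
                                          forest = 0.60, rock = 0.13),
                       park_fraction = 0.12) {
  stopifnot(wf_range[1] < wf_range[2], ilf_multiplier >= 1,
            abs(sum(lulc_fractions) - 1) < 1e-8)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, seed = as.integer(seed), relief = relief,
                 valley_count = as.integer(valley_count), noise_sd = noise_sd,
                 wf_range = wf_range, ilf_multiplier = ilf_multiplier,
                 base_elev = base_elev, la_table = la_table,
                 lulc_fractions = lulc_fractions, park_fraction = park_fraction),
            class = "sim_config")
}

# smooth unit-variance Gaussian noise field (separable kernel smoothing of
# white noise, renormalized to sd 1)
smooth_noise <- function(nr, nc, sigma = 2) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- ceiling(3 * sigma)
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -half:half) {
      i <- seq_len(n); j <- i + d
      ok <- j >= 1 & j <= n
      m[cbind(i[ok], j[ok])] <- kern[d + half + 1]
    }
    m / rowSums(m)
  }
  s <- band(nr) %*% w %*% t(band(nc))
  s / stats::sd(s)
}

# valley centreline geometry: per valley a main stem from a southern boundary
# exit up-grid plus one branch; returns per-cell distance to the nearest
# valley point (cells), its along-stream distance from the exit (cells), and
# the point lists
valley_geometry <- function(cfg) {
  nr <- cfg$nrow; nc <- cfg$ncol
  set.seed(cfg$seed + 101L)
  pts <- list()
  for (v in seq_len(cfg$valley_count)) {
    exit_col <- round(nc * (v - 0.5) / cfg$valley_count +
                        stats::runif(1, -0.04, 0.04) * nc)
    exit_col <- min(max(exit_col, 3L), nc - 2L)
    head_row <- round(0.12 * nr)
    rows <- seq(nr, head_row)
    tfrac <- seq(0, 1, length.out = length(rows))
    amp <- stats::runif(1, 0.05, 0.10) * nc
    phase <- stats::runif(1, 0, 2 * pi)
    cols <- pmin(pmax(round(exit_col + amp * sin(2.2 * pi * tfrac + phase)), 2L),
                 nc - 1L)
    along <- c(0, cumsum(sqrt(diff(rows)^2 + diff(cols)^2)))
    main <- data.frame(row = rows, col = cols, along = along, valley = v,
                       branch = FALSE)
    jb <- round(0.55 * length(rows))
    dirn <- sample(c(-1, 1), 1)
    nb <- round(0.30 * length(rows))
    brow <- rows[jb] - seq_len(nb)
    bcol <- pmin(pmax(round(cols[jb] + dirn * 0.8 * seq_len(nb)), 2L), nc - 1L)
    ok <- brow >= 2L
    branch <- data.frame(row = brow[ok], col = bcol[ok],
                         along = along[jb] + seq_len(sum(ok)) * sqrt(1 + 0.8^2),
                         valley = v, branch = TRUE)
    pts[[v]] <- rbind(main, branch)
  }
  pts <- do.call(rbind, pts)

  cells <- seq_len(nr * nc)
  crow <- (cells - 1L) %% nr + 1L
  ccol <- (cells - 1L) %/% nr + 1L
  dmin <- rep(Inf, nr * nc)
  nearest <- integer(nr * nc)
  for (p in seq_len(nrow(pts))) {
    d2 <- (crow - pts$row[p])^2 + (ccol - pts$col[p])^2
    upd <- d2 < dmin
    dmin[upd] <- d2[upd]
    nearest[upd] <- p
  }
  list(points = pts,
       dperp = matrix(sqrt(dmin), nr, nc),
       along = matrix(pts$along[nearest], nr, nc),
       valley = matrix(pts$valley[nearest], nr, nc),
       exits = pts[pts$along == 0, c("row", "col")])
}

#' Generate the synthetic DEM
#'
#' Terrain = valley-floor gradient descending to boundary exits + hillslope
#' gradient away from the valley network + a boundary rim (suppressed at the
#' exits so each valley drains off-grid) + smooth Gaussian noise. The result
#' is pit-fillable with a boundary minimum per valley; with the default noise
#' the priority-flood fill changes well under 5% of cells.
#'
#' @param cfg A [sim_config()].
#' @return A [value_raster()] DEM carrying the valley geometry in `$meta`.
#' @export
make_dem <- function(cfg = sim_config()) {
  vg <- valley_geometry(cfg)
  nr <- cfg$nrow; nc <- cfg$ncol
  set.seed(cfg$seed + 202L)
  max_along <- max(vg$along)
  max_perp <- 0.5 * max(nr, nc)
  elev <- cfg$base_elev +
    0.35 * cfg$relief * vg$along / max_along +
    0.65 * cfg$relief * pmin(vg$dperp / max_perp, 1.2)
  # boundary rim, faded out near the valley exits
  crow <- matrix(rep(seq_len(nr), nc), nr, nc)
  ccol <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  dedge <- pmin(crow - 1, nr - crow, ccol - 1, nc - ccol)
  dexit <- Reduce(pmin, lapply(seq_len(nrow(vg$exits)), function(i)
    sqrt((crow - vg$exits$row[i])^2 + (ccol - vg$exits$col[i])^2)))
  rim <- 0.20 * cfg$relief * pmax(0, 1 - dedge / 6)^2 * pmin(dexit / 10, 1)
  elev <- elev + rim + cfg$noise_sd * smooth_noise(nr, nc)
  dem <- value_raster(elev, grid_spec(nr, nc, cfg$cellsize))
  dem$meta <- vg
  dem
}

#' Generate the synthetic LULC raster
#'
#' Valley-position classes first (a mid-valley lake as the only mapped
#' waterbody; wetland strips flanking the stream; floodplain agriculture in
#' the lower reaches), then elevation-zoned upland classes at the
#' `cfg$lulc_fractions` quantile targets (residential and urban low,
#' grassland and shrub mid, forest mid-high, rock on top). A circular park
#' overlay spans several upland base classes.
#'
#' @param dem A [make_dem()] raster (its `$meta` valley geometry is required).
#' @param cfg A [sim_config()].
#' @return A [categorical_raster()] with a `"park"` overlay.
#' @export
make_lulc <- function(dem, cfg = sim_config()) {
  if (is.null(dem$meta)) stop("make_lulc needs a DEM produced by make_dem()")
  vg <- dem$meta
  nr <- cfg$nrow; nc <- cfg$ncol
  elev <- dem$values
  afrac <- vg$along / max(vg$along)

  codes <- matrix(NA_integer_, nr, nc)
  lake <- afrac >= 0.28 & afrac <= 0.42 & vg$dperp <= 2.2
  codes[lake] <- 1L
  ag <- is.na(codes) & afrac < 0.30 & vg$dperp <= 6
  codes[ag] <- 3L
  wet <- is.na(codes) & vg$dperp <= 2.5
  codes[wet] <- 2L

  pool <- which(is.na(codes))
  qs <- cumsum(cfg$lulc_fractions[c("residential", "urban", "grassland",
                                    "shrub", "forest", "rock")])
  br <- stats::quantile(elev[pool], probs = qs[-length(qs)])
  zp <- elev[pool]
  cls <- findInterval(zp, br) + 1L # 1..6 over the pool
  codes[pool] <- c(4L, 5L, 6L, 7L, 8L, 9L)[cls]

  legend <- c("1" = "water", "2" = "wetland", "3" = "agriculture",
              "4" = "residential", "5" = "urban", "6" = "grassland",
              "7" = "shrub", "8" = "forest", "9" = "rock")
  crow <- matrix(rep(seq_len(nr), nc), nr, nc)
  ccol <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  r_park <- sqrt(cfg$park_fraction * nr * nc / pi)
  park <- (crow - 0.30 * nr)^2 + (ccol - 0.74 * nc)^2 <= r_park^2
  categorical_raster(codes, dem$grid, legend, overlays = list(park = park))
}

#' Generate the synthetic ES supply rasters, parcels and ILF zones
#'
#' * PA: positive only on agriculture cells, higher on low floodplain ground,
#'   grouped into a parcel fabric of adjacent blocks (the parcel layer to
#'   dissolve).
#' * WF: positive on every terrestrial cell from LULC-specific perviousness
#'   weights times smooth noise, min-max scaled so that after multiplying the
#'   ILF patches by `cfg$ilf_multiplier` all values lie in `cfg$wf_range`
#'   (default 19-1200); zero on waterbodies.
#' * LA: the `cfg$la_table` value per LULC class (park adds a bonus;
#'   vineyard parcels are scenic), plus smooth noise, positive nearly
#'   everywhere including aquatic cells.
#' * ILF zones: wetland/floodplain/riparian patches flanking the stream and
#'   seasonally flooded fields on valley-bottom farmland.
#'
#' @param dem A [make_dem()] raster.
#' @param lulc A [make_lulc()] raster.
#' @param subbasins A [make_subbasins()] result (unused by the value models
#'   but kept in the signature so bundles regenerate consistently).
#' @param cfg A [sim_config()].
#' @return List with `pa`, `wf`, `la` ([value_raster()]s), `wf_pre` (WF
#'   before the ILF multiplier, for auditing), `parcels`
#'   ([polygon_layer()]), `ilf_zones` (list of [ilf_zone()]).
#' @export
make_supply_rasters <- function(dem, lulc, subbasins = NULL, cfg = sim_config()) {
  if (is.null(dem$meta)) stop("make_supply_rasters needs a DEM from make_dem()")
  vg <- dem$meta
  nr <- cfg$nrow; nc <- cfg$ncol
  grid <- dem$grid
  codes <- lulc$codes
  elev <- dem$values
  relz <- (elev - min(elev)) / diff(range(elev))

  set.seed(cfg$seed + 303L)
  n_pa <- smooth_noise(nr, nc, sigma = 2)
  n_wf <- smooth_noise(nr, nc, sigma = 3)
  n_la <- smooth_noise(nr, nc, sigma = 3)

  # --- PA: farmland value and parcel fabric -------------------------------
  ag <- which(codes == 3L)
  pa <- matrix(0, nr, nc)
  pa[ag] <- pmax(1, 40 + 60 * (1 - relz[ag]) + 8 * n_pa[ag])
  rc <- cell_rowcol(ag, grid)
  block <- paste(connected_components(codes == 3L, "queen")$labels[ag],
                 (rc[, "row"] - 1L) %/% 6L, (rc[, "col"] - 1L) %/% 6L)
  parcel_cells <- split(ag, block)
  # keep each parcel internally connected
  parcel_cells <- unlist(lapply(parcel_cells, split_cell_parts, grid = grid),
                         recursive = FALSE, use.names = FALSE)
  crops <- sample(c("apples", "cherries", "grapes", "vegetables"),
                  length(parcel_cells), replace = TRUE)
  parcels <- polygonize(parcel_cells, grid,
                        ids = paste0("parcel_", seq_along(parcel_cells)),
                        attrs = data.frame(crop = crops, stringsAsFactors = FALSE))

  # --- WF: perviousness-weighted terrestrial supply -----------------------
  perv <- c(0, 1.0, 0.35, 0.15, 0.05, 0.55, 0.50, 0.80, 0.20)[codes]
  wf_raw <- matrix(perv * exp(0.3 * n_wf), nr, nc)
  terr <- codes != 1L
  # ILF patches: stream-flanking wetland strips and seasonally flooded fields
  ilf_mask <- (codes == 2L & vg$dperp <= 2.5) |
              (codes == 3L & vg$dperp <= 3.5)
  lo <- cfg$wf_range[1]; hi <- cfg$wf_range[2] / cfg$ilf_multiplier
  v <- wf_raw[terr]
  wf <- matrix(0, nr, nc)
  wf[terr] <- lo + (hi - lo) * (v - min(v)) / (max(v) - min(v))
  wf_pre <- wf
  wf[ilf_mask & terr] <- wf[ilf_mask & terr] * cfg$ilf_multiplier

  ilf_cc <- connected_components(ilf_mask, "queen")
  kinds <- c("wetland", "floodplain", "riparian", "seasonally-flooded-field")
  ilf_zones <- lapply(seq_along(ilf_cc$components), function(i) {
    cs <- ilf_cc$components[[i]]
    kind <- if (any(codes[cs] == 3L)) "seasonally-flooded-field"
            else kinds[(i - 1L) %% 3L + 1L]
    ilf_zone(paste0("ILF_", i), cs, kind)
  })

  # --- LA: LULC value table + park bonus + scenic vineyards ---------------
  la <- matrix(cfg$la_table[c("water", "wetland", "agriculture", "residential",
                              "urban", "grassland", "shrub", "forest",
                              "rock")][codes], nr, nc)
  la <- la + 2 * lulc$overlays$park
  vineyard <- unlist(parcel_cells[crops == "grapes"])
  la[vineyard] <- pmax(la[vineyard], 9)
  la <- pmax(la + 0.5 * n_la, 0.1)

  list(pa = value_raster(pa, grid), wf = value_raster(wf, grid),
       la = value_raster(la, grid), wf_pre = value_raster(wf_pre, grid),
       parcels = parcels, ilf_zones = ilf_zones)
}

# interior pour points: on each valley's D8 stream, the trace cell closest to
# 45% of the trace length, so each valley splits into an upper sub-basin
# (interior outlet) and a lower one (boundary exit), with ILFs downstream
sim_pour_points <- function(dem, cfg) {
  vg <- dem$meta
  eps_dem <- fill_depressions(dem, eps = 1e-6)
  rec <- d8_receivers(eps_dem)
  vapply(seq_len(cfg$valley_count), function(v) {
    main <- vg$points[vg$points$valley == v & !vg$points$branch, ]
    head_cell <- rowcol_cell(main$row[nrow(main)], main$col[nrow(main)], dem$grid)
    trace <- d8_trace(rec, head_cell)
    trace[round(0.55 * length(trace))]
  }, integer(1))
}

#' Generate a complete synthetic input bundle
#'
#' Runs [make_dem()], [make_subbasins()] (with interior pour points so every
#' valley has an upper sub-basin with ILF zones downstream of it),
#' [make_lulc()] and [make_supply_rasters()] under the one configuration
#' seed. The same seed always yields the bit-identical bundle.
#'
#' @param cfg A [sim_config()].
#' @return List with `cfg`, `grid`, `dem`, `filled`, `subbasins`, `outlets`,
#'   `lulc`, `pa`, `wf`, `la`, `wf_pre`, `parcels`, `ilf_zones`.
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  dem <- make_dem(cfg)
  pour <- sim_pour_points(dem, cfg)
  subbasins <- make_subbasins(dem, outlets = pour, min_cells = 25L)
  lulc <- make_lulc(dem, cfg)
  es <- make_supply_rasters(dem, lulc, subbasins, cfg)
  c(list(cfg = cfg, grid = dem$grid, dem = dem,
         filled = fill_depressions(dem), subbasins = subbasins,
         outlets = pour, lulc = lulc), es)
}

#' Write / read a synthetic bundle as plain-text GIS files
#'
#' Rasters go to ESRI ASCII grids, parcels and ILF zones to GeoJSON, and the
#' configuration (plus pour points) to `bundle.yml`, from which
#' [read_bundle()] reconstructs the derived pieces deterministically.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) / the bundle list (read), invisibly for write.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  for (nm in c("dem", "pa", "wf", "la", "wf_pre"))
    write_raster(bundle[[nm]], p(paste0(nm, ".asc")))
  write_raster(bundle$lulc, p("lulc.asc"))
  write_polygons(bundle$parcels, p("parcels.geojson"))
  ilf_attrs <- data.frame(
    kind = vapply(bundle$ilf_zones, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)
  write_polygons(polygonize(lapply(bundle$ilf_zones, `[[`, "cells"),
                            bundle$grid,
                            ids = vapply(bundle$ilf_zones, `[[`, character(1), "id"),
                            attrs = ilf_attrs),
                 p("ilf.geojson"))
  yaml::write_yaml(list(config = unclass(bundle$cfg),
                        outlets = as.integer(bundle$outlets)),
                   p("bundle.yml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  meta <- yaml::read_yaml(p("bundle.yml"))
  cfg <- do.call(sim_config, meta$config[setdiff(names(meta$config),
                                                 c("la_table", "lulc_fractions"))])
  cfg$la_table <- unlist(meta$config$la_table)
  cfg$lulc_fractions <- unlist(meta$config$lulc_fractions)
  dem <- read_raster(p("dem.asc"), type = "value")
  ilf_layer <- read_polygons(p("ilf.geojson"))
  ilf_zones <- lapply(seq_along(ilf_layer$ids), function(i)
    ilf_zone(ilf_layer$ids[i], rasterize_geom(ilf_layer$geoms[[i]], dem$grid),
             ilf_layer$attrs$kind[i]))
  parcels <- read_polygons(p("parcels.geojson"))
  parcels$cells <- lapply(parcels$geoms, rasterize_geom, grid = dem$grid)
  list(cfg = cfg, grid = dem$grid, dem = dem,
       filled = fill_depressions(dem),
       subbasins = make_subbasins(dem, outlets = meta$outlets, min_cells = 25L),
       outlets = meta$outlets,
       lulc = read_raster(p("lulc.asc")),
       pa = read_raster(p("pa.asc"), type = "value"),
       wf = read_raster(p("wf.asc"), type = "value"),
       la = read_raster(p("la.asc"), type = "value"),
       wf_pre = read_raster(p("wf_pre.asc"), type = "value"),
       parcels = parcels, ilf_zones = ilf_zones)
}
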