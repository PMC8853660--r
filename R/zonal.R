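#' Zonal sum of raster values
#'
#' Sums the unmasked values of the cells whose centres fall inside the zone.
#' Nodata cells contribute nothing; an empty intersection sums to 0. The zone
#' may be given as a vector of linear cell indices, a logical matrix, a
#' multipolygon geometry, or a [polygon_layer()] feature.
#'
#' @param raster A [value_raster()].
#' @param zone Cell-index vector, logical matrix, multipolygon geometry, or a
#'   single-feature [polygon_layer()].
#' @return The zonal sum (a single real).
#' @export
zonal_sum <- function(raster, zone) {
  stopifnot(inherits(raster, "value_raster"))
  cells <- zone_cells(zone, raster$grid)
  if (!length(cells)) return(0)
  sum(raster$values[cells], na.rm = TRUE)
}

#' Zonal mean of raster values
#'
#' Mean over the zone's unmasked cells; `NaN`-free: an all-nodata or empty
#' zone returns 0.
#'
#' @inheritParams zonal_sum
#' @return The zonal mean.
#' @export
zonal_mean <- function(raster, zone) {
  cells <- zone_cells(zone, raster$grid)
  v <- raster$values[cells]
  v <- v[!is.na(v)]
  if (!length(v)) return(0)
  mean(v)
}

zone_cells <- function(zone, grid) {
  if (inherits(zone, "polygon_layer")) {
    if (!is.null(zone$cells)) return(unique(unlist(zone$cells)))
    zone <- do.call(c, zone$geoms)
  }
  if (is.matrix(zone) && is.logical(zone)) {
    stopifnot(nrow(zone) == grid$nrow, ncol(zone) == grid$ncol)
    return(which(zone))
  }
  if (is.numeric(zone)) {
    cells <- as.integer(zone)
    n <- grid$nrow * grid$ncol
    if (length(cells) && (min(cells) < 1L || max(cells) > n))
      stop("zone cells fall outside the raster extent")
    return(cells)
  }
  if (is.list(zone)) { # multipolygon geometry
    cells <- rasterize_geom(zone, grid)
    if (!length(cells)) {
      xs <- unlist(lapply(zone, function(p) lapply(p, function(r) r[, 1])))
      ys <- unlist(lapply(zone, function(p) lapply(p, function(r) r[, 2])))
      if (max(xs) < grid$xmin || min(xs) > grid$xmin + grid$ncol * grid$cellsize ||
          max(ys) < grid$ymax - grid$nrow * grid$cellsize || min(ys) > grid$ymax)
        stop("zone lies outside the raster extent")
    }
    return(cells)
  }
  stop("unsupported zone type: ", class(zone)[1])
}

#' Resample rasters onto a common grid
#'
#' Harmonizes rasters onto a target [grid_spec()]: continuous values are
#' resampled bilinearly, categorical codes by nearest neighbour; nodata is
#' propagated (a bilinear result is nodata when its nearest source cell is
#' nodata). Rasters already on the target grid are returned unchanged.
#'
#' @param rasters A raster or list of rasters.
#' @param target Target [grid_spec()].
#' @return A list of rasters on `target` (a bare raster input comes back bare).
#' @export
align_rasters <- function(rasters, target) {
  single <- is_raster(rasters)
  if (single) rasters <- list(rasters)
  out <- lapply(rasters, align_one, target = target)
  if (single) out[[1]] else out
}

align_one <- function(r, target) {
  stopifnot(is_raster(r))
  g <- r$grid
  if (!identical(g$crs, target$crs))
    stop("raster CRS differs from target CRS; reproject before aligning")
  if (same_grid(g, target)) return(r)
  sx0 <- g$xmin; sx1 <- g$xmin + g$ncol * g$cellsize
  sy1 <- g$ymax; sy0 <- g$ymax - g$nrow * g$cellsize
  tx0 <- target$xmin; tx1 <- target$xmin + target$ncol * target$cellsize
  ty1 <- target$ymax; ty0 <- target$ymax - target$nrow * target$cellsize
  if (tx1 <= sx0 || tx0 >= sx1 || ty1 <= sy0 || ty0 >= sy1)
    stop("raster extent is disjoint from the target grid")

  cells <- seq_len(target$nrow * target$ncol)
  xy <- cell_xy(cells, target)
  # fractional source grid coordinates of the target cell centres
  fc <- (xy[, "x"] - g$xmin) / g$cellsize + 0.5
  fr <- (g$ymax - xy[, "y"]) / g$cellsize + 0.5
  nn_r <- pmin(pmax(round(fr), 1L), g$nrow)
  nn_c <- pmin(pmax(round(fc), 1L), g$ncol)
  outside <- fr < 0.5 | fr > g$nrow + 0.5 | fc < 0.5 | fc > g$ncol + 0.5
  src <- raster_matrix(r)
  nn_val <- src[cbind(nn_r, nn_c)]
  nn_val[outside] <- NA

  if (inherits(r, "categorical_raster")) {
    m <- matrix(nn_val, target$nrow, target$ncol)
    ov <- lapply(r$overlays, function(o) {
      om <- matrix(o[cbind(nn_r, nn_c)], target$nrow, target$ncol)
      om[is.na(om)] <- FALSE
      om
    })
    return(categorical_raster(m, target, r$legend, ov))
  }

  r0 <- pmin(pmax(floor(fr), 1L), g$nrow); r1 <- pmin(r0 + 1L, g$nrow)
  c0 <- pmin(pmax(floor(fc), 1L), g$ncol); c1 <- pmin(c0 + 1L, g$ncol)
  wr <- pmin(pmax(fr - r0, 0), 1); wc <- pmin(pmax(fc - c0, 0), 1)
  v00 <- src[cbind(r0, c0)]; v01 <- src[cbind(r0, c1)]
  v10 <- src[cbind(r1, c0)]; v11 <- src[cbind(r1, c1)]
  val <- (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
  val[is.na(val)] <- nn_val[is.na(val)] # fall back to nearest at data edges
  val[is.na(nn_val)] <- NA             # propagate nodata by nearest cell
  value_raster(matrix(val, target$nrow, target$ncol), target)
}

#' Connected components of a boolean mask
#'
#' Labels the maximal sets of `TRUE` cells mutually reachable under rook
#' (4-neighbour) or queen (8-neighbour) adjacency. Components are numbered
#' 1..K in row-major order of their first cell, so labelling is deterministic.
#'
#' @param mask Logical matrix (`NA` counts as `FALSE`).
#' @param adjacency `"queen"` (default) or `"rook"`.
#' @return A list with `labels` (integer matrix, `NA` off-mask), `components`
#'   (list of cell-index vectors) and `n` (number of components).
#' @export
connected_components <- function(mask, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  labels <- matrix(NA_integer_, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx))
    return(list(labels = labels, components = list(), n = 0L))
  pairs <- mask_adjacency_pairs(mask, adjacency)
  vid <- match(seq_len(length(mask)), idx) # cell index -> vertex id
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(pairs) && nrow(pairs))
    gr <- igraph::add_edges(gr, rbind(vid[pairs[, 1]], vid[pairs[, 2]]))
  memb <- igraph::components(gr)$membership
  # relabel in row-major order of first occurrence: sort cells by (row, col)
  rc <- cell_rowcol(idx, grid_spec(nrow(mask), ncol(mask)))
  ord <- order(rc[, "row"], rc[, "col"])
  relabel <- integer(max(memb))
  nxt <- 0L
  for (i in ord) {
    m <- memb[i]
    if (relabel[m] == 0L) { nxt <- nxt + 1L; relabel[m] <- nxt }
  }
  lab <- relabel[memb]
  labels[idx] <- lab
  comps <- split(idx, lab)
  names(comps) <- NULL
  list(labels = labels, components = comps, n = nxt)
}
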