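#' Grid specification for aligned rasters
#'
#' All rasters taking part in one analysis share a `grid_spec`: a regular grid
#' of square cells in a projected, metric CRS. Cells are addressed by
#' `(row, col)` with row 1 at the top of the grid, or by the column-major
#' linear index R uses for matrices; a cell's location is its centre point.
#'
#' @param nrow,ncol Grid dimensions (positive integers).
#' @param cellsize Cell side length in metres.
#' @param xmin X coordinate of the grid's left (west) edge.
#' @param ymax Y coordinate of the grid's top (north) edge.
#' @param crs CRS identifier or WKT string; must describe a projected, metric
#'   CRS. Defaults to a generic local metric system.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, cellsize = 29, xmin = 0, ymax = nrow * cellsize,
                      crs = "LOCAL_CS[\"synthetic local metric grid\",UNIT[\"metre\",1]]") {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = as.numeric(cellsize),
                 xmin = as.numeric(xmin), ymax = as.numeric(ymax),
                 crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m (extent %g..%g, %g..%g)\n",
              x$nrow, x$ncol, x$cellsize,
              x$xmin, x$xmin + x$ncol * x$cellsize,
              x$ymax - x$nrow * x$cellsize, x$ymax))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol
}

#' Continuous-valued raster
#'
#' Holds per-cell real values (ES model values or elevations) on a
#' [grid_spec()]. Nodata is represented by `NA`; nodata cells never take part
#' in sums, thresholds or component searches. ES supply rasters must be
#' non-negative where unmasked; DEMs may carry any real elevations.
#'
#' @param values Numeric matrix (`grid$nrow` x `grid$ncol`); `NA` marks nodata.
#' @param grid A [grid_spec()].
#' @return An object of class `value_raster`.
#' @export
value_raster <- function(values, grid) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  structure(list(values = values, grid = grid), class = "value_raster")
}

#' @export
print.value_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("value_raster: %d x %d, %d data cells, range [%g, %g]\n",
              x$grid$nrow, x$grid$ncol, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Categorical (land-use / land-cover) raster
#'
#' Integer class codes plus a legend, with optional overlay layers: boolean
#' masks for classes that lie on top of the base classification (e.g. parkland
#' over forest, grassland, shrub or rock), so coverage percentages of base
#' classes and overlays are accounted for independently.
#'
#' @param codes Integer matrix of class codes; `NA` marks nodata.
#' @param grid A [grid_spec()].
#' @param legend Named character vector mapping code (name) to class name.
#' @param overlays Named list of logical matrices, one per overlay class.
#' @return An object of class `categorical_raster`.
#' @export
categorical_raster <- function(codes, grid, legend, overlays = list()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  stopifnot(nrow(codes) == grid$nrow, ncol(codes) == grid$ncol)
  present <- unique(codes[!is.na(codes)])
  missing <- setdiff(present, as.integer(names(legend)))
  if (length(missing))
    warning("codes not in legend reported as 'unknown': ",
            paste(missing, collapse = ", "))
  for (ov in overlays) stopifnot(identical(dim(ov), dim(codes)))
  structure(list(codes = codes, grid = grid,
                 legend = legend, overlays = overlays),
            class = "categorical_raster")
}

#' @export
print.categorical_raster <- function(x, ...) {
  cat(sprintf("categorical_raster: %d x %d, %d classes%s\n",
              x$grid$nrow, x$grid$ncol, length(x$legend),
              if (length(x$overlays))
                paste0(" + overlays: ", paste(names(x$overlays), collapse = ", "))
              else ""))
  invisible(x)
}

is_raster <- function(x) inherits(x, c("value_raster", "categorical_raster"))

raster_grid <- function(x) x$grid

raster_matrix <- function(x) if (inherits(x, "categorical_raster")) x$codes else x$values

# ---- cell indexing helpers (column-major linear index <-> row/col <-> x/y) --

#' Convert between cell indices, row/col and coordinates
#'
#' Cells are identified by the column-major linear index of the raster matrix.
#' `cell_rowcol` returns a two-column matrix of (row, col); `cell_xy` the cell
#' centre coordinates; `xy_cell` the cell index containing a point (NA when
#' outside the grid); `rowcol_cell` the inverse of `cell_rowcol`.
#'
#' @param cell Integer vector of linear cell indices.
#' @param grid A [grid_spec()].
#' @return See description.
#' @export
cell_rowcol <- function(cell, grid) {
  cell <- as.integer(cell)
  cbind(row = (cell - 1L) %% grid$nrow + 1L,
        col = (cell - 1L) %/% grid$nrow + 1L)
}

#' @rdname cell_rowcol
#' @param row,col Integer vectors of 1-based row and column numbers.
#' @export
rowcol_cell <- function(row, col, grid) {
  as.integer((col - 1L) * grid$nrow + row)
}

#' @rdname cell_rowcol
#' @export
cell_xy <- function(cell, grid) {
  rc <- cell_rowcol(cell, grid)
  cbind(x = grid$xmin + (rc[, "col"] - 0.5) * grid$cellsize,
        y = grid$ymax - (rc[, "row"] - 0.5) * grid$cellsize)
}

#' @rdname cell_rowcol
#' @param x,y Numeric point coordinates.
#' @export
xy_cell <- function(x, y, grid) {
  col <- floor((x - grid$xmin) / grid$cellsize) + 1L
  row <- floor((grid$ymax - y) / grid$cellsize) + 1L
  out <- rowcol_cell(row, col, grid)
  out[row < 1L | row > grid$nrow | col < 1L | col > grid$ncol] <- NA_integer_
  out
}

#' Area of a set of cells in hectares
#'
#' @param n_cells Number of cells (or a cell-index vector, whose length is used).
#' @param grid A [grid_spec()].
#' @return Area in hectares (`cells * cellsize^2 / 10000`).
#' @export
cells_to_ha <- function(n_cells, grid) {
  if (length(n_cells) > 1L) n_cells <- length(n_cells)
  n_cells * grid$cellsize^2 / 1e4
}

# Queen / rook neighbour pairs among the cells of a logical mask, as a
# two-column matrix of linear indices (each undirected pair once).
mask_adjacency_pairs <- function(mask, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  nr <- nrow(mask); nc <- ncol(mask)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (adjacency == "queen") shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  out <- vector("list", length(shifts))
  idx <- which(mask)
  rc <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
  inmask <- mask
  for (s in seq_along(shifts)) {
    dr <- shifts[[s]][1]; dc <- shifts[[s]][2]
    r2 <- rc[, 1] + dr; c2 <- rc[, 2] + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- inmask[j]
    out[[s]] <- cbind(idx[ok][keep], j[keep])
  }
  do.call(rbind, out)
}
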