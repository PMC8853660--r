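# Grid-aligned polygon geometry: boundary tracing of cell sets into rings,
# even-odd point-in-polygon, and rasterization by cell centres.

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized even-odd (ray crossing) containment test against a multipolygon
#' geometry as stored in a [polygon_layer()]. Points exactly on an edge follow
#' the half-open convention of the crossing test, which is immaterial here
#' because zonal membership uses cell centres that generically avoid edges.
#'
#' @param x,y Numeric point coordinates.
#' @param geom Multipolygon: list of polygons, each a list of (n x 2) rings.
#' @return Logical vector.
#' @export
point_in_geom <- function(x, y, geom) {
  inside <- logical(length(x))
  for (poly in geom) for (ring in poly) {
    xr <- ring[, 1]; yr <- ring[, 2]
    n <- length(xr)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      xi <- xr[k]; yi <- yr[k]; xj <- xr[j[k]]; yj <- yr[j[k]]
      cross <- ((yi > y) != (yj > y)) &
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
  }
  inside
}

#' Cells whose centres fall inside a geometry
#'
#' A cell belongs to a zone iff its centre point lies inside the zone; there
#' is no partial-cell area weighting. Restricting the candidate cells to the
#' geometry's bounding box keeps this fast on large grids.
#'
#' @param geom Multipolygon geometry (see [point_in_geom()]).
#' @param grid A [grid_spec()].
#' @return Integer vector of linear cell indices (sorted).
#' @export
rasterize_geom <- function(geom, grid) {
  xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 2])))
  c0 <- max(1L, floor((min(xs) - grid$xmin) / grid$cellsize) + 1L)
  c1 <- min(grid$ncol, ceiling((max(xs) - grid$xmin) / grid$cellsize))
  r0 <- max(1L, floor((grid$ymax - max(ys)) / grid$cellsize) + 1L)
  r1 <- min(grid$nrow, ceiling((grid$ymax - min(ys)) / grid$cellsize))
  if (c1 < c0 || r1 < r0) return(integer(0))
  rc <- expand.grid(row = r0:r1, col = c0:c1)
  cells <- rowcol_cell(rc$row, rc$col, grid)
  xy <- cell_xy(cells, grid)
  sort(cells[point_in_geom(xy[, "x"], xy[, "y"], geom)])
}

# Trace the boundary of a cell set into closed rings. Exterior rings come out
# counter-clockwise (positive shoelace area), holes clockwise. At pinch
# vertices (diagonally touching cells) the sharpest-left-turn rule keeps each
# ring simple.
trace_cell_rings <- function(cells, grid) {
  if (!length(cells)) return(list())
  cs <- grid$cellsize
  rc <- cell_rowcol(cells, grid)
  nr <- grid$nrow
  inset <- new.env(hash = TRUE, size = length(cells) * 2L)
  for (i in cells) assign(as.character(i), TRUE, envir = inset)
  has <- function(r, c) {
    if (r < 1L || r > grid$nrow || c < 1L || c > grid$ncol) return(FALSE)
    exists(as.character((c - 1L) * nr + r), envir = inset)
  }
  # collect directed boundary edges keyed by integer vertex (col, row) lattice
  # coordinates; vertex (i, j) is at x = xmin + i*cs, y = ymax - j*cs
  edges_from <- list()   # key "i,j" -> list of to-vertices c(i, j)
  add_edge <- function(v1, v2) {
    k <- paste(v1, collapse = ",")
    edges_from[[k]] <<- c(edges_from[[k]], list(v2))
  }
  for (n in seq_len(nrow(rc))) {
    r <- unname(rc[n, "row"]); c <- unname(rc[n, "col"])
    # lattice corners of the cell: TL=(c-1, r-1), TR=(c, r-1), BL=(c-1, r), BR=(c, r)
    if (!has(r - 1L, c)) add_edge(c(c, r - 1L), c(c - 1L, r - 1L))      # top: TR -> TL
    if (!has(r + 1L, c)) add_edge(c(c - 1L, r), c(c, r))                # bottom: BL -> BR
    if (!has(r, c - 1L)) add_edge(c(c - 1L, r - 1L), c(c - 1L, r))      # left: TL -> BL
    if (!has(r, c + 1L)) add_edge(c(c, r), c(c, r - 1L))                # right: BR -> TR
  }
  rings <- list()
  while (length(edges_from)) {
    k0 <- sort(names(edges_from))[1]
    v <- edges_from[[k0]][[1]]
    start <- as.integer(strsplit(k0, ",")[[1]])
    ring <- list(start)
    prev <- start
    cur <- v
    # consume the first edge
    edges_from[[k0]] <- edges_from[[k0]][-1]
    if (!length(edges_from[[k0]])) edges_from[[k0]] <- NULL
    while (!identical(cur, start)) {
      ring <- c(ring, list(cur))
      k <- paste(cur, collapse = ",")
      outs <- edges_from[[k]]
      if (is.null(outs)) stop("boundary tracing failed: open ring")
      if (length(outs) == 1L) { pick <- 1L } else {
        # Pinch vertex (diagonally touching cells): take the sharpest left
        # turn in map coordinates so touching rings stay separate and simple.
        # Lattice j runs downward, so that is the minimum lattice-frame angle.
        din <- cur - prev
        ang <- vapply(outs, function(o) {
          dout <- o - cur
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        pick <- which.min(ang)
      }
      nxt <- outs[[pick]]
      outs[[pick]] <- NULL
      if (length(outs)) edges_from[[k]] <- outs else edges_from[[k]] <- NULL
      prev <- cur
      cur <- nxt
    }
    m <- do.call(rbind, ring)
    rings <- c(rings, list(cbind(x = grid$xmin + m[, 1] * cs,
                                 y = grid$ymax - m[, 2] * cs)))
  }
  rings
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Assemble traced rings into a multipolygon: exterior rings (CCW, area > 0)
# become polygons; holes (CW) attach to the exterior ring containing them.
rings_to_geom <- function(rings) {
  areas <- vapply(rings, ring_area, numeric(1))
  ext <- which(areas > 0); holes <- which(areas < 0)
  polys <- lapply(ext, function(i) list(rings[[i]]))
  for (h in holes) {
    p <- rings[[h]][1, ]
    owner <- NULL
    for (i in seq_along(ext)) {
      if (point_in_geom(p[1] + 1e-9, p[2] - 1e-9, list(list(rings[[ext[i]]]))))
        owner <- i
    }
    if (is.null(owner)) owner <- 1L
    polys[[owner]] <- c(polys[[owner]], list(rings[[h]]))
  }
  polys
}

#' Convert labelled cell components to a polygon layer
#'
#' Builds one (multi)polygon per component by tracing the component's cell
#' boundary; polygon area equals `cell count * cellsize^2` exactly.
#'
#' @param components List of cell-index vectors (disjoint).
#' @param grid A [grid_spec()].
#' @param ids Feature ids (defaults to `1..K`).
#' @param attrs Optional attribute data frame.
#' @return A [polygon_layer()] carrying the cell sets alongside the geometry.
#' @export
polygonize <- function(components, grid, ids = NULL, attrs = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(components))
  geoms <- lapply(components, function(cells) {
    rings_to_geom(trace_cell_rings(cells, grid))
  })
  polygon_layer(ids, geoms, attrs, crs = grid$crs, cells = components)
}

#' Area of a multipolygon geometry
#'
#' Shoelace area summed over exterior rings minus holes.
#'
#' @param geom Multipolygon geometry.
#' @return Area in square CRS units (square metres).
#' @export
geom_area <- function(geom) {
  sum(unlist(lapply(geom, function(p) vapply(p, ring_area, numeric(1)))))
}
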