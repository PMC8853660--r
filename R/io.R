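#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`), the plain-text
#' single-band raster format read by every desktop GIS and by GDAL. A `.prj`
#' sidecar (WKT) carries the CRS; rasters in a geographic (degree-unit) CRS
#' are rejected because every area and distance computation here is metric.
#' Categorical rasters additionally carry a `<path>.legend.json` sidecar with
#' the code legend and any overlay-class masks.
#'
#' @param path Path to the `.asc` file.
#' @param type `"auto"` (categorical when a legend sidecar exists), `"value"`
#'   or `"categorical"`.
#' @return A [value_raster()] or [categorical_raster()].
#' @export
read_raster <- function(path, type = c("auto", "value", "categorical")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    ln <- readLines(con, n = 1L)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) # .asc rows are top-down
  m[m == nodata] <- NA

  crs <- NULL
  prj <- sub("\\.asc$", ".prj", path)
  if (file.exists(prj)) {
    crs <- paste(readLines(prj, warn = FALSE), collapse = "")
    if (grepl("^\\s*GEOGCS", crs) && !grepl("PROJCS", crs))
      stop("raster ", path, " is in a geographic (degree-unit) CRS; ",
           "reproject it to a projected metric CRS before use")
  }
  grid <- grid_spec(nr, nc, hdr$cellsize,
                    xmin = hdr$xllcorner,
                    ymax = hdr$yllcorner + nr * hdr$cellsize,
                    crs = if (is.null(crs)) formals(grid_spec)$crs else crs)

  legend_path <- paste0(path, ".legend.json")
  categorical <- switch(type, value = FALSE, categorical = TRUE,
                        auto = file.exists(legend_path))
  if (!categorical) return(value_raster(m, grid))

  overlays <- list()
  legend <- character()
  if (file.exists(legend_path)) {
    meta <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
    legend <- meta$legend
    for (nm in names(meta$overlays %||% list())) {
      ov <- read_raster(meta$overlays[[nm]], type = "value")
      overlays[[nm]] <- !is.na(ov$values) & ov$values > 0
    }
  } else {
    codes <- sort(unique(m[!is.na(m)]))
    legend <- stats::setNames(as.character(codes), codes)
  }
  categorical_raster(m, grid, legend, overlays)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Values are written with full double precision so a write/read round trip is
#' exact. The CRS goes to a `.prj` sidecar; categorical rasters also write
#' their legend (and overlay masks as companion `.asc` files) to
#' `<path>.legend.json`.
#'
#' @param r A [value_raster()] or [categorical_raster()].
#' @param path Output `.asc` path.
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(is_raster(r))
  g <- r$grid
  m <- raster_matrix(r)
  if (any(!is.na(m) & m == nodata))
    stop("nodata sentinel ", nodata, " collides with a data value")
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", g$ncol),
           sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10f", g$xmin),
           sprintf("yllcorner %.10f", g$ymax - g$nrow * g$cellsize),
           sprintf("cellsize %.10f", g$cellsize),
           sprintf("NODATA_value %s", format(nodata)))
  body <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  if (!is.null(g$crs)) writeLines(g$crs, sub("\\.asc$", ".prj", path))
  if (inherits(r, "categorical_raster")) {
    ov_paths <- list()
    for (nm in names(r$overlays)) {
      op <- sub("\\.asc$", paste0(".overlay-", nm, ".asc"), path)
      write_raster(value_raster(r$overlays[[nm]] + 0, g), op)
      ov_paths[[nm]] <- op
    }
    jsonlite::write_json(list(legend = as.list(r$legend), overlays = ov_paths),
                         paste0(path, ".legend.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polygon layer
#'
#' A light vector container: one geometry per record plus attributes.
#' Geometries are multipolygons: a list of polygons, each polygon a list of
#' rings, each ring an (n x 2) coordinate matrix (first ring exterior,
#' further rings holes; rings are stored unclosed).
#'
#' @param ids Character vector of unique feature ids.
#' @param geoms List of multipolygon geometries (see description).
#' @param attrs Data frame of attributes, one row per feature (optional).
#' @param crs CRS identifier shared with the rasters.
#' @param cells Optional list of cell-index vectors when geometries are
#'   grid-aligned (kept alongside for exact zonal work).
#' @return An object of class `polygon_layer`.
#' @export
polygon_layer <- function(ids, geoms, attrs = NULL, crs = NULL, cells = NULL) {
  ids <- as.character(ids)
  stopifnot(!anyDuplicated(ids), length(ids) == length(geoms))
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(ids))
  stopifnot(nrow(attrs) == length(ids))
  structure(list(ids = ids, geoms = geoms, attrs = attrs, crs = crs,
                 cells = cells),
            class = "polygon_layer")
}

#' @export
print.polygon_layer <- function(x, ...) {
  cat(sprintf("polygon_layer: %d features, attributes: %s\n",
              length(x$ids), paste(names(x$attrs), collapse = ", ")))
  invisible(x)
}

#' @export
length.polygon_layer <- function(x) length(x$ids)

#' Read / write polygon layers as GeoJSON
#'
#' @param path GeoJSON file path.
#' @return `read_polygons` returns a [polygon_layer()]; `write_polygons`
#'   returns `path` invisibly.
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not GeoJSON: ", path)
  feats <- fc$features
  ids <- character(length(feats)); geoms <- vector("list", length(feats))
  attrs <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ids[i] <- as.character(f$id %||% f$properties$id %||% i)
    g <- f$geometry
    ring_mat <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    }
    geoms[[i]] <- switch(g$type,
      Polygon = list(lapply(g$coordinates, ring_mat)),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, ring_mat)),
      stop("unsupported geometry type: ", g$type))
    attrs[[i]] <- f$properties[setdiff(names(f$properties), "id")]
  }
  nm <- unique(unlist(lapply(attrs, names)))
  adf <- as.data.frame(stats::setNames(lapply(nm, function(n) {
    sapply(attrs, function(a) if (is.null(a[[n]])) NA else a[[n]])
  }), nm), optional = TRUE)
  polygon_layer(ids, geoms, adf, crs = fc$crs$properties$name %||% NULL)
}

#' @rdname read_polygons
#' @param layer A [polygon_layer()].
#' @export
write_polygons <- function(layer, path) {
  close_ring <- function(m) lapply(seq_len(nrow(m) + 1), function(i) {
    j <- if (i > nrow(m)) 1 else i
    c(m[j, 1], m[j, 2])
  })
  feats <- lapply(seq_along(layer$ids), function(i) {
    props <- as.list(layer$attrs[i, , drop = FALSE])
    props$id <- layer$ids[i]
    g <- layer$geoms[[i]]
    list(type = "Feature", id = layer$ids[i], properties = props,
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(g, function(p) lapply(p, close_ring))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(layer$crs))
    fc$crs <- list(type = "name", properties = list(name = layer$crs))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
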