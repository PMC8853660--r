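#' Delineation configuration
#'
#' Controls how top-value supply areas are carved out of an ES value raster.
#' `top_fraction = 0.5` keeps the top-valued half of the supply-positive
#' cells (the median threshold, ties retained); `threshold_mode =
#' "cumulative_value"` instead keeps the fewest highest-value cells holding
#' that fraction of the total value.
#'
#' @param top_fraction Fraction of supply-positive cells (or value) kept, in
#'   (0, 1].
#' @param adjacency Cell adjacency for aggregation: `"queen"` (default,
#'   8-neighbour, the most permissive reading of "immediately adjacent") or
#'   `"rook"`.
#' @param min_area_cells Components smaller than this many cells are dropped.
#' @param norm_range Two-element numeric, the unit-less normalization range.
#' @param threshold_mode `"quantile"` (cell-value quantile) or
#'   `"cumulative_value"`.
#' @param la_value `"mean"` (default: LA raw value = area ha x mean cell
#'   value) or `"sum"` (area ha x summed cell value).
#' @return An object of class `delineation_config`.
#' @export
delineation_config <- function(top_fraction = 0.5,
                               adjacency = c("queen", "rook"),
                               min_area_cells = 1L,
                               norm_range = c(1, 10000),
                               threshold_mode = c("quantile", "cumulative_value"),
                               la_value = c("mean", "sum")) {
  stopifnot(top_fraction > 0, top_fraction <= 1,
            min_area_cells >= 0, norm_range[1] < norm_range[2])
  structure(list(top_fraction = top_fraction,
                 adjacency = match.arg(adjacency),
                 min_area_cells = as.integer(min_area_cells),
                 norm_range = as.numeric(norm_range),
                 threshold_mode = match.arg(threshold_mode),
                 la_value = match.arg(la_value)),
            class = "delineation_config")
}

#' Mask of top-valued supply cells
#'
#' Thresholds the supply-positive cells (unmasked, value > 0) of an ES value
#' raster at the `(1 - top_fraction)` quantile of their values; cells tying
#' the threshold are retained. An all-zero raster yields an empty mask with a
#' warning.
#'
#' @param raster A [value_raster()] of non-negative supply values.
#' @param cfg A [delineation_config()].
#' @return Logical matrix, `TRUE` on retained cells.
#' @export
top_value_mask <- function(raster, cfg = delineation_config()) {
  stopifnot(inherits(raster, "value_raster"))
  v <- raster$values
  pos <- !is.na(v) & v > 0
  if (!any(pos)) {
    warning("raster has no supply-positive cells; mask is empty")
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  vals <- v[pos]
  thr <- switch(cfg$threshold_mode,
    quantile = unname(stats::quantile(vals, probs = 1 - cfg$top_fraction)),
    cumulative_value = {
      s <- sort(vals, decreasing = TRUE)
      k <- which(cumsum(s) >= cfg$top_fraction * sum(s))[1]
      s[k]
    })
  pos & v >= thr
}

#' Dissolve adjacent parcels into single polygons
#'
#' Merges touching or overlapping parcels (e.g. agricultural land-use
#' inventory polygons) into single features, concatenating their character
#' attributes (crop types) and summing numeric ones. When a grid is supplied
#' (or the layer carries cell sets) the dissolve is exact cell-set algebra:
#' parcels are rasterized, their union split into queen-connected components,
#' and each component re-polygonized. Without a grid a shared-vertex test is
#' used, which is exact for boundary-sharing parcel fabrics.
#'
#' @param parcels A [polygon_layer()].
#' @param grid Optional [grid_spec()] for the exact grid-based dissolve.
#' @return A dissolved [polygon_layer()].
#' @export
dissolve_parcels <- function(parcels, grid = NULL) {
  stopifnot(inherits(parcels, "polygon_layer"))
  n <- length(parcels$ids)
  if (n == 0L) return(parcels)

  if (!is.null(grid) || !is.null(parcels$cells)) {
    if (is.null(grid)) stop("parcel layer carries cells but no grid was given")
    cells <- parcels$cells
    if (is.null(cells)) cells <- lapply(parcels$geoms, rasterize_geom, grid = grid)
    mask <- matrix(FALSE, grid$nrow, grid$ncol)
    mask[unlist(cells)] <- TRUE
    cc <- connected_components(mask, "queen")
    member <- vapply(cells, function(cs) {
      if (!length(cs)) NA_integer_ else cc$labels[cs[1]]
    }, integer(1))
    groups <- split(seq_len(n), member)
  } else {
    # union-find over parcels sharing a vertex or containing another's vertex
    vkeys <- lapply(parcels$geoms, function(g) {
      m <- do.call(rbind, unlist(g, recursive = FALSE))
      unique(paste(signif(m[, 1], 12), signif(m[, 2], 12)))
    })
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      touch <- length(intersect(vkeys[[i]], vkeys[[j]])) > 0
      if (!touch) {
        p <- parcels$geoms[[j]][[1]][[1]][1, ]
        touch <- point_in_geom(p[1], p[2], parcels$geoms[[i]])
      }
      if (touch) parent[find(j)] <- find(i)
    }
    groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  }

  agg_attrs <- function(rows) {
    out <- lapply(parcels$attrs[rows, , drop = FALSE], function(col) {
      if (is.numeric(col)) sum(col, na.rm = TRUE)
      else paste(sort(unique(stats::na.omit(as.character(col)))), collapse = "+")
    })
    out$source_ids <- paste(parcels$ids[rows], collapse = "+")
    as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
  }
  attrs <- do.call(rbind, lapply(groups, agg_attrs))

  if (!is.null(grid) || !is.null(parcels$cells)) {
    comp_cells <- lapply(groups, function(rows) sort(unique(unlist(cells[rows]))))
    return(polygonize(comp_cells, grid, ids = seq_along(groups), attrs = attrs))
  }
  geoms <- lapply(groups, function(rows) do.call(c, parcels$geoms[rows]))
  polygon_layer(seq_along(groups), geoms, attrs, crs = parcels$crs)
}

#' Delineate top-value ES supply areas
#'
#' Turns an ES value raster into the nodes of the connectivity network. For
#' WF and LA, supply areas are the connected components of the top-value mask
#' (under `cfg$adjacency`); for PA they are the dissolved crop parcels clipped
#' to the top-value mask. Each area's raw value follows the ES-specific rule:
#' PA = potential crop area (ha); WF = summed WF model value over the area;
#' LA = area (ha) x mean LA model value (or x summed value with
#' `cfg$la_value = "sum"`). Raw values are then min-max normalized per ES to
#' `cfg$norm_range` (default 1-10,000).
#'
#' @param raster The ES [value_raster()].
#' @param es_type `"PA"`, `"WF"` or `"LA"`.
#' @param cfg A [delineation_config()].
#' @param parcels Dissolved parcel [polygon_layer()] (required for PA).
#' @return An object of class `supply_area_set`.
#' @export
delineate_supply_areas <- function(raster, es_type = c("WF", "LA", "PA"),
                                   cfg = delineation_config(), parcels = NULL) {
  es_type <- match.arg(es_type)
  grid <- raster$grid
  mask <- top_value_mask(raster, cfg)

  if (es_type == "PA") {
    if (is.null(parcels)) stop("PA delineation requires a parcel layer")
    pcells <- parcels$cells
    if (is.null(pcells)) pcells <- lapply(parcels$geoms, rasterize_geom, grid = grid)
    comps <- lapply(pcells, function(cs) cs[mask[cs]])
    keep <- lengths(comps) >= max(1L, cfg$min_area_cells)
    comps <- comps[keep]
  } else {
    cc <- connected_components(mask, cfg$adjacency)
    comps <- cc$components[lengths(cc$components) >= max(1L, cfg$min_area_cells)]
  }

  raw <- vapply(comps, function(cs) {
    ha <- cells_to_ha(length(cs), grid)
    switch(es_type,
      PA = ha,
      WF = zonal_sum(raster, cs),
      LA = ha * if (cfg$la_value == "mean") zonal_mean(raster, cs)
                else zonal_sum(raster, cs))
  }, numeric(1))

  ids <- if (length(comps)) paste0(es_type, "_", seq_along(comps)) else character(0)
  norm <- if (length(raw)) normalize_weights(raw, cfg$norm_range[1], cfg$norm_range[2])
          else numeric(0)
  structure(list(es_type = es_type, grid = grid, ids = ids,
                 cells = comps, raw_value = raw, norm_weight = norm),
            class = "supply_area_set")
}

#' @export
print.supply_area_set <- function(x, ...) {
  cat(sprintf("supply_area_set (%s): %d areas, %d cells, raw value range [%g, %g]\n",
              x$es_type, length(x$ids), sum(lengths(x$cells)),
              if (length(x$raw_value)) min(x$raw_value) else NA,
              if (length(x$raw_value)) max(x$raw_value) else NA))
  invisible(x)
}

#' @export
length.supply_area_set <- function(x) length(x$ids)

#' @export
as.data.frame.supply_area_set <- function(x, ...) {
  data.frame(id = x$ids, es_type = rep(x$es_type, length(x$ids)),
             n_cells = lengths(x$cells),
             area_ha = cells_to_ha(1, x$grid) * lengths(x$cells),
             raw_value = x$raw_value, norm_weight = x$norm_weight,
             stringsAsFactors = FALSE)
}

#' Convert a supply-area set to a polygon layer
#'
#' @param x A `supply_area_set`.
#' @return A [polygon_layer()] with `es_type`, `raw_value`, `norm_weight`.
#' @export
supply_areas_to_polygons <- function(x) {
  polygonize(x$cells, x$grid, ids = x$ids,
             attrs = as.data.frame(x)[, c("es_type", "raw_value", "norm_weight")])
}

#' Min-max normalization onto a unit-less weight scale
#'
#' Linear map of raw values onto `[low, high]` (default 1-10,000):
#' `w' = low + (high - low) * (w - min) / (max - min)`. A degenerate group
#' (all values equal) maps entirely to `high`.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param low,high Target range endpoints.
#' @return Numeric vector of normalized weights in `[low, high]`.
#' @export
normalize_weights <- function(values, low = 1, high = 10000) {
  if (!length(values)) stop("cannot normalize an empty value set")
  if (any(is.na(values)) || any(!is.finite(values)))
    stop("normalize_weights requires finite, non-missing values")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(high, length(values)))
  low + (high - low) * (values - rng[1]) / (rng[2] - rng[1])
}
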