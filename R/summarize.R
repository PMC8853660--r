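#' Amalgamate link weights into a single connectivity raster
#'
#' Per-cell sum of link weights across every link whose geometry covers the
#' cell: overlap polygons contribute at their member cells, topographic
#' corridors at their traced cells (each once per link). Cells no link covers
#' are zero. By default the per-rule normalized weights are accumulated so no
#' link type dominates by natural-unit scale; `scale = "raw"` accumulates raw
#' weights instead.
#'
#' @param links A `functional_links` object (normalized when
#'   `scale = "norm"`).
#' @param grid A [grid_spec()] (defaults to the links' grid).
#' @param scale `"norm"` or `"raw"`.
#' @return A [value_raster()] of accumulated link values.
#' @export
amalgamate_links <- function(links, grid = attr(links, "grid"),
                             scale = c("norm", "raw")) {
  scale <- match.arg(scale)
  acc <- matrix(0, grid$nrow, grid$ncol)
  if (nrow(links)) {
    w <- if (scale == "norm") links$norm_weight else links$raw_weight
    if (scale == "norm" && anyNA(w))
      stop("links carry no normalized weights; run normalize_link_weights()")
    for (i in seq_len(nrow(links)))
      acc[unique(links$cells[[i]])] <- acc[unique(links$cells[[i]])] + w[i]
  }
  value_raster(acc, grid)
}

#' LULC coverage of a feature set
#'
#' Compares the union footprint of a feature set (supply areas of one ES, or
#' the links of one rule) against a categorical LULC raster. For every LULC
#' class the table reports the covered area (ha), the percentage of the
#' feature union on that class (`pct_of_feature`), and the percentage of the
#' class's total area covered (`pct_of_class_total`). Overlay classes (e.g.
#' park over forest/grassland/shrub/rock) are computed from their masks
#' independently of the base classification, so `pct_of_feature` summed over
#' all rows may exceed 100. Codes absent from the legend are reported as
#' `"unknown"`. Overlapping features never double-count area (union
#' semantics).
#'
#' @param features A `supply_area_set`, `functional_links`, [polygon_layer()]
#'   with cells, list of cell vectors, or a single cell vector.
#' @param lulc A [categorical_raster()] on the same grid.
#' @param feature_set Label for the table's `feature_set` column.
#' @return A data frame of class `coverage_table`.
#' @export
lulc_coverage <- function(features, lulc, feature_set = "features") {
  stopifnot(inherits(lulc, "categorical_raster"))
  grid <- lulc$grid
  cells <- feature_union_cells(features)
  n_feat <- length(cells)
  ha <- cells_to_ha(1, grid)

  codes <- lulc$codes
  known <- as.integer(names(lulc$legend))
  class_names <- c(unname(lulc$legend),
                   if (any(!is.na(codes) & !(codes %in% known))) "unknown")
  rows <- lapply(class_names, function(cn) {
    cls_cells <- if (cn == "unknown") which(!is.na(codes) & !(codes %in% known))
                 else which(!is.na(codes) & codes == known[match(cn, unname(lulc$legend))])
    cov <- sum(cells %in% cls_cells)
    data.frame(feature_set = feature_set, lulc_class = cn,
               area_ha = cov * ha,
               pct_of_feature = if (n_feat) 100 * cov / n_feat else 0,
               pct_of_class_total = if (length(cls_cells)) 100 * cov / length(cls_cells) else 0,
               class_total_ha = length(cls_cells) * ha,
               overlay = FALSE, stringsAsFactors = FALSE)
  })
  ov_rows <- lapply(names(lulc$overlays), function(nm) {
    cls_cells <- which(lulc$overlays[[nm]])
    cov <- sum(cells %in% cls_cells)
    data.frame(feature_set = feature_set, lulc_class = nm,
               area_ha = cov * ha,
               pct_of_feature = if (n_feat) 100 * cov / n_feat else 0,
               pct_of_class_total = if (length(cls_cells)) 100 * cov / length(cls_cells) else 0,
               class_total_ha = length(cls_cells) * ha,
               overlay = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, ov_rows))
  class(out) <- c("coverage_table", "data.frame")
  out
}

feature_union_cells <- function(features) {
  if (inherits(features, "supply_area_set")) return(unique(unlist(features$cells)))
  if (inherits(features, "functional_links")) return(unique(unlist(features$cells)))
  if (inherits(features, "polygon_layer")) {
    if (!is.null(features$cells)) return(unique(unlist(features$cells)))
    stop("polygon layer has no cell footprint; rasterize it first")
  }
  if (is.list(features)) return(unique(unlist(features)))
  unique(as.integer(features))
}

#' Coverage tables for all supply areas and link rules
#'
#' Convenience wrapper producing one [lulc_coverage()] table per ES supply
#' set and per link rule, bound together.
#'
#' @param supply Named list of `supply_area_set`s.
#' @param links A `functional_links` object (all rules together).
#' @param lulc A [categorical_raster()].
#' @return A `coverage_table` data frame.
#' @export
coverage_report <- function(supply, links, lulc) {
  tabs <- lapply(names(supply), function(es)
    lulc_coverage(supply[[es]], lulc, feature_set = paste0("supply_", es)))
  for (rid in unique(links$rule_id)) {
    sub <- links[links$rule_id == rid, , drop = FALSE]
    class(sub) <- c("functional_links", "data.frame")
    tabs <- c(tabs, list(lulc_coverage(sub, lulc, feature_set = paste0("link_", rid))))
  }
  out <- do.call(rbind, tabs)
  class(out) <- c("coverage_table", "data.frame")
  out
}
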