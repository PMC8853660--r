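# Link-type registry and the functional-link container shared by the overlap
# and topographic link builders.

# The eight mechanisms with a defined functional connection between the three
# ES; every other ordered pair has none and cannot be registered.
LINK_RULES <- data.frame(
  rule_id      = c("OV_WF_PA", "OV_PA_WF", "OV_LA_WF", "OV_WF_LA", "OV_PA_LA",
                   "TP_WF_WF", "TP_WF_PA", "TP_WF_LA"),
  link_class   = c(rep("overlap", 5), rep("topographic", 3)),
  source_es    = c("WF", "PA", "LA", "WF", "PA", "WF", "WF", "WF"),
  recipient_es = c("PA", "WF", "WF", "LA", "LA", "WF", "PA", "LA"),
  # zonal scope of the weight rule: the pair intersection restricted to the
  # top-value source cells, or the entire source supply area
  weight_scope = c("intersection", "source_area", "source_area",
                   "intersection", "source_area", "path", "path", "path"),
  weight_raster = c("WF", "WF", "WF", "WF", "LA", "WF", "WF", "WF"),
  mechanism = c(
    "WF regulation on PA croplands: summed WF supply-area values within the PA supply area",
    "PA croplands providing WF regulation: all summed WF values within the entire PA supply area",
    "LA areas providing WF regulation: summed WF values within the LA supply area",
    "WF regulation on LA areas: summed WF supply-area values within the LA supply area",
    "PA cropland providing LA: summed LA values within the PA supply area",
    "WF regulation downslope: summed WF values along the LCP from WF1 to WF2",
    "WF regulation downslope: summed WF values along the LCP from WF to PA",
    "WF regulation downslope: summed WF values along the LCP from WF to LA"),
  stringsAsFactors = FALSE)

#' The functional link-type registry
#'
#' Returns the eight directed link rules between the three ES: five overlap
#' rules (WF->PA, PA->WF, LA->WF, WF->LA, PA->LA) and three topographic rules
#' (WF->WF, WF->PA, WF->LA). No other ordered pair carries a functional
#' mechanism; [link_rule()] refuses to resolve one.
#'
#' @return Data frame of rules (`rule_id`, `link_class`, `source_es`,
#'   `recipient_es`, `weight_scope`, `weight_raster`, `mechanism`).
#' @export
link_rules <- function() LINK_RULES

#' Resolve (and validate) one link rule
#'
#' @param link_class `"overlap"` or `"topographic"`.
#' @param source_es,recipient_es ES codes (`"PA"`, `"WF"`, `"LA"`).
#' @return A one-row data frame from [link_rules()].
#' @export
link_rule <- function(link_class, source_es, recipient_es) {
  link_class <- match.arg(link_class, c("overlap", "topographic"))
  source_es <- match.arg(source_es, c("PA", "WF", "LA"))
  recipient_es <- match.arg(recipient_es, c("PA", "WF", "LA"))
  hit <- LINK_RULES$link_class == link_class &
    LINK_RULES$source_es == source_es & LINK_RULES$recipient_es == recipient_es
  if (!any(hit))
    stop("no functional connection is defined from ", source_es, " to ",
         recipient_es, " as a ", link_class, " link")
  LINK_RULES[hit, , drop = FALSE]
}

# internal constructor for the link container (a data frame subclass with the
# cell geometries in a list column: overlap links hold unordered intersection
# cells, topographic links the ordered corridor cells)
new_links <- function(rule, source_id, recipient_id, cells, raw_weight,
                      grid, flagged = FALSE) {
  n <- length(source_id)
  ids <- character(n)
  if (n > 0) ids <- paste0(rule$rule_id, "_", seq_len(n))
  df <- data.frame(
    id = ids,
    rule_id = rep_len(rule$rule_id, n), link_class = rep_len(rule$link_class, n),
    source_es = rep_len(rule$source_es, n),
    recipient_es = rep_len(rule$recipient_es, n),
    source_id = as.character(source_id), recipient_id = as.character(recipient_id),
    raw_weight = as.numeric(raw_weight), norm_weight = rep(NA_real_, n),
    n_cells = lengths(cells), flagged = rep_len(flagged, n),
    stringsAsFactors = FALSE)
  df$cells <- cells
  structure(df, class = c("functional_links", "data.frame"), grid = grid)
}

#' Bind link sets together
#'
#' @param ... `functional_links` objects.
#' @return A single `functional_links` object.
#' @export
bind_links <- function(...) {
  ls <- Filter(Negate(is.null), list(...))
  if (length(ls) == 1L && !inherits(ls[[1]], "functional_links"))
    ls <- ls[[1]]
  stopifnot(all(vapply(ls, inherits, logical(1), "functional_links")))
  grid <- attr(ls[[1]], "grid")
  out <- do.call(rbind.data.frame, c(lapply(ls, as.data.frame), make.row.names = FALSE))
  structure(out, class = c("functional_links", "data.frame"), grid = grid)
}

#' @export
print.functional_links <- function(x, ...) {
  cat(sprintf("functional_links: %d links\n", nrow(x)))
  if (nrow(x)) print(table(rule = x$rule_id))
  invisible(x)
}

#' Compute one overlap link type between two supply-area sets
#'
#' Applies a GIS-clip between every (source, recipient) supply-area pair of
#' the rule's ES types: each pair whose cells intersect yields links over the
#' intersection. By default each single-part (queen-connected) intersection
#' polygon is a separate link, matching the census convention of counting
#' single-part overlap polygons; `split_parts = FALSE` keeps one multi-part
#' link per pair. Weights follow the rule's zonal scope (see
#' [weight_overlap_link()]); links whose weighting cells are all nodata get
#' weight 0 and are flagged.
#'
#' @param source_set,recipient_set [delineate_supply_areas()] outputs whose
#'   `es_type` match the rule.
#' @param rule A one-row rule from [link_rule()] with `link_class "overlap"`.
#' @param rasters Named list of ES value rasters (needs the rule's
#'   `weight_raster`, e.g. `rasters$WF`).
#' @param split_parts Split multi-part intersections into single-part links.
#' @return A `functional_links` object.
#' @export
compute_overlap_links <- function(source_set, recipient_set, rule, rasters,
                                  split_parts = TRUE) {
  if (!identical(rule$link_class, "overlap"))
    stop("compute_overlap_links requires an overlap rule, got ", rule$link_class)
  stopifnot(source_set$es_type == rule$source_es,
            recipient_set$es_type == rule$recipient_es)
  grid <- source_set$grid
  stopifnot(same_grid(grid, recipient_set$grid))
  wr <- rasters[[rule$weight_raster]]
  if (is.null(wr)) stop("missing weighting raster: ", rule$weight_raster)

  src_id <- rec_id <- character(0)
  cells <- list(); raw <- numeric(0); flagged <- logical(0)
  for (i in seq_along(source_set$ids)) {
    sc <- source_set$cells[[i]]
    for (j in seq_along(recipient_set$ids)) {
      inter <- intersect(sc, recipient_set$cells[[j]])
      if (!length(inter)) next
      parts <- if (split_parts) split_cell_parts(inter, grid) else list(sort(inter))
      for (p in parts) {
        w <- weight_overlap_cells(rule, p, source_set$cells[[i]], wr)
        src_id <- c(src_id, source_set$ids[i])
        rec_id <- c(rec_id, recipient_set$ids[j])
        cells <- c(cells, list(p))
        raw <- c(raw, w$weight)
        flagged <- c(flagged, w$flagged)
      }
    }
  }
  new_links(rule, src_id, rec_id, cells, raw, grid, flagged)
}

split_cell_parts <- function(cells, grid) {
  mask <- matrix(FALSE, grid$nrow, grid$ncol)
  mask[cells] <- TRUE
  connected_components(mask, "queen")$components
}

weight_overlap_cells <- function(rule, inter_cells, source_cells, wraster) {
  zone <- switch(rule$weight_scope,
                 intersection = inter_cells,
                 source_area = source_cells,
                 stop("not an overlap weight scope: ", rule$weight_scope))
  vals <- wraster$values[zone]
  list(weight = sum(vals, na.rm = TRUE),
       flagged = all(is.na(wraster$values[inter_cells])))
}

#' Weight one overlap link
#'
#' Resolves the Table-of-mechanisms zonal sum for a link: rules phrased over
#' "supply area values" sum the weighting raster over the pair intersection
#' (which lies inside the top-value source cells); rules phrased over the
#' entire source supply area (PA->WF, PA->LA, LA->WF) sum it over all cells
#' of the source area, whether or not they are top-valued in the weighting
#' raster.
#'
#' @param link One-row subset of a `functional_links` object.
#' @param source_set The supply-area set the link's source belongs to.
#' @param rasters Named list of ES value rasters.
#' @return The raw weight (a single real).
#' @export
weight_overlap_link <- function(link, source_set, rasters) {
  rule <- link_rule(link$link_class, link$source_es, link$recipient_es)
  wr <- rasters[[rule$weight_raster]]
  if (is.null(wr)) stop("missing weighting raster: ", rule$weight_raster)
  sc <- source_set$cells[[match(link$source_id, source_set$ids)]]
  weight_overlap_cells(rule, link$cells[[1]], sc, wr)$weight
}

#' Normalize link weights within each rule group
#'
#' Min-max normalization of `raw_weight` to the 1-10,000 scale, applied
#' separately per rule (the rules weigh in different natural units); a
#' degenerate group maps to the top of the scale, as for supply areas.
#'
#' @param links A `functional_links` object.
#' @param low,high Range endpoints.
#' @return `links` with `norm_weight` filled in.
#' @export
normalize_link_weights <- function(links, low = 1, high = 10000) {
  if (!nrow(links)) return(links)
  for (rid in unique(links$rule_id)) {
    sel <- links$rule_id == rid
    links$norm_weight[sel] <- normalize_weights(links$raw_weight[sel], low, high)
  }
  links
}

#' Convert links to a polygon layer
#'
#' Overlap links become their intersection polygons; topographic links the
#' one-cell-wide corridor footprint.
#'
#' @param links A `functional_links` object.
#' @param grid The [grid_spec()] the links live on (defaults to the links'
#'   own grid attribute).
#' @return A [polygon_layer()].
#' @export
links_to_polygons <- function(links, grid = attr(links, "grid")) {
  polygonize(lapply(links$cells, function(cs) sort(unique(cs))), grid,
             ids = links$id,
             attrs = as.data.frame(links)[, c("rule_id", "link_class",
                                              "source_id", "recipient_id",
                                              "raw_weight", "norm_weight")])
}

#' Link census per rule
#'
#' @param links A `functional_links` object.
#' @return Data frame with one row per rule: link count, weight summaries.
#' @export
link_census <- function(links) {
  rules <- link_rules()
  n <- vapply(rules$rule_id, function(r) sum(links$rule_id == r), integer(1))
  data.frame(rule_id = rules$rule_id, link_class = rules$link_class,
             source_es = rules$source_es, recipient_es = rules$recipient_es,
             n_links = n,
             total_raw_weight = vapply(rules$rule_id, function(r)
               sum(links$raw_weight[links$rule_id == r]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
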