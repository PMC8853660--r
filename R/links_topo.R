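# Topographic links: least-cost corridors from WF supply areas downslope to
# sub-basin outlets, extended through downstream influential landscape
# features, then segmented into source -> recipient links.

#' Influential landscape feature (ILF) zone
#'
#' Wetlands, floodplains, riparian areas and seasonally flooded fields
#' functionally tied to upstream flow regulation; corridors are extended from
#' sub-basin outlets to downstream ILF zones.
#'
#' @param id Zone id.
#' @param cells Linear cell indices of the zone footprint (non-empty).
#' @param kind One of `"wetland"`, `"floodplain"`, `"riparian"`,
#'   `"seasonally-flooded-field"`.
#' @param downstream_of Character vector of sub-basin ids the zone lies
#'   downstream of (may be left empty and inferred from D8 routing).
#' @return An object of class `ilf_zone`.
#' @export
ilf_zone <- function(id, cells, kind = c("wetland", "floodplain", "riparian",
                                         "seasonally-flooded-field"),
                     downstream_of = character(0)) {
  kind <- match.arg(kind)
  stopifnot(length(cells) > 0)
  structure(list(id = as.character(id), cells = as.integer(cells),
                 kind = kind, downstream_of = as.character(downstream_of)),
            class = "ilf_zone")
}

#' Trace outlet corridors for every WF supply area
#'
#' For each WF supply area, computes the least-cost path from the area's
#' lowest-elevation cell (where water exits the area) to the outlet of the
#' sub-basin containing that cell. An area already containing its outlet gets
#' a zero-length (single-cell) path. Areas straddling a sub-basin divide are
#' assigned by their start cell, with a warning.
#'
#' @param wf_set WF [delineate_supply_areas()] output.
#' @param subbasins A [make_subbasins()] result.
#' @param surface A [build_resistance()] surface.
#' @return List of corridors: each has `source_id`, `basin_id`, `start`,
#'   `cells` (ordered path), `cost`, and an empty `extensions` list.
#' @export
trace_wf_corridors <- function(wf_set, subbasins, surface) {
  stopifnot(wf_set$es_type == "WF")
  elev <- surface$elev
  lapply(seq_along(wf_set$ids), function(i) {
    cs <- wf_set$cells[[i]]
    z <- elev[cs]
    start <- cs[order(z, cs)][1]
    lab <- subbasins$labels[start]
    if (is.na(lab))
      stop("WF area ", wf_set$ids[i], " starts on a nodata cell")
    labs <- unique(subbasins$labels[cs])
    if (length(stats::na.omit(labs)) > 1L)
      warning("WF area ", wf_set$ids[i],
              " spans a sub-basin divide; assigned by its start cell")
    basin <- subbasins$basins[[lab]]
    if (basin$outlet %in% cs) {
      path <- list(cells = basin$outlet, cost = 0)
    } else {
      path <- tryCatch(lcp_path(surface, start, basin$outlet),
                       error = function(e)
                         stop("no corridor from WF area ", wf_set$ids[i],
                              " to its sub-basin outlet: ", conditionMessage(e),
                              call. = FALSE))
    }
    list(source_id = wf_set$ids[i], basin_id = basin$id, start = start,
         cells = path$cells, cost = path$cost, extensions = list())
  })
}

#' Extend corridors to downstream ILF zones
#'
#' For each sub-basin with downstream ILF zones, computes one least-cost path
#' from the basin outlet to each zone (its lowest-elevation cell) and appends
#' it to every member corridor of that basin. Zones without explicit
#' `downstream_of` tags are tagged by following the D8 receiver chain from
#' each basin outlet. Unreachable zones are skipped with a warning. Each
#' extension records the merged cost (outlet-path cost + extension cost).
#'
#' @param corridors Output of [trace_wf_corridors()].
#' @param ilf_zones List of [ilf_zone()] objects.
#' @param subbasins A [make_subbasins()] result.
#' @param surface A [build_resistance()] surface.
#' @return `corridors` with `extensions` filled: each extension has
#'   `ilf_id`, `cells` (continuing after the outlet), `cost`, `merged_cost`.
#' @export
attach_ilf <- function(corridors, ilf_zones, subbasins, surface) {
  if (!length(ilf_zones)) return(corridors)
  basin_ids <- vapply(subbasins$basins, `[[`, character(1), "id")

  downstream <- lapply(ilf_zones, function(z) z$downstream_of)
  untagged <- which(lengths(downstream) == 0L)
  if (length(untagged)) {
    for (b in seq_along(subbasins$basins)) {
      trace <- d8_trace(subbasins$receivers, subbasins$basins[[b]]$outlet)
      for (zi in untagged)
        if (any(ilf_zones[[zi]]$cells %in% trace))
          downstream[[zi]] <- c(downstream[[zi]], basin_ids[b])
    }
  }

  # one extension LCP per (basin, zone)
  ext_by_basin <- stats::setNames(vector("list", length(basin_ids)), basin_ids)
  for (zi in seq_along(ilf_zones)) {
    z <- ilf_zones[[zi]]
    for (bid in downstream[[zi]]) {
      b <- subbasins$basins[[match(bid, basin_ids)]]
      goal_cells <- z$cells
      goal <- goal_cells[order(surface$elev[goal_cells], goal_cells)][1]
      ext <- tryCatch(lcp_path(surface, b$outlet, goal), error = function(e) NULL)
      if (is.null(ext)) {
        warning("ILF zone ", z$id, " is unreachable from basin ", bid, "; skipped")
        next
      }
      ext_by_basin[[bid]] <- c(ext_by_basin[[bid]],
                               list(list(ilf_id = z$id,
                                         cells = ext$cells[-1],
                                         cost = ext$cost)))
    }
  }

  lapply(corridors, function(co) {
    exts <- ext_by_basin[[co$basin_id]]
    co$extensions <- lapply(exts, function(e) {
      e$merged_cost <- co$cost + e$cost
      e
    })
    co
  })
}

#' All cells a corridor traverses
#'
#' @param corridor One corridor from [trace_wf_corridors()] / [attach_ilf()].
#' @return Integer vector of unique traversed cells.
#' @export
corridor_cells <- function(corridor) {
  unique(c(corridor$cells, unlist(lapply(corridor$extensions, `[[`, "cells"))))
}

#' Segment corridors into topographic links
#'
#' Walks each corridor (and its ILF extensions) cell by cell and emits one
#' directed link per recipient supply area the corridor enters: the link
#' geometry is the sub-path from the source area's exit cell to the
#' recipient's first entered cell, weighted by the summed WF values over
#' those cells. Source-interior cells are excluded by default. Rule-specific
#' restrictions: WF->WF links form only between spatially isolated pairs
#' (areas not queen-adjacent); WF->PA recipients must lie within the
#' corridor's sub-basin or within an ILF zone (when `subbasins` is given).
#'
#' @param corridors Output of [trace_wf_corridors()] / [attach_ilf()].
#' @param source_set The WF supply-area set the corridors originate from.
#' @param recipient_set Supply-area set of the rule's recipient ES.
#' @param rule A topographic rule from [link_rule()].
#' @param wf_raster The WF [value_raster()] used for weighting.
#' @param subbasins Optional [make_subbasins()] result (enables the WF->PA
#'   sub-basin restriction).
#' @param ilf_zones Optional list of [ilf_zone()]s (WF->PA downstream
#'   exemption).
#' @param include_source_cells Include the path cells inside the source area
#'   in link geometry and weight.
#' @return A `functional_links` object (ordered corridor cells as geometry).
#' @export
segment_paths <- function(corridors, source_set, recipient_set, rule, wf_raster,
                          subbasins = NULL, ilf_zones = NULL,
                          include_source_cells = FALSE) {
  if (!identical(rule$link_class, "topographic"))
    stop("segment_paths requires a topographic rule, got ", rule$link_class)
  stopifnot(source_set$es_type == "WF",
            recipient_set$es_type == rule$recipient_es)
  grid <- source_set$grid

  # cell -> recipient area index lookup
  owner <- integer(grid$nrow * grid$ncol)
  for (j in seq_along(recipient_set$ids)) owner[recipient_set$cells[[j]]] <- j

  allowed <- function(co, src_idx, j) {
    if (rule$recipient_es == "WF") {
      if (recipient_set$ids[j] == co$source_id) return(FALSE)
      return(!areas_adjacent(source_set$cells[[src_idx]],
                             recipient_set$cells[[j]], grid))
    }
    if (rule$recipient_es == "PA" && !is.null(subbasins)) {
      lab <- match(co$basin_id, vapply(subbasins$basins, `[[`, character(1), "id"))
      in_basin <- any(subbasins$labels[recipient_set$cells[[j]]] == lab, na.rm = TRUE)
      in_ilf <- length(ilf_zones) &&
        any(recipient_set$cells[[j]] %in% unlist(lapply(ilf_zones, `[[`, "cells")))
      return(in_basin || in_ilf)
    }
    TRUE
  }

  src_id <- rec_id <- character(0)
  geoms <- list(); raw <- numeric(0)
  for (co in corridors) {
    src_idx <- match(co$source_id, source_set$ids)
    scells <- source_set$cells[[src_idx]]
    seqs <- list(co$cells)
    for (e in co$extensions) seqs <- c(seqs, list(c(co$cells, e$cells)))
    seen <- character(0)
    for (sq in seqs) {
      outside <- !(sq %in% scells)
      exit_idx <- if (include_source_cells) 1L else which(outside)[1]
      if (is.na(exit_idx)) next
      hits <- owner[sq]
      hits[seq_len(exit_idx - 1L)] <- 0L # entries before leaving the source
      for (j in unique(hits[hits > 0L])) {
        rid <- recipient_set$ids[j]
        if (rid %in% seen) next
        if (!allowed(co, src_idx, j)) next
        entry <- which(hits == j)[1]
        sub <- sq[exit_idx:entry]
        src_id <- c(src_id, co$source_id)
        rec_id <- c(rec_id, rid)
        geoms <- c(geoms, list(sub))
        raw <- c(raw, weight_topographic_link(sub, wf_raster))
        seen <- c(seen, rid)
      }
    }
  }
  new_links(rule, src_id, rec_id, geoms, raw, grid)
}

areas_adjacent <- function(cells_a, cells_b, grid) {
  if (length(intersect(cells_a, cells_b))) return(TRUE)
  rc <- cell_rowcol(cells_a, grid)
  nbrs <- unlist(lapply(list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                             c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L)),
                        function(d) {
    r <- rc[, "row"] + d[1]; c <- rc[, "col"] + d[2]
    ok <- r >= 1L & r <= grid$nrow & c >= 1L & c <= grid$ncol
    rowcol_cell(r[ok], c[ok], grid)
  }))
  any(cells_b %in% nbrs)
}

#' Weight a topographic link
#'
#' The raw weight is the sum of WF model values over the corridor's traced
#' cells, each cell counted once; nodata cells contribute nothing and a
#' zero-length path weighs 0.
#'
#' @param link A one-row `functional_links` subset, a `cell_path`, or a
#'   vector of path cells.
#' @param wf_raster The WF [value_raster()].
#' @return The raw weight.
#' @export
weight_topographic_link <- function(link, wf_raster) {
  cells <- if (inherits(link, "functional_links")) link$cells[[1]]
           else if (inherits(link, "cell_path")) link$cells
           else as.integer(link)
  if (!length(cells)) return(0)
  sum(wf_raster$values[unique(cells)], na.rm = TRUE)
}
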