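#' Pipeline configuration
#'
#' Run-wide options of the end-to-end connectivity pipeline, serializable to
#' plain-text YAML (CLI flags override file values).
#'
#' @param top_fraction,adjacency,threshold_mode,la_value Supply delineation
#'   options, see [delineation_config()].
#' @param min_area_cells Minimum supply-area size in cells.
#' @param resistance_strategy,k,c_low Resistance options, see
#'   [build_resistance()].
#' @param split_parts Count each single-part overlap polygon as one link.
#' @param amalgam_scale `"norm"` or `"raw"`, see [amalgamate_links()].
#' @param include_source_cells See [segment_paths()].
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(top_fraction = 0.5, adjacency = "queen",
                            threshold_mode = "quantile", la_value = "mean",
                            min_area_cells = 1L,
                            resistance_strategy = "downslope", k = 1, c_low = 500,
                            split_parts = TRUE, amalgam_scale = "norm",
                            include_source_cells = FALSE, seed = 1L) {
  structure(list(top_fraction = top_fraction, adjacency = adjacency,
                 threshold_mode = threshold_mode, la_value = la_value,
                 min_area_cells = as.integer(min_area_cells),
                 resistance_strategy = resistance_strategy, k = k, c_low = c_low,
                 split_parts = isTRUE(split_parts), amalgam_scale = amalgam_scale,
                 include_source_cells = isTRUE(include_source_cells),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full ES-connectivity pipeline
#'
#' Executes delineate -> overlap links -> topographic links -> normalize ->
#' amalgamate -> LULC report on an input bundle, optionally writing all
#' products plus a run manifest (input hashes, config echo, per-stage
#' counts). Output files are a pure function of the inputs and config, so
#' reruns are byte-identical.
#'
#' @param input A bundle directory (see [write_bundle()]) or an in-memory
#'   bundle list from [simulate_bundle()] / [read_bundle()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @return List with `supply` (per-ES `supply_area_set`s), `links`
#'   (normalized `functional_links`), `census`, `amalgam`
#'   ([value_raster()]), `coverage` (coverage table) and `manifest`.
#' @export
run_pipeline <- function(input, cfg = pipeline_config(), out_dir = NULL) {
  stage <- "load-inputs"
  on_fail <- function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  withCallingHandlers({
  input_hashes <- NULL
  if (is.character(input)) {
    need <- file.path(input, c("dem.asc", "pa.asc", "wf.asc", "la.asc",
                               "lulc.asc", "parcels.geojson", "bundle.yml"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    input_hashes <- as.list(tools::md5sum(need))
    names(input_hashes) <- basename(need)
    input <- read_bundle(input)
  }
  bundle <- input
  rasters <- list(PA = bundle$pa, WF = bundle$wf, LA = bundle$la)

  dcfg <- delineation_config(cfg$top_fraction, cfg$adjacency,
                             cfg$min_area_cells,
                             threshold_mode = cfg$threshold_mode,
                             la_value = cfg$la_value)
  stage <- "delineate"
  message("delineating top-", round(100 * cfg$top_fraction), "% supply areas")
  dissolved <- dissolve_parcels(bundle$parcels, bundle$grid)
  supply <- list(
    PA = delineate_supply_areas(bundle$pa, "PA", dcfg, parcels = dissolved),
    WF = delineate_supply_areas(bundle$wf, "WF", dcfg),
    LA = delineate_supply_areas(bundle$la, "LA", dcfg))

  stage <- "overlap-links"
  rules <- link_rules()
  ov <- lapply(which(rules$link_class == "overlap"), function(i) {
    r <- rules[i, , drop = FALSE]
    compute_overlap_links(supply[[r$source_es]], supply[[r$recipient_es]],
                          r, rasters, split_parts = cfg$split_parts)
  })

  stage <- "topographic-links"
  filled <- bundle$filled %||% fill_depressions(bundle$dem)
  eps_filled <- fill_depressions(bundle$dem, eps = 1e-6)
  surface <- build_resistance(eps_filled, strategy = cfg$resistance_strategy,
                              k = cfg$k, c_low = cfg$c_low)
  subbasins <- bundle$subbasins %||% make_subbasins(bundle$dem, min_cells = 25L)
  corridors <- trace_wf_corridors(supply$WF, subbasins, surface)
  corridors <- attach_ilf(corridors, bundle$ilf_zones, subbasins, surface)
  tp <- lapply(which(rules$link_class == "topographic"), function(i) {
    r <- rules[i, , drop = FALSE]
    segment_paths(corridors, supply$WF, supply[[r$recipient_es]], r,
                  bundle$wf, subbasins = subbasins,
                  ilf_zones = bundle$ilf_zones,
                  include_source_cells = cfg$include_source_cells)
  })

  stage <- "normalize"
  links <- normalize_link_weights(bind_links(c(ov, tp)))

  stage <- "amalgamate"
  amalgam <- amalgamate_links(links, bundle$grid, scale = cfg$amalgam_scale)

  stage <- "lulc-report"
  coverage <- coverage_report(supply, links, bundle$lulc)
  census <- link_census(links)

  manifest <- list(
    config = unclass(cfg),
    input_hashes = input_hashes,
    grid = list(nrow = bundle$grid$nrow, ncol = bundle$grid$ncol,
                cellsize = bundle$grid$cellsize),
    counts = list(
      supply_areas = lapply(supply, length),
      subbasins = length(subbasins$basins),
      corridors = length(corridors),
      ilf_zones = length(bundle$ilf_zones),
      links_total = nrow(links),
      links_by_rule = as.list(stats::setNames(census$n_links, census$rule_id))))

  out <- list(supply = supply, links = links, census = census,
              amalgam = amalgam, coverage = coverage, manifest = manifest,
              corridors = corridors, subbasins = subbasins)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
  }, error = on_fail)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  for (es in names(res$supply))
    if (length(res$supply[[es]]))
      write_polygons(supply_areas_to_polygons(res$supply[[es]]),
                     p(paste0("supply_", es, ".geojson")))
  if (nrow(res$links))
    write_polygons(links_to_polygons(res$links), p("links.geojson"))
  utils::write.csv(res$census, p("link_census.csv"), row.names = FALSE)
  utils::write.csv(res$coverage, p("lulc_coverage.csv"), row.names = FALSE)
  sup <- do.call(rbind, lapply(res$supply, as.data.frame))
  utils::write.csv(sup, p("supply_areas.csv"), row.names = FALSE)
  write_raster(res$amalgam, p("amalgam.asc"))
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
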