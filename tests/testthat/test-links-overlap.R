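test_that("the registry holds exactly the eight defined mechanisms", {
  rules <- link_rules()
  expect_equal(nrow(rules), 8)
  expect_equal(sum(rules$link_class == "overlap"), 5)
  expect_equal(sum(rules$link_class == "topographic"), 3)
  ov <- rules[rules$link_class == "overlap", ]
  expect_setequal(paste(ov$source_es, ov$recipient_es),
                  c("WF PA", "PA WF", "LA WF", "WF LA", "PA LA"))
  tp <- rules[rules$link_class == "topographic", ]
  expect_true(all(tp$source_es == "WF"))
  expect_setequal(tp$recipient_es, c("WF", "PA", "LA"))
})

test_that("undefined ES pairs cannot be resolved as rules", {
  expect_error(link_rule("overlap", "LA", "PA"), "no functional connection")
  expect_error(link_rule("topographic", "PA", "WF"), "no functional connection")
  expect_error(link_rule("topographic", "LA", "LA"), "no functional connection")
  expect_error(link_rule("overlap", "WF", "WF"), "no functional connection")
  expect_silent(link_rule("overlap", "PA", "LA"))
})

make_wf_raster <- function(g, cells, vals) {
  m <- matrix(0, g$nrow, g$ncol)
  m[cells] <- vals
  value_raster(m, g)
}

test_that("overlap links appear only where supplies intersect", {
  g <- grid_spec(8, 8, 29)
  wf_cells <- rowcol_cell(c(2, 2), c(2, 3), g)
  far <- rowcol_cell(c(7, 7), c(6, 7), g)
  rasters <- list(WF = make_wf_raster(g, wf_cells, c(5, 5)),
                  LA = make_wf_raster(g, far, c(1, 1)))
  wf <- manual_supply_set("WF", list(wf_cells), g)
  la_far <- manual_supply_set("LA", list(far), g)
  none <- compute_overlap_links(wf, la_far, link_rule("overlap", "WF", "LA"),
                                rasters)
  expect_equal(nrow(none), 0)

  la_same <- manual_supply_set("LA", list(wf_cells), g)
  fwd <- compute_overlap_links(wf, la_same, link_rule("overlap", "WF", "LA"),
                               rasters)
  rev <- compute_overlap_links(la_same, wf, link_rule("overlap", "LA", "WF"),
                               rasters)
  expect_equal(nrow(fwd), 1)
  expect_equal(nrow(rev), 1)
  expect_setequal(fwd$cells[[1]], rev$cells[[1]])  # identical geometry
  expect_error(
    compute_overlap_links(wf, la_same, link_rule("topographic", "WF", "LA"),
                          rasters),
    "overlap rule")
})

test_that("weight scopes distinguish supply-area values from entire-area sums", {
  g <- grid_spec(8, 8, 29)
  pa_cells <- rowcol_cell(rep(2:4, each = 3), rep(2:4, 3), g)  # 9-cell farm
  wf_top <- rowcol_cell(c(2, 2), c(2, 3), g)                   # top-WF inside it
  stray <- rowcol_cell(3, 4, g)                                # non-top WF cell
  wf_raster <- make_wf_raster(g, c(wf_top, stray), c(10, 20, 5))
  rasters <- list(WF = wf_raster, PA = make_wf_raster(g, pa_cells, 50))

  pa <- manual_supply_set("PA", list(pa_cells), g)
  wf <- manual_supply_set("WF", list(wf_top), g)

  # WF->PA: summed WF supply-area values within the PA area = 10 + 20
  wf_pa <- compute_overlap_links(wf, pa, link_rule("overlap", "WF", "PA"), rasters)
  expect_equal(wf_pa$raw_weight, 30)
  # PA->WF: all WF values within the entire PA area = 10 + 20 + 5
  pa_wf <- compute_overlap_links(pa, wf, link_rule("overlap", "PA", "WF"), rasters)
  expect_equal(pa_wf$raw_weight, 35)
  # weight_overlap_link reproduces both from the stored links
  expect_equal(weight_overlap_link(wf_pa[1, ], wf, rasters), 30)
  expect_equal(weight_overlap_link(pa_wf[1, ], pa, rasters), 35)
})

test_that("all-nodata intersections weigh zero and are flagged", {
  g <- grid_spec(5, 5, 29)
  cells <- rowcol_cell(c(2, 2), c(2, 3), g)
  wf_na <- value_raster(matrix(NA_real_, 5, 5), g)
  rasters <- list(WF = wf_na)
  wf <- manual_supply_set("WF", list(cells), g)
  la <- manual_supply_set("LA", list(cells), g)
  out <- compute_overlap_links(wf, la, link_rule("overlap", "WF", "LA"), rasters)
  expect_equal(out$raw_weight, 0)
  expect_true(out$flagged)
})

test_that("multi-part intersections split into single-part links by default", {
  g <- grid_spec(6, 6, 29)
  # two separate 1-cell overlaps between one source and one recipient
  src <- rowcol_cell(c(2, 2, 2), c(2, 3, 4), g)
  rec <- rowcol_cell(c(2, 3, 2), c(2, 3, 4), g)
  rasters <- list(WF = make_wf_raster(g, src, c(1, 2, 4)))
  wf <- manual_supply_set("WF", list(src), g)
  la <- manual_supply_set("LA", list(rec), g)
  rule <- link_rule("overlap", "WF", "LA")
  split <- compute_overlap_links(wf, la, rule, rasters)
  expect_equal(nrow(split), 2)
  expect_equal(sort(split$raw_weight), c(1, 4))
  multi <- compute_overlap_links(wf, la, rule, rasters, split_parts = FALSE)
  expect_equal(nrow(multi), 1)
  expect_equal(multi$raw_weight, 5)
})

test_that("overlap weights equal brute-force zonal sums on random landscapes", {
  set.seed(31)
  g <- grid_spec(20, 20, 29)
  for (rep in 1:10) {
    wf_m <- matrix(round(runif(400, 0, 100)), 20, 20)
    la_m <- matrix(round(runif(400, 0, 10), 2), 20, 20)
    rasters <- list(WF = value_raster(wf_m, g), LA = value_raster(la_m, g))
    mk <- function() {
      n <- sample(2:4, 1)
      sets <- connected_components(matrix(runif(400) < 0.3, 20, 20))$components
      sets[seq_len(min(n, length(sets)))]
    }
    wf <- manual_supply_set("WF", mk(), g)
    la <- manual_supply_set("LA", mk(), g)
    for (dir in list(c("WF", "LA"), c("LA", "WF"))) {
      rule <- link_rule("overlap", dir[1], dir[2])
      src <- if (dir[1] == "WF") wf else la
      out <- compute_overlap_links(src, if (dir[1] == "WF") la else wf,
                                   rule, rasters)
      for (i in seq_len(nrow(out))) {
        zone <- if (rule$weight_scope == "intersection") out$cells[[i]]
                else src$cells[[match(out$source_id[i], src$ids)]]
        brute <- 0
        for (cl in zone) brute <- brute + wf_m[cl]
        expect_equal(out$raw_weight[i], brute)
        # intersection geometry lies inside the source area
        expect_true(all(out$cells[[i]] %in%
                          src$cells[[match(out$source_id[i], src$ids)]]))
      }
      expect_true(all(out$raw_weight >= 0))
    }
  }
})

test_that("normalization by rule group hits endpoints and preserves order", {
  g <- grid_spec(4, 4, 29)
  cells <- lapply(1:3, function(i) rowcol_cell(i, i, g))
  rule <- link_rule("overlap", "WF", "LA")
  links <- esconnect:::new_links(rule, c("WF_1", "WF_2", "WF_3"),
                                 c("LA_1", "LA_2", "LA_3"), cells,
                                 raw_weight = c(3, 6, 4.5), grid = g)
  out <- normalize_link_weights(links)
  expect_equal(sort(out$norm_weight), c(1, 5000.5, 10000))
  expect_equal(order(out$raw_weight), order(out$norm_weight))
  single <- normalize_link_weights(links[1, , drop = FALSE])
  expect_equal(single$norm_weight, 10000)
})
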