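# Independent oracles used across the suite: these deliberately re-derive
# results by the simplest possible means (flood fill, explicit-graph
# Dijkstra, per-cell loops) and never call the code paths they check.

# recursive flood fill connected components
oracle_components <- function(mask, adjacency = "queen") {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (adjacency == "queen")
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  k <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!isTRUE(mask[r0, c0]) || lab[r0, c0] != 0L) next
    k <- k + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- k
      for (i in seq_len(nrow(nbrs))) {
        r <- p[1] + nbrs$dr[i]; c <- p[2] + nbrs$dc[i]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            isTRUE(mask[r, c]) && lab[r, c] == 0L)
          stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  lab
}

# plain-R Dijkstra on the explicit directed move-cost graph of a resistance
# surface (no heap, O(n^2); fine for small grids)
oracle_dijkstra <- function(surface, start, goal) {
  g <- surface$grid
  n <- g$nrow * g$ncol
  dist <- rep(Inf, n); dist[start] <- 0
  done <- rep(FALSE, n)
  done[is.na(surface$elev)] <- TRUE
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    i <- cand[which.min(dist[cand])]
    done[i] <- TRUE
    if (i == goal) break
    rc <- cell_rowcol(i, g)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- rc[1] + dr; c <- rc[2] + dc
      if (r < 1 || r > g$nrow || c < 1 || c > g$ncol) next
      j <- rowcol_cell(r, c, g)
      if (done[j] || is.na(surface$elev[j])) next
      w <- 1 / conductance(surface, i, j)
      if (dist[i] + w < dist[j]) dist[j] <- dist[i] + w
    }
  }
  dist[goal]
}

# simple pit DEM fixtures
bowl_dem <- function(n = 7, cellsize = 29) {
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  z <- matrix(10 + 2 * pmax(abs(rc$r - (n + 1) / 2), abs(rc$c - (n + 1) / 2)),
              n, n)
  value_raster(z, grid_spec(n, n, cellsize))
}

cone_dem <- function(n = 21, cellsize = 29, slope = 2) {
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  mid <- (n + 1) / 2
  z <- matrix(10 + slope * sqrt((rc$r - mid)^2 + (rc$c - mid)^2), n, n)
  value_raster(z, grid_spec(n, n, cellsize))
}

# a supply_area_set built directly from cell sets (bypasses delineation)
manual_supply_set <- function(es_type, cell_sets, grid, raw = NULL) {
  raw <- raw %||% rep(1, length(cell_sets))
  structure(list(es_type = es_type, grid = grid,
                 ids = paste0(es_type, "_", seq_along(cell_sets)),
                 cells = cell_sets, raw_value = raw,
                 norm_weight = rep(10000, length(cell_sets))),
            class = "supply_area_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_bundle(sim_config(seed = 42))
    cache
  }
})
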