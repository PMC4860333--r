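# Independent oracles and small landscape builders used across the suite.

# brute-force distance to the nearest TRUE cell: exhaustive minimum over all
# mask cells, for both metrics
bf_escape_distance <- function(mask, cell_size, metric = "euclidean") {
  nr <- nrow(mask); nc <- ncol(mask)
  esc <- which(mask, arr.ind = TRUE)
  d <- matrix(Inf, nr, nc)
  if (nrow(esc) == 0L) return(d)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dr <- abs(esc[, 1] - i); dc <- abs(esc[, 2] - j)
    d[i, j] <- if (metric == "euclidean") sqrt(min(dr^2 + dc^2))
               else min(pmax(dr, dc))
  }
  d * cell_size
}

# independent straight-line re-implementation of the per-step behaviour
# heuristic: randomised neighbour list (fixed row-major offset order before
# the shuffle), no backtracking, barrier rejection, deterministic acceptance
# within the escape radius, one uniform draw per distant candidate
ref_run_agent <- function(land, seed, rules = land$rules) {
  cur <- as.integer(seed); prev <- NULL
  path <- list(cur); steps <- 0L
  repeat {
    if (steps >= rules$max_steps)
      return(list(path = do.call(rbind, path), reason = "max_steps"))
    nbrs <- list()
    for (dr in -1:1) for (dc in -1:1) if (dr != 0L || dc != 0L)
      nbrs[[length(nbrs) + 1L]] <- cur + c(dr, dc)
    if (!is.null(prev))
      nbrs <- Filter(function(p) !(p[1] == prev[1] && p[2] == prev[2]), nbrs)
    ord <- sample.int(length(nbrs))
    moved <- FALSE; reason <- NULL
    for (k in ord) {
      p <- nbrs[[k]]
      if (p[1] < 1 || p[1] > land$n_rows || p[2] < 1 || p[2] > land$n_cols) {
        reason <- "left_extent"; break
      }
      blocked <- land$nodata_mask[p[1], p[2]] ||
        (rules$roads_block && land$road_mask[p[1], p[2]]) ||
        (rules$water_blocks && land$water_mask[p[1], p[2]]) ||
        (rules$cover_rule_enabled &&
           land$cover$values[p[1], p[2]] > rules$cover_threshold_pct)
      if (blocked) next
      d <- land$escape_distance[p[1], p[2]]
      acc <- d <= rules$escape_accept_dist_m ||
        runif(1, 0, 100) < rules$prob_coef_a * exp(-rules$prob_rate_b * d)
      if (acc) {
        prev <- cur; cur <- p; steps <- steps + 1L
        path[[length(path) + 1L]] <- cur
        moved <- TRUE; break
      }
    }
    if (!is.null(reason))
      return(list(path = do.call(rbind, path), reason = reason))
    if (!moved) return(list(path = do.call(rbind, path), reason = "stuck"))
  }
}

# small fully passable landscape: escape terrain everywhere, no barriers
all_escape_landscape <- function(nr, nc, cell_size = 75, ...) {
  make_toy_landscape(slope = matrix(45, nr, nc), cell_size = cell_size, ...)
}

# passable pocket sealed in by water: the centre cell is the only dry land
sealed_landscape <- function() {
  w <- matrix(1, 3, 3); w[2, 2] <- 0
  make_toy_landscape(slope = matrix(45, 3, 3), water = w)
}

# 3 x n corridor: middle row passable for columns 2..(n-1), water elsewhere,
# so the single legal move at every step is one cell to the east
corridor_landscape <- function(n) {
  w <- matrix(1, 3, n)
  w[2, 2:(n - 1)] <- 0
  make_toy_landscape(slope = matrix(45, 3, n), water = w)
}

# synthetic landscape with a random mix of barriers for property tests
mixed_landscape <- function(seed = 1, nr = 30, nc = 30) {
  make_synthetic_landscape(synth_params(n_rows = nr, n_cols = nc,
                                        rng_seed = seed))
}
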