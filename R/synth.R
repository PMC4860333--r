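#' Parameters for the synthetic landscape generator
#'
#' Defaults describe a 7.5 km x 7.5 km (100 x 100 cells of 75 m) valley-like
#' landscape: a handful of elongated steep ridges providing escape terrain,
#' spatially clumped crown cover averaging ~35% (so contiguous dense patches
#' exceed the 40% movement threshold and act as barriers), one wandering
#' river and one road crossing the extent.
#'
#' @param n_rows,n_cols Grid dimensions (>= 10 each).
#' @param cell_size Cell edge length (m).
#' @param n_ridges Number of steep ridge features (0 allowed: a landscape
#'   with no escape terrain).
#' @param ridge_slope_deg Slope assigned to ridge cells; must exceed the
#'   40-degree escape threshold so ridges are escape terrain.
#' @param cover_mean Target mean percent crown cover.
#' @param cover_clump_scale Smoothing radius (cells) of the cover field;
#'   larger values give larger contiguous patches.
#' @param n_roads,n_rivers Number of linear road / river features.
#' @param rng_seed Seed making the landscape reproducible.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_rows = 100, n_cols = 100, cell_size = 75,
                         n_ridges = 4, ridge_slope_deg = 55,
                         cover_mean = 35, cover_clump_scale = 6,
                         n_roads = 1, n_rivers = 1, rng_seed = 1) {
  stopifnot(n_rows >= 10, n_cols >= 10, cell_size > 0,
            n_ridges >= 0, cover_mean >= 0, cover_mean <= 100,
            cover_clump_scale >= 1, n_roads >= 0, n_rivers >= 0)
  if (n_ridges > 0 && ridge_slope_deg <= 40)
    stop("ridge_slope_deg must exceed 40 degrees so ridges form escape ",
         "terrain", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, n_ridges = as.integer(n_ridges),
         ridge_slope_deg = ridge_slope_deg, cover_mean = cover_mean,
         cover_clump_scale = as.integer(cover_clump_scale),
         n_roads = as.integer(n_roads), n_rivers = as.integer(n_rivers),
         rng_seed = as.integer(rng_seed)),
    class = "synth_params"
  )
}

#' Build a landscape from literal layer values
#'
#' Deterministic constructor for small test landscapes: pass matrices (or
#' lists of row vectors) of slope, cover, water and roads. Scalars are
#' recycled to the slope layer's shape.
#'
#' @param slope Matrix or list of equal-length row vectors, degrees.
#' @param cover Matrix/rows/scalar, percent crown cover (default 0).
#' @param water,roads Matrix/rows/scalar, nonzero = feature present
#'   (default 0).
#' @param cell_size Cell edge length (m).
#' @param rules Movement rules attached to the landscape.
#' @return A `raster_landscape`.
#' @examples
#' m <- matrix(0, 3, 3); m[2, 2] <- 45
#' land <- make_toy_landscape(slope = m)
#' land$escape[2, 2]
#' @export
make_toy_landscape <- function(slope, cover = 0, water = 0, roads = 0,
                               cell_size = 75, rules = movement_rules()) {
  as_mat <- function(x, ref = NULL) {
    if (is.matrix(x)) return(x)
    if (is.list(x)) {
      lens <- lengths(x)
      if (length(unique(lens)) != 1L)
        stop("ragged rows: all rows must have the same length",
             call. = FALSE)
      return(do.call(rbind, lapply(x, as.numeric)))
    }
    if (length(x) == 1L && !is.null(ref))
      return(matrix(x, nrow(ref), ncol(ref)))
    stop("layer must be a matrix, a list of rows, or a scalar",
         call. = FALSE)
  }
  sm <- as_mat(slope)
  gl <- function(m) grid_layer(as_mat(m, sm), cell_size = cell_size)
  assemble_landscape(gl(sm), gl(cover), gl(water), gl(roads), rules = rules)
}

# separable box blur by matrix products; k = half-width in cells
smooth_field <- function(m, k) {
  band <- function(n) {
    b <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - k):min(n, i + k)
      b[i, j] <- 1 / length(j)
    }
    b
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# supercover rasterisation of a polyline: every cell the line passes
# through, stepping both orthogonal cells at (near-)corner crossings so
# barriers have no diagonal leaks. Coordinates in cell units (col, row).
supercover_cells <- function(xs, ys, nr, nc) {
  cells <- list()
  for (s in seq_len(length(xs) - 1L)) {
    x0 <- xs[s]; y0 <- ys[s]; x1 <- xs[s + 1L]; y1 <- ys[s + 1L]
    dx <- x1 - x0; dy <- y1 - y0
    cx <- floor(x0); cy <- floor(y0)
    ex <- floor(x1); ey <- floor(y1)
    sx <- sign(dx); sy <- sign(dy)
    tmx <- if (dx != 0) ((cx + (sx > 0)) - x0) / dx else Inf
    tmy <- if (dy != 0) ((cy + (sy > 0)) - y0) / dy else Inf
    tdx <- if (dx != 0) abs(1 / dx) else Inf
    tdy <- if (dy != 0) abs(1 / dy) else Inf
    cells[[length(cells) + 1L]] <- c(cx, cy)
    guard <- 0L
    while ((cx != ex || cy != ey) && guard < 4L * (nr + nc)) {
      guard <- guard + 1L
      if (abs(tmx - tmy) < 1e-12) {
        # corner crossing: add both orthogonal neighbours, step diagonally
        cells[[length(cells) + 1L]] <- c(cx + sx, cy)
        cells[[length(cells) + 1L]] <- c(cx, cy + sy)
        cx <- cx + sx; cy <- cy + sy
        tmx <- tmx + tdx; tmy <- tmy + tdy
      } else if (tmx < tmy) {
        cx <- cx + sx; tmx <- tmx + tdx
      } else {
        cy <- cy + sy; tmy <- tmy + tdy
      }
      cells[[length(cells) + 1L]] <- c(cx, cy)
    }
  }
  m <- unique(do.call(rbind, cells))
  # cell units are 0-based (col, row); convert to 1-based matrix indices
  col <- m[, 1] + 1L; row <- m[, 2] + 1L
  keep <- row >= 1 & row <= nr & col >= 1 & col <= nc
  cbind(row = row[keep], col = col[keep])
}

# wandering polyline across the grid; axis = "ns" (top to bottom) or "ew"
wander_polyline <- function(nr, nc, axis = c("ns", "ew")) {
  axis <- match.arg(axis)
  n_pts <- 12L
  if (axis == "ns") {
    ys <- seq(0, nr, length.out = n_pts)
    xs <- nc * 0.2 + nc * 0.6 * stats::runif(1) +
      cumsum(c(0, stats::rnorm(n_pts - 1L, 0, nc / 25)))
    xs <- pmin(pmax(xs, 0.5), nc - 0.5)
  } else {
    xs <- seq(0, nc, length.out = n_pts)
    ys <- nr * 0.2 + nr * 0.6 * stats::runif(1) +
      cumsum(c(0, stats::rnorm(n_pts - 1L, 0, nr / 25)))
    ys <- pmin(pmax(ys, 0.5), nr - 0.5)
  }
  list(xs = xs, ys = ys)
}

#' Generate a stochastic synthetic landscape
#'
#' Emulates the structure of the model's real inputs without any download:
#' ridge-like patches of steep slope (escape terrain), spatially clumped
#' crown cover in \[0, 100\] whose dense patches block movement, and
#' rasterised river and road polylines. Deterministic given
#' `params$rng_seed`.
#'
#' @param params A [synth_params()] object.
#' @param rules Movement rules attached to the landscape.
#' @return A `raster_landscape`. Errors if the parameters admit no suitable
#'   cell (passable and within the acceptance distance of escape terrain).
#' @examples
#' land <- make_synthetic_landscape(synth_params(n_rows = 40, n_cols = 40))
#' land
#' @export
make_synthetic_landscape <- function(params = synth_params(),
                                     rules = movement_rules()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$rng_seed)
  nr <- params$n_rows; nc <- params$n_cols

  # gentle base terrain, then steep ridge segments
  slope <- smooth_field(matrix(stats::runif(nr * nc, 0, 30), nr, nc), 3L)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(params$n_ridges)) {
    r0 <- stats::runif(1, 0.15 * nr, 0.85 * nr)
    c0 <- stats::runif(1, 0.15 * nc, 0.85 * nc)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.15, 0.3) * min(nr, nc)
    wid <- stats::runif(1, 1.2, 2.5)
    ux <- cos(ang); uy <- sin(ang)
    dr <- rows - r0; dc <- cols - c0
    along <- dr * uy + dc * ux
    across <- abs(dr * ux - dc * uy)
    core <- abs(along) <= len / 2 & across <= wid
    shoulder <- abs(along) <= len / 2 + 2 & across <= wid + 2 & !core
    slope[core] <- params$ridge_slope_deg
    slope[shoulder] <- pmax(slope[shoulder], 32)
  }
  slope <- pmin(pmax(slope, 0), 90)

  # clumped crown cover: smoothed noise rescaled around the target mean
  z <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                    params$cover_clump_scale)
  z <- (z - mean(z)) / stats::sd(z)
  cover <- pmin(pmax(params$cover_mean + 22 * z, 0), 100)

  water <- matrix(0, nr, nc)
  for (i in seq_len(params$n_rivers)) {
    pl <- wander_polyline(nr, nc, "ns")
    water[supercover_cells(pl$xs, pl$ys, nr, nc)] <- 1
  }
  roads <- matrix(0, nr, nc)
  for (i in seq_len(params$n_roads)) {
    pl <- wander_polyline(nr, nc, "ew")
    roads[supercover_cells(pl$xs, pl$ys, nr, nc)] <- 1
  }

  land <- assemble_landscape(
    grid_layer(slope, cell_size = params$cell_size),
    grid_layer(cover, cell_size = params$cell_size),
    grid_layer(water, cell_size = params$cell_size),
    grid_layer(roads, cell_size = params$cell_size),
    rules = rules
  )
  if (params$n_ridges > 0 && length(suitable_indices(land, rules)) == 0L)
    stop("generated landscape has no suitable cell (passable and within ",
         rules$escape_accept_dist_m, " m of escape terrain); ",
         "increase n_ridges or reduce cover_mean", call. = FALSE)
  land
}

#' Generate synthetic occurrence points
#'
#' Places `n` points in suitable habitat (passable cells within the
#' acceptance distance of escape terrain), uniformly over the suitable set
#' with replacement and jittered uniformly inside each chosen cell —
#' emulating observed occurrence records, which concentrate in good habitat
#' near escape terrain.
#'
#' @param landscape A `raster_landscape`.
#' @param n Number of points (>= 1).
#' @param rules Movement rules defining suitability.
#' @param rng_seed Seed for reproducibility.
#' @return A tibble with columns `x`, `y`.
#' @export
make_synthetic_occurrences <- function(landscape, n,
                                       rules = landscape$rules,
                                       rng_seed = 1) {
  if (n < 1) stop("no occurrences requested: n must be >= 1", call. = FALSE)
  idx <- suitable_indices(landscape, rules)
  if (length(idx) == 0L)
    stop("landscape has no suitable cell to place occurrences in",
         call. = FALSE)
  set.seed(rng_seed)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  nr <- landscape$n_rows
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  cs <- landscape$cell_size
  tibble::tibble(
    x = landscape$origin_x + (col - 1L) * cs + stats::runif(n) * cs,
    y = landscape$origin_y - (row - 1L) * cs - stats::runif(n) * cs
  )
}
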