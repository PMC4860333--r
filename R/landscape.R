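#' Classify escape terrain
#'
#' Escape terrain is steep ground that predators cannot easily traverse; in
#' the model it is any cell whose slope is *strictly* greater than the
#' threshold. A 40.0-degree cell at the default threshold is not escape
#' terrain. `NA` (nodata) slope is never escape terrain.
#'
#' @param slope A [grid_layer()] of slope in degrees, or a numeric matrix.
#' @param threshold_deg Slope threshold in degrees (default 40).
#' @return A logical matrix.
#' @export
escape_mask <- function(slope, threshold_deg = 40) {
  if (threshold_deg < 0) stop("threshold must be >= 0", call. = FALSE)
  v <- if (inherits(slope, "grid_layer")) slope$values else slope
  m <- !is.na(v) & v > threshold_deg
  m
}

# exact chessboard (Chebyshev) distance transform in ring counts,
# two-pass (1,1)-chamfer with vectorised row scans
chebyshev_rings <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- nr + nc + 1
  d <- matrix(big, nr, nc)
  d[mask] <- 0
  j <- seq_len(nc)
  scan_row <- function(row) {
    row <- pmin(row, j + cummin(row - j))              # from the west
    pmin(row, -j + rev(cummin(rev(row + j))))          # from the east
  }
  for (i in seq_len(nr)) {
    if (i > 1L) {
      up <- d[i - 1L, ]
      d[i, ] <- pmin(d[i, ], up + 1, c(big, up[-nc]) + 1, c(up[-1L], big) + 1)
    }
    d[i, ] <- scan_row(d[i, ])
  }
  for (i in rev(seq_len(nr))) {
    if (i < nr) {
      dn <- d[i + 1L, ]
      d[i, ] <- pmin(d[i, ], dn + 1, c(big, dn[-nc]) + 1, c(dn[-1L], big) + 1)
    }
    d[i, ] <- scan_row(d[i, ])
  }
  d
}

#' Distance to the nearest escape-terrain cell
#'
#' Computes, for every cell, the distance to the nearest `TRUE` cell of the
#' escape mask. Two metrics are offered: `"euclidean"` is the exact
#' centre-to-centre Euclidean distance transform; `"grid_ring"` counts
#' Chebyshev rings (a diagonal neighbour is one ring) and multiplies by the
#' cell size, so distances are multiples of the cell size. Escape cells have
#' distance 0. If the mask has no `TRUE` cell, every distance is `Inf`.
#'
#' @param mask Logical matrix of escape terrain (see [escape_mask()]).
#' @param cell_size Cell edge length in metres.
#' @param metric `"euclidean"` or `"grid_ring"`.
#' @return Numeric matrix of distances in metres.
#' @export
escape_distance <- function(mask, cell_size,
                            metric = c("euclidean", "grid_ring")) {
  metric <- match.arg(metric)
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  if (metric == "euclidean") {
    # distmap: distance of foreground (non-escape) pixels to the background
    px <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)),
                           metric = "euclidean")
    as.matrix(px) * cell_size
  } else {
    chebyshev_rings(mask) * cell_size
  }
}

#' Assemble aligned raster layers into a simulation landscape
#'
#' Validates that the four layers share one lattice, range-checks slope
#' (0-90 degrees) and crown cover (0-100%), derives the escape-terrain mask
#' and the distance-to-escape grid, and caches everything the movement
#' kernel consults. The landscape is treated as static: derived grids are
#' computed once here.
#'
#' Nodata cells (in any of the four layers) are impassable and never escape
#' terrain — agents cannot walk through unmapped ground.
#'
#' @param slope [grid_layer()], slope in degrees.
#' @param cover [grid_layer()], percent crown cover.
#' @param water [grid_layer()], nonzero where a lake or river is present.
#' @param roads [grid_layer()], nonzero where a road is present.
#' @param rules A [movement_rules()] object; its slope threshold and
#'   distance metric drive the derived grids.
#' @return An object of class `raster_landscape`.
#' @export
assemble_landscape <- function(slope, cover, water, roads,
                               rules = movement_rules()) {
  layers <- list(slope = slope, cover = cover, water = water, roads = roads)
  for (nm in names(layers))
    if (!inherits(layers[[nm]], "grid_layer"))
      stop(nm, " must be a grid_layer", call. = FALSE)
  for (nm in c("cover", "water", "roads"))
    if (!grids_aligned(slope, layers[[nm]]))
      stop("layer '", nm, "' is not aligned with the slope layer",
           call. = FALSE)
  sv <- slope$values
  if (any(sv < 0 | sv > 90, na.rm = TRUE))
    stop("slope values outside [0, 90] degrees", call. = FALSE)
  cv <- cover$values
  if (any(cv < 0 | cv > 100, na.rm = TRUE))
    stop("crown cover values outside [0, 100] percent", call. = FALSE)
  land <- structure(
    list(slope = slope, cover = cover, water = water, roads = roads,
         rules = rules),
    class = "raster_landscape"
  )
  refresh_derived(land)
}

# (re)compute cached grids for the rules attached to the landscape
refresh_derived <- function(land) {
  rules <- land$rules
  sv <- land$slope$values
  land$escape <- escape_mask(sv, rules$slope_threshold_deg)
  land$escape_distance <- escape_distance(land$escape, land$slope$cell_size,
                                          rules$distance_metric)
  land$water_mask <- !is.na(land$water$values) & land$water$values != 0
  land$road_mask <- !is.na(land$roads$values) & land$roads$values != 0
  land$nodata_mask <- is.na(sv) | is.na(land$cover$values) |
    is.na(land$water$values) | is.na(land$roads$values)
  land$n_rows <- land$slope$n_rows
  land$n_cols <- land$slope$n_cols
  land$cell_size <- land$slope$cell_size
  land$origin_x <- land$slope$origin_x
  land$origin_y <- land$slope$origin_y
  land
}

# landscape with different rules; re-derives escape grids only when needed
with_rules <- function(land, rules) {
  redo <- rules$slope_threshold_deg != land$rules$slope_threshold_deg ||
    rules$distance_metric != land$rules$distance_metric
  land$rules <- rules
  if (redo) refresh_derived(land) else land
}

#' @export
print.raster_landscape <- function(x, ...) {
  cat(sprintf("<raster_landscape> %d x %d cells of %g m (%.1f x %.1f km)\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$n_cols * x$cell_size / 1000, x$n_rows * x$cell_size / 1000))
  cat(sprintf("  escape terrain: %d cells (slope > %g deg); water: %d; roads: %d; nodata: %d\n",
              sum(x$escape), x$rules$slope_threshold_deg,
              sum(x$water_mask), sum(x$road_mask), sum(x$nodata_mask)))
  if (!any(x$escape)) cat("  NOTE: no escape terrain anywhere\n")
  invisible(x)
}

# logical matrix of cells an agent may occupy under `rules`
passability_matrix <- function(land, rules = land$rules) {
  blocked <- land$nodata_mask
  if (rules$roads_block) blocked <- blocked | land$road_mask
  if (rules$water_blocks) blocked <- blocked | land$water_mask
  if (rules$cover_rule_enabled)
    blocked <- blocked |
      (!is.na(land$cover$values) & land$cover$values > rules$cover_threshold_pct)
  !blocked
}

#' Can a sheep occupy this cell?
#'
#' A cell is impassable if it carries a road (when roads block), a lake or
#' river (when water blocks), strictly more than the cover threshold of
#' crown cover (when the cover rule is enabled), or nodata in any layer.
#' Thresholds are strict: exactly 40% cover is passable.
#'
#' @param landscape A [assemble_landscape()] result.
#' @param row,col Integer vectors of 1-based cell indices (vectorised).
#' @param rules Movement rules; defaults to the landscape's rules.
#' @return Logical vector.
#' @export
is_passable <- function(landscape, row, col, rules = landscape$rules) {
  if (any(row < 1 | row > landscape$n_rows | col < 1 | col > landscape$n_cols))
    stop("cell out of extent", call. = FALSE)
  pm <- passability_matrix(landscape, rules)
  pm[cbind(row, col)]
}

#' Build a landscape from a YAML configuration file
#'
#' The file names the four raster files (relative paths resolve against the
#' config file's directory) and may override movement rules:
#'
#' ```yaml
#' layers:
#'   slope: slope.asc
#'   cover: cover.asc
#'   water: water.asc
#'   roads: roads.asc
#' rules:
#'   escape_accept_dist_m: 400
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `raster_landscape`.
#' @export
landscape_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("layers", "rules"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  need <- c("slope", "cover", "water", "roads")
  if (!all(need %in% names(cfg$layers)))
    stop("config must name all four layers: ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  rd <- function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    read_grid(p)
  }
  rules <- apply_rule_overrides(movement_rules(), cfg$rules)
  assemble_landscape(rd(cfg$layers$slope), rd(cfg$layers$cover),
                     rd(cfg$layers$water), rd(cfg$layers$roads),
                     rules = rules)
}
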