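#' Create an empty per-pixel usage map
#'
#' A usage map counts how many times sheep agents occupied each pixel,
#' aggregated over all trajectories of a run. Revisits count again and the
#' seed cell counts as an occupancy.
#'
#' @param landscape A `raster_landscape` the map is aligned to.
#' @param counts Optional initial integer matrix (defaults to all zero).
#' @param n_trajectories Number of trajectories already accumulated.
#' @param scenario,rng_seed Metadata recorded on the map.
#' @return An object of class `usage_map`.
#' @export
new_usage_map <- function(landscape, counts = NULL, n_trajectories = 0L,
                          scenario = NA_character_, rng_seed = NA_integer_) {
  if (is.null(counts))
    counts <- matrix(0L, landscape$n_rows, landscape$n_cols)
  stopifnot(nrow(counts) == landscape$n_rows,
            ncol(counts) == landscape$n_cols)
  structure(
    list(counts = counts, n_trajectories = as.integer(n_trajectories),
         n_rows = landscape$n_rows, n_cols = landscape$n_cols,
         origin_x = landscape$origin_x, origin_y = landscape$origin_y,
         cell_size = landscape$cell_size,
         scenario = scenario, rng_seed = rng_seed),
    class = "usage_map"
  )
}

#' @export
print.usage_map <- function(x, ...) {
  used <- sum(x$counts > 0)
  cat(sprintf("<usage_map> %d x %d, %d trajectories, %.0f visits over %d used cells (max %d)\n",
              x$n_rows, x$n_cols, x$n_trajectories, sum(x$counts), used,
              max(x$counts)))
  invisible(x)
}

#' Add one trajectory to a usage map
#'
#' Every occupied cell (seed included) increments its pixel count by one
#' per visit.
#'
#' @param usage A [new_usage_map()] object.
#' @param trajectory A trajectory from [run_agent()], or any data frame
#'   with `row`/`col` columns.
#' @return The updated `usage_map`.
#' @export
accumulate_trajectory <- function(usage, trajectory) {
  if (any(trajectory$row < 1 | trajectory$row > usage$n_rows |
          trajectory$col < 1 | trajectory$col > usage$n_cols))
    stop("trajectory is not aligned with the usage map", call. = FALSE)
  idx <- trajectory$row + (trajectory$col - 1L) * usage$n_rows
  rl <- rle(sort.int(idx, method = "radix"))
  usage$counts[rl$values] <- usage$counts[rl$values] + rl$lengths
  usage$n_trajectories <- usage$n_trajectories + 1L
  usage
}

#' Relative frequency of use
#'
#' Divides each pixel's visit count by the count of the most used pixel,
#' giving values in (0, 1]. Pixels never used by any agent are flagged as
#' nodata (`NA`) rather than zero — on the maps these are the white areas.
#'
#' @param usage A `usage_map` with at least one positive count.
#' @return A [grid_layer()] of relative frequencies with `NA` where a pixel
#'   was never used.
#' @export
relative_frequency <- function(usage) {
  mx <- max(usage$counts)
  if (mx == 0) stop("usage map is empty: no pixel was ever used",
                    call. = FALSE)
  rel <- usage$counts / mx
  rel[usage$counts == 0L] <- NA_real_
  grid_layer(rel, cell_size = usage$cell_size, origin_x = usage$origin_x,
             origin_y = usage$origin_y, nodata = -9999)
}

#' Rank road pixels by simulated crossing use
#'
#' Intended for usage maps from the road-permeable scenario: road pixels
#' that agents actually used are ranked by visit count and the top fraction
#' (nearest-rank ceiling, default 10%) is highlighted as priority
#' crossing-site candidates. Ties at the cutoff count are all included, so
#' the highlighted set can exceed `ceiling(fraction * N)`.
#'
#' @param usage A `usage_map`.
#' @param roads Road [grid_layer()] (nonzero = road) or logical matrix,
#'   aligned with the usage map.
#' @param fraction Fraction of used road pixels to highlight.
#' @return A tibble of class `crossing_report` with columns `row`, `col`,
#'   `x`, `y`, `count`, `rank`, `highlighted`, sorted by count descending
#'   (ties broken by row then column for determinism). Zero used road
#'   pixels yield an empty report.
#' @export
road_crossing_sites <- function(usage, roads, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  rm_ <- if (inherits(roads, "grid_layer")) {
    !is.na(roads$values) & roads$values != 0
  } else roads
  if (nrow(rm_) != usage$n_rows || ncol(rm_) != usage$n_cols)
    stop("road layer is not aligned with the usage map", call. = FALSE)
  cand <- which(rm_ & usage$counts > 0L, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    out <- tibble::tibble(row = integer(), col = integer(),
                          x = double(), y = double(), count = integer(),
                          rank = integer(), highlighted = logical())
  } else {
    cnt <- usage$counts[cand]
    ord <- order(-cnt, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    cnt <- cnt[ord]
    n_top <- ceiling(fraction * length(cnt))
    cutoff <- cnt[n_top]
    xy <- tibble::tibble(
      x = usage$origin_x + (cand[, 2] - 0.5) * usage$cell_size,
      y = usage$origin_y - (cand[, 1] - 0.5) * usage$cell_size
    )
    out <- tibble::tibble(row = as.integer(cand[, 1]),
                          col = as.integer(cand[, 2]),
                          x = xy$x, y = xy$y, count = as.integer(cnt),
                          rank = seq_along(cnt),
                          highlighted = cnt >= cutoff)
  }
  attr(out, "fraction") <- fraction
  class(out) <- c("crossing_report", class(out))
  out
}

#' Occurrence-point coverage of a usage map
#'
#' The model's validation metric: the fraction of occurrence points whose
#' pixel was used at least once by a simulated sheep. A calibrated model is
#' expected to cover more than 80% of occurrence points.
#'
#' @param usage A `usage_map`.
#' @param occurrences Tibble with `x`, `y` columns.
#' @param landscape The `raster_landscape` the usage map came from.
#' @return Fraction in \[0, 1\].
#' @export
occurrence_coverage <- function(usage, occurrences, landscape) {
  if (is.null(occurrences) || nrow(occurrences) == 0L)
    stop("empty occurrence set", call. = FALSE)
  cl <- occurrence_to_cell(landscape, occurrences)
  mean(usage$counts[cbind(cl$row, cl$col)] > 0L)
}

#' Write a usage map (or any aligned grid) as a raster
#'
#' Usage maps are written as integer count bands; relative-frequency grids
#' as float bands with nodata marking never-used pixels.
#'
#' @param x A `usage_map` or [grid_layer()].
#' @param path Output path (ESRI ASCII grid).
#' @return `path`, invisibly.
#' @export
write_usage_raster <- function(x, path) {
  g <- if (inherits(x, "usage_map")) {
    grid_layer(x$counts, cell_size = x$cell_size, origin_x = x$origin_x,
               origin_y = x$origin_y, nodata = -9999)
  } else if (inherits(x, "grid_layer")) x
  else stop("x must be a usage_map or grid_layer", call. = FALSE)
  write_grid(g, path)
}
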