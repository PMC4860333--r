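#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario result into a removal-reason table
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble with columns `reason`, `count`, `fraction`.
#' @export
tidy.scenario_result <- function(x, ...) {
  tibble::tibble(
    reason = names(x$removal_counts),
    count = as.integer(x$removal_counts),
    fraction = as.integer(x$removal_counts) / x$n_trajectories
  )
}

#' One-row summary of a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble with one row: scenario, trajectory count, total cell
#'   visits, number and fraction of used cells, peak pixel count.
#' @export
glance.scenario_result <- function(x, ...) {
  g <- glance(x$usage)
  g$scenario <- x$config$scenario
  g$rng_seed <- x$config$rng_seed
  dplyr::relocate(g, "scenario")
}

#' Tidy a usage map into a long table of used pixels
#'
#' @param x A `usage_map`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `count`, `rel_freq` for
#'   every pixel with a positive count.
#' @export
tidy.usage_map <- function(x, ...) {
  used <- which(x$counts > 0L, arr.ind = TRUE)
  cnt <- x$counts[used]
  xc <- x$origin_x + (used[, 2] - 0.5) * x$cell_size
  yc <- x$origin_y - (used[, 1] - 0.5) * x$cell_size
  tibble::tibble(
    row = as.integer(used[, 1]), col = as.integer(used[, 2]),
    x = xc, y = yc,
    count = as.integer(cnt),
    rel_freq = cnt / max(cnt)
  )
}

#' One-row summary of a usage map
#'
#' @param x A `usage_map`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.usage_map <- function(x, ...) {
  tibble::tibble(
    n_trajectories = x$n_trajectories,
    total_visits = sum(x$counts),
    n_used_cells = sum(x$counts > 0L),
    frac_used = mean(x$counts > 0L),
    max_count = max(x$counts)
  )
}
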