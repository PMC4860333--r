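.scenario_names <- c("occurrence_dispersal", "potential_connectivity",
                     "fire_restored", "road_permeable")

#' Scenario configuration
#'
#' Describes one of the four management-scenario protocols:
#'
#' * `occurrence_dispersal` — dispersal from known locations: 100 agents per
#'   occurrence pixel, iterated over every occurrence location.
#' * `potential_connectivity` — broad landscape use: single agents seeded at
#'   random suitable pixels, re-initiated for 20,000 iterations.
#' * `fire_restored` — as `potential_connectivity`, but crown cover no
#'   longer restricts movement (prescribed burns / natural fire regime).
#' * `road_permeable` — as `potential_connectivity`, but roads no longer
#'   block movement, so road-crossing sites can be ranked; intended for
#'   finer-grained (25 m) layers.
#'
#' @param scenario One of the four scenario names.
#' @param n_agents_per_seed Agents per occurrence pixel (scenario 1 only).
#' @param n_iterations Single-agent re-initiations (scenarios 2-4).
#' @param max_steps Step cap per agent.
#' @param rng_seed Master seed; per-trajectory child seeds are derived from
#'   it by counter, so any trajectory is reproducible in isolation.
#' @param cell_size_m If given, the landscape's resolution must match
#'   (e.g. 25 for the road scenario); `NULL` accepts any resolution.
#' @param rule_overrides Named list of [movement_rules()] fields to override
#'   before the scenario's own rule modification is applied.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = .scenario_names,
                            n_agents_per_seed = 100,
                            n_iterations = 20000,
                            max_steps = 2000,
                            rng_seed = 1,
                            cell_size_m = NULL,
                            rule_overrides = list()) {
  scenario <- match.arg(scenario)
  stopifnot(n_agents_per_seed >= 1, n_iterations >= 1, max_steps >= 1)
  structure(
    list(scenario = scenario,
         n_agents_per_seed = as.integer(n_agents_per_seed),
         n_iterations = as.integer(n_iterations),
         max_steps = as.integer(max_steps),
         rng_seed = as.integer(rng_seed),
         cell_size_m = cell_size_m,
         rule_overrides = rule_overrides),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' Keys mirror the arguments of [scenario_config()]; unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return A `scenario_config`.
#' @export
scenario_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown scenario config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, cfg)
}

# deterministic per-trajectory child seed, kept inside [1, 2^31 - 2]
child_seed <- function(master, k) {
  x <- as.double(master) %% 2147483647
  x <- (x * 48271) %% 2147483647
  x <- (x + as.double(k) * 69621 + 12345) %% 2147483647
  as.integer(x)
}

#' Load occurrence points from CSV
#'
#' The file must have `x` and `y` columns in the landscape's map units.
#' Points outside the landscape extent are dropped with a warning.
#'
#' @param path CSV path.
#' @param landscape Optional `raster_landscape` used for the extent check.
#' @return A tibble with at least columns `x` and `y`.
#' @export
load_occurrences <- function(path, landscape = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("occurrence CSV must have x and y columns", call. = FALSE)
  if (nrow(df) == 0L) stop("no occurrences in ", path, call. = FALSE)
  df <- tibble::as_tibble(df)
  if (!is.null(landscape)) {
    cl <- xy_to_cell(landscape, df$x, df$y)
    n_out <- sum(!cl$in_extent)
    if (n_out > 0L) {
      warning(n_out, " occurrence point(s) outside the landscape extent ",
              "were dropped", call. = FALSE)
      df <- df[cl$in_extent, , drop = FALSE]
    }
    if (nrow(df) == 0L)
      stop("no occurrences inside the landscape extent", call. = FALSE)
  }
  df
}

#' Map occurrence points to grid cells
#'
#' Applies the landscape's floor convention (a point on a shared edge
#' belongs to the larger-index cell). Out-of-extent points are an error;
#' filter them first with [load_occurrences()].
#'
#' @param landscape A `raster_landscape`.
#' @param occurrences Tibble/data frame with `x`, `y` columns.
#' @return A tibble with integer columns `row`, `col`, one row per point.
#' @export
occurrence_to_cell <- function(landscape, occurrences) {
  cl <- xy_to_cell(landscape, occurrences$x, occurrences$y)
  if (any(!cl$in_extent))
    stop("occurrence point outside landscape extent", call. = FALSE)
  cl[c("row", "col")]
}

# linear indices (column-major) of cells satisfying the movement
# requirements: passable under `rules` and within the deterministic
# acceptance distance of escape terrain
suitable_indices <- function(landscape, rules = landscape$rules) {
  landscape <- with_rules(landscape, rules)
  ok <- passability_matrix(landscape, rules) &
    landscape$escape_distance <= rules$escape_accept_dist_m
  which(ok)
}

#' Sample a random suitable seed pixel
#'
#' Draws uniformly over the cells that satisfy the movement requirements:
#' passable under the rules and within the deterministic acceptance
#' distance of escape terrain. Under fire-restored rules the cover clause
#' is dropped from suitability too (it is dropped from passability).
#'
#' @param landscape A `raster_landscape`.
#' @param rules Movement rules.
#' @return Integer `c(row, col)`.
#' @export
sample_suitable_seed <- function(landscape, rules = landscape$rules) {
  idx <- suitable_indices(landscape, rules)
  if (length(idx) == 0L)
    stop("no cell satisfies the movement requirements", call. = FALSE)
  i <- idx[sample.int(length(idx), 1L)]
  nr <- landscape$n_rows
  c(((i - 1L) %% nr) + 1L, ((i - 1L) %/% nr) + 1L)
}

#' Derive scenario-specific movement rules
#'
#' The fire scenario drops the crown-cover rule (canopy no longer restricts
#' movement); the road scenario makes roads permeable. Water always blocks.
#' The two seeded scenarios leave the rules unchanged.
#'
#' @param base A [movement_rules()] object.
#' @param scenario Scenario name.
#' @return A `movement_rules` object.
#' @export
scenario_rules <- function(base, scenario) {
  scenario <- match.arg(scenario, .scenario_names)
  switch(scenario,
    fire_restored = apply_rule_overrides(base,
                                         list(cover_rule_enabled = FALSE)),
    road_permeable = apply_rule_overrides(base, list(roads_block = FALSE)),
    base)
}

#' Run a management scenario
#'
#' Orchestrates one full simulation protocol and accumulates every
#' trajectory into a shared per-pixel usage map. For `occurrence_dispersal`
#' the seed set is the deduplicated set of occurrence cells and
#' `n_agents_per_seed` independent agents are run from each; for the other
#' scenarios `n_iterations` single agents start from random suitable
#' pixels. Each trajectory k runs under the child seed derived from
#' `config$rng_seed` and k, so the whole result is reproducible and any
#' single trajectory can be replayed.
#'
#' @param landscape A `raster_landscape`.
#' @param occurrences Tibble with `x`, `y` columns; required for
#'   `occurrence_dispersal`, ignored otherwise.
#' @param config A [scenario_config()].
#' @return An object of class `scenario_result`: list with `usage` (a
#'   `usage_map`), `removal_counts` (named integer vector over
#'   stuck/left_extent/max_steps), `n_trajectories`, `config`, `rules`.
#' @export
run_scenario <- function(landscape, occurrences = NULL, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$cell_size_m) &&
      abs(config$cell_size_m - landscape$cell_size) > 1e-9)
    stop("config expects ", config$cell_size_m, " m cells but the landscape ",
         "has ", landscape$cell_size, " m cells", call. = FALSE)
  rules <- apply_rule_overrides(landscape$rules, config$rule_overrides)
  rules <- scenario_rules(rules, config$scenario)
  rules <- apply_rule_overrides(rules, list(max_steps = config$max_steps))
  ctx <- walk_context(landscape, rules)
  land <- ctx$landscape

  from_occurrences <- config$scenario == "occurrence_dispersal"
  if (from_occurrences) {
    if (is.null(occurrences))
      stop("occurrence_dispersal requires an occurrence set", call. = FALSE)
    cells <- unique(occurrence_to_cell(land, occurrences))
    ok <- ctx$pass[cbind(cells$row, cells$col)]
    if (any(!ok)) {
      warning(sum(!ok), " occurrence cell(s) are impassable under the ",
              "scenario rules and were not seeded", call. = FALSE)
      cells <- cells[ok, , drop = FALSE]
    }
    if (nrow(cells) == 0L) stop("no seedable occurrence cells", call. = FALSE)
    seed_rows <- rep(cells$row, each = config$n_agents_per_seed)
    seed_cols <- rep(cells$col, each = config$n_agents_per_seed)
    n_traj <- length(seed_rows)
  } else {
    suitable <- suitable_indices(land, rules)
    if (length(suitable) == 0L)
      stop("no cell satisfies the movement requirements", call. = FALSE)
    n_traj <- config$n_iterations
  }

  counts <- matrix(0L, land$n_rows, land$n_cols)
  reasons <- c(stuck = 0L, left_extent = 0L, max_steps = 0L)
  nr <- land$n_rows
  for (k in seq_len(n_traj)) {
    set.seed(child_seed(config$rng_seed, k))
    if (from_occurrences) {
      r0 <- seed_rows[k]; c0 <- seed_cols[k]
    } else {
      i <- suitable[sample.int(length(suitable), 1L)]
      r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
    }
    res <- walk_one(ctx, r0, c0)
    idx <- res$cells[, 1L] + (res$cells[, 2L] - 1L) * nr
    rl <- rle(sort.int(idx, method = "radix"))
    counts[rl$values] <- counts[rl$values] + rl$lengths
    reasons[res$reason] <- reasons[res$reason] + 1L
  }

  usage <- new_usage_map(land, counts, n_trajectories = n_traj,
                         scenario = config$scenario,
                         rng_seed = config$rng_seed)
  structure(
    list(usage = usage, removal_counts = reasons, n_trajectories = n_traj,
         config = config, rules = rules),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %d trajectories, %.0f cell visits\n",
              x$config$scenario, x$n_trajectories, sum(x$usage$counts)))
  cat(sprintf("  removed: %d stuck, %d left extent, %d hit step cap\n",
              x$removal_counts[["stuck"]], x$removal_counts[["left_extent"]],
              x$removal_counts[["max_steps"]]))
  invisible(x)
}

#' Sweep movement-rule parameters against occurrence coverage
#'
#' Runs the potential-connectivity protocol once per combination of the
#' supplied candidate values and scores each run by the fraction of
#' occurrence points falling on used pixels — the model's calibration
#' metric. All combinations run under the same master seed, so rows are
#' paired comparisons.
#'
#' @param landscape A `raster_landscape`.
#' @param occurrences Tibble with `x`, `y` columns (the validation points).
#' @param grid Named list of candidate value vectors; allowed names:
#'   `slope_threshold_deg`, `cover_threshold_pct`, `escape_accept_dist_m`,
#'   `prob_rate_b`.
#' @param config A [scenario_config()]; its scenario field is ignored
#'   (always `potential_connectivity`).
#' @return A tibble with one row per combination: the four parameters,
#'   `coverage` (fraction in \[0, 1\]) and `n_trajectories`, sorted by
#'   coverage, descending.
#' @export
parameter_sweep <- function(landscape, occurrences, grid, config) {
  allowed <- c("slope_threshold_deg", "cover_threshold_pct",
               "escape_accept_dist_m", "prob_rate_b")
  if (length(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  unknown <- setdiff(names(grid), allowed)
  if (length(unknown))
    stop("unknown sweep parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    overrides <- as.list(combos[i, , drop = FALSE])
    cfg <- config
    cfg$scenario <- "potential_connectivity"
    cfg$rule_overrides <- utils::modifyList(config$rule_overrides, overrides)
    res <- run_scenario(landscape, occurrences = NULL, config = cfg)
    base <- apply_rule_overrides(landscape$rules, cfg$rule_overrides)
    out <- tibble::as_tibble(overrides)
    out$coverage <- occurrence_coverage(res$usage, occurrences, landscape)
    out$n_trajectories <- res$n_trajectories
    out
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$coverage))
}
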