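# Moore-neighbourhood offsets, fixed pre-shuffle order (row-major)
.moore_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
.moore_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

#' Randomised neighbour candidate list for one step
#'
#' Returns the 8 Moore neighbours of the agent's current cell, minus the
#' previously occupied cell (agents cannot move backwards), in a uniformly
#' random order drawn from the current RNG stream. Neighbours outside the
#' landscape extent are kept in the list as exit markers (`in_extent =
#' FALSE`): if the step iteration reaches one, the agent leaves the
#' landscape.
#'
#' Exactly one `sample.int()` permutation is consumed per call, so the RNG
#' stream of a full simulation is reproducible.
#'
#' @param landscape A `raster_landscape`.
#' @param current Integer vector `c(row, col)` of the agent's cell.
#' @param previous `c(row, col)` of the previous cell, or `NULL` at the
#'   first step.
#' @return A tibble with columns `row`, `col`, `in_extent`, in evaluation
#'   order.
#' @export
neighbor_candidates <- function(landscape, current, previous = NULL) {
  r <- current[1] + .moore_dr
  c <- current[2] + .moore_dc
  if (!is.null(previous)) {
    keep <- !(r == previous[1] & c == previous[2])
    r <- r[keep]; c <- c[keep]
  }
  ord <- sample.int(length(r))
  r <- r[ord]; c <- c[ord]
  tibble::tibble(
    row = r, col = c,
    in_extent = r >= 1L & r <= landscape$n_rows &
      c >= 1L & c <= landscape$n_cols
  )
}

#' Evaluate one candidate cell against the movement rules
#'
#' Implements the per-cell decision: an impassable cell (road, water, dense
#' cover, nodata) is rejected outright; a passable cell within the
#' deterministic acceptance distance of escape terrain is accepted without
#' consuming a random draw; beyond that distance a uniform draw on (0, 100)
#' is compared strictly against the distance-decay probability
#' ([movement_probability()]), so a probability of 100 or more always
#' accepts.
#'
#' @param landscape A `raster_landscape`.
#' @param cell Integer `c(row, col)`; must be in extent.
#' @param rules Movement rules (default: the landscape's).
#' @param draw Optional fixed number in (0, 100) standing in for the random
#'   draw — used to make single evaluations deterministic in tests; leave
#'   `NULL` to draw from the RNG.
#' @return `TRUE` if the agent would move to this cell.
#' @export
evaluate_candidate <- function(landscape, cell, rules = landscape$rules,
                               draw = NULL) {
  if (!is_passable(landscape, cell[1], cell[2], rules)) return(FALSE)
  d <- landscape$escape_distance[cell[1], cell[2]]
  if (d <= rules$escape_accept_dist_m) return(TRUE)
  p <- movement_probability(d, rules)
  if (is.null(draw)) draw <- stats::runif(1, 0, 100)
  draw < p
}

#' Advance an agent by one decision step
#'
#' One tick of the behaviour heuristic: if the agent has already made
#' `rules$max_steps` moves it is removed (`max_steps`); otherwise the
#' randomised candidate list is walked in order and the first acceptable
#' cell becomes the destination. Reaching an out-of-extent exit marker
#' removes the agent (`left_extent`); exhausting the list removes it
#' (`stuck` — surrounded by only poor habitat).
#'
#' @param landscape A `raster_landscape`.
#' @param agent A list with `current` (`c(row, col)`), `previous` (`c(row,
#'   col)` or `NULL`) and `steps_taken`.
#' @param rules Movement rules.
#' @return A list with `kind` (`"moved"` or `"removed"`), `destination`
#'   (`c(row, col)` or `NULL`) and `reason` (`"stuck"`, `"left_extent"`,
#'   `"max_steps"` or `NULL`).
#' @export
step_agent <- function(landscape, agent, rules = landscape$rules) {
  if (agent$steps_taken >= rules$max_steps)
    return(list(kind = "removed", destination = NULL, reason = "max_steps"))
  cand <- neighbor_candidates(landscape, agent$current, agent$previous)
  for (k in seq_len(nrow(cand))) {
    if (!cand$in_extent[k])
      return(list(kind = "removed", destination = NULL,
                  reason = "left_extent"))
    if (evaluate_candidate(landscape, c(cand$row[k], cand$col[k]), rules))
      return(list(kind = "moved",
                  destination = c(cand$row[k], cand$col[k]), reason = NULL))
  }
  list(kind = "removed", destination = NULL, reason = "stuck")
}

# Precomputed per-(landscape, rules) matrices consulted inside the walk loop.
walk_context <- function(landscape, rules = landscape$rules) {
  landscape <- with_rules(landscape, rules)
  pass <- passability_matrix(landscape, rules)
  d <- landscape$escape_distance
  list(pass = pass,
       det = d <= rules$escape_accept_dist_m,
       prob = rules$prob_coef_a * exp(-rules$prob_rate_b * d),
       nr = landscape$n_rows, nc = landscape$n_cols,
       max_steps = rules$max_steps,
       landscape = landscape)
}

# The tight inner loop. RNG consumption per step: one sample.int() for the
# candidate shuffle, then one runif() per probabilistically evaluated
# candidate, in list order — identical to step_agent()'s consumption.
walk_one <- function(ctx, r0, c0) {
  nr <- ctx$nr; nc <- ctx$nc
  pass <- ctx$pass; det <- ctx$det; prob <- ctx$prob
  max_steps <- ctx$max_steps
  cells <- matrix(0L, max_steps + 1L, 2L)
  cells[1L, ] <- c(r0, c0)
  cr <- r0; cc <- c0
  pr <- 0L; pc <- 0L            # 0 = no previous cell
  steps <- 0L
  reason <- NULL
  repeat {
    if (steps >= max_steps) { reason <- "max_steps"; break }
    r8 <- cr + .moore_dr; c8 <- cc + .moore_dc
    if (pr > 0L) {
      keep <- !(r8 == pr & c8 == pc)
      r8 <- r8[keep]; c8 <- c8[keep]
    }
    ord <- sample.int(length(r8))
    moved <- FALSE
    for (k in ord) {
      rr <- r8[k]; kc <- c8[k]
      if (rr < 1L || rr > nr || kc < 1L || kc > nc) {
        reason <- "left_extent"; break
      }
      if (!pass[rr, kc]) next
      ok <- det[rr, kc] || stats::runif(1, 0, 100) < prob[rr, kc]
      if (ok) {
        pr <- cr; pc <- cc; cr <- rr; cc <- kc
        steps <- steps + 1L
        cells[steps + 1L, ] <- c(cr, cc)
        moved <- TRUE
        break
      }
    }
    if (!is.null(reason)) break
    if (!moved) { reason <- "stuck"; break }
  }
  list(cells = cells[seq_len(steps + 1L), , drop = FALSE], reason = reason)
}

#' Run one agent to removal
#'
#' Repeatedly applies the step heuristic from a seed cell until the agent is
#' removed: stuck (no acceptable neighbour), left the landscape extent, or
#' reached the step cap. Every occupied cell, the seed included, is recorded
#' in order.
#'
#' @param landscape A `raster_landscape`.
#' @param seed_cell Integer `c(row, col)`; must be in extent and passable.
#' @param rules Movement rules.
#' @param rng_seed Optional integer; when given, `set.seed()` is called so
#'   the trajectory is reproducible in isolation. When `NULL` the current
#'   RNG stream is consumed.
#' @return A tibble of class `hw_trajectory` with columns `step` (0-based),
#'   `row`, `col`, `x`, `y` and attributes `removal_reason` and `rng_seed`.
#' @examples
#' land <- make_toy_landscape(slope = matrix(45, 9, 9))
#' traj <- run_agent(land, c(5, 5), rng_seed = 1)
#' attr(traj, "removal_reason")
#' @export
run_agent <- function(landscape, seed_cell, rules = landscape$rules,
                      rng_seed = NULL) {
  if (any(seed_cell < 1) || seed_cell[1] > landscape$n_rows ||
      seed_cell[2] > landscape$n_cols)
    stop("seed cell out of extent", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ctx <- walk_context(landscape, rules)
  if (!ctx$pass[seed_cell[1], seed_cell[2]])
    stop("seed cell is not passable under the given rules", call. = FALSE)
  res <- walk_one(ctx, as.integer(seed_cell[1]), as.integer(seed_cell[2]))
  trajectory_tibble(ctx$landscape, res$cells, res$reason, rng_seed)
}

trajectory_tibble <- function(landscape, cells, reason, rng_seed) {
  xy <- cell_to_xy(landscape, cells[, 1], cells[, 2])
  out <- tibble::tibble(
    step = seq_len(nrow(cells)) - 1L,
    row = cells[, 1], col = cells[, 2],
    x = xy$x, y = xy$y
  )
  attr(out, "removal_reason") <- reason
  attr(out, "rng_seed") <- rng_seed
  class(out) <- c("hw_trajectory", class(out))
  out
}

#' @export
print.hw_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d cells (%d moves), removed: %s\n",
              nrow(x), nrow(x) - 1L, attr(x, "removal_reason")))
  NextMethod()
}
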