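#' Bighorn sheep movement rules
#'
#' Bundles every behavioural threshold of the model. Defaults are the
#' field-calibrated values for Okanagan bighorn sheep: escape terrain is any
#' slope strictly above 40 degrees; cells with strictly more than 40% crown
#' cover, or carrying a road or water, cannot be occupied; cells within 400 m
#' of escape terrain are always acceptable, and beyond that acceptance is
#' probabilistic with percent probability `prob_coef_a * exp(-prob_rate_b *
#' distance)` (188.21 at distance 0, decaying at 0.0016 per metre). Agents
#' are removed after `max_steps` moves.
#'
#' The rule flags exist so management scenarios can relax individual rules:
#' `cover_rule_enabled = FALSE` emulates a restored fire regime (canopy no
#' longer restricts movement) and `roads_block = FALSE` makes roads permeable
#' for crossing-site analysis. Water always blocks in every scenario.
#'
#' @param slope_threshold_deg Slope (degrees) strictly above which a cell is
#'   escape terrain.
#' @param cover_threshold_pct Crown cover (percent) strictly above which a
#'   cell cannot be occupied.
#' @param escape_accept_dist_m Distance to escape terrain (m) up to which a
#'   candidate cell is accepted deterministically.
#' @param prob_coef_a,prob_rate_b Coefficients of the distance-decay
#'   acceptance probability (percent at distance 0; decay rate per metre).
#' @param max_steps Maximum number of moves before an agent is removed.
#' @param cover_rule_enabled,roads_block,water_blocks Rule switches.
#' @param distance_metric `"euclidean"` (centre-to-centre distance transform)
#'   or `"grid_ring"` (Chebyshev ring count times the cell size, so distances
#'   come in multiples of the cell size).
#' @return An object of class `movement_rules`.
#' @examples
#' movement_rules()
#' movement_rules(cover_rule_enabled = FALSE)  # fire-restored canopy
#' @export
movement_rules <- function(slope_threshold_deg = 40,
                           cover_threshold_pct = 40,
                           escape_accept_dist_m = 400,
                           prob_coef_a = 188.21,
                           prob_rate_b = 0.0016,
                           max_steps = 2000,
                           cover_rule_enabled = TRUE,
                           roads_block = TRUE,
                           water_blocks = TRUE,
                           distance_metric = c("euclidean", "grid_ring")) {
  distance_metric <- match.arg(distance_metric)
  stopifnot(slope_threshold_deg > 0, cover_threshold_pct > 0,
            escape_accept_dist_m > 0, prob_coef_a > 0, prob_rate_b > 0,
            max_steps > 0)
  structure(
    list(slope_threshold_deg = slope_threshold_deg,
         cover_threshold_pct = cover_threshold_pct,
         escape_accept_dist_m = escape_accept_dist_m,
         prob_coef_a = prob_coef_a, prob_rate_b = prob_rate_b,
         max_steps = as.integer(max_steps),
         cover_rule_enabled = isTRUE(cover_rule_enabled),
         roads_block = isTRUE(roads_block),
         water_blocks = isTRUE(water_blocks),
         distance_metric = distance_metric),
    class = "movement_rules"
  )
}

#' @export
print.movement_rules <- function(x, ...) {
  cat("<movement_rules>\n")
  cat(sprintf("  escape terrain: slope > %g deg; accept within %g m, beyond: %g*exp(-%g*d) %%\n",
              x$slope_threshold_deg, x$escape_accept_dist_m,
              x$prob_coef_a, x$prob_rate_b))
  cat(sprintf("  cover rule %s (> %g%% blocks); roads %s; water %s; max %d moves; %s distance\n",
              if (x$cover_rule_enabled) "on" else "off", x$cover_threshold_pct,
              if (x$roads_block) "block" else "open",
              if (x$water_blocks) "block" else "open",
              x$max_steps, x$distance_metric))
  invisible(x)
}

# merge a partial named list of overrides into a movement_rules object
apply_rule_overrides <- function(rules, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(rules)
  unknown <- setdiff(names(overrides), names(unclass(rules)))
  if (length(unknown))
    stop("unknown rule override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(movement_rules, utils::modifyList(unclass(rules), overrides))
}

#' Distance-decay movement probability
#'
#' Percent probability that a sheep moves to a cell at the given distance
#' from escape terrain: `a * exp(-b * distance)`. The value may exceed 100
#' at short distances; acceptance logic caps the effect, not the value.
#' Within `escape_accept_dist_m` this function is not consulted at all —
#' acceptance there is a deterministic rule.
#'
#' @param distance Distance to escape terrain in metres (vectorised, >= 0).
#' @param rules A [movement_rules()] object.
#' @return Numeric vector of percent probabilities.
#' @examples
#' movement_probability(0)    # 188.21
#' movement_probability(450)  # ~91.6
#' @export
movement_probability <- function(distance, rules = movement_rules()) {
  if (any(distance < 0, na.rm = TRUE))
    stop("distance must be non-negative", call. = FALSE)
  rules$prob_coef_a * exp(-rules$prob_rate_b * distance)
}

#' Smallest grid-attainable distance beyond the acceptance radius
#'
#' On a square grid distances to escape terrain come in discrete steps, so
#' the probabilistic rule first takes effect at the smallest attainable
#' distance strictly greater than `escape_accept_dist_m`. Under the
#' `grid_ring` metric (multiples of the cell size) with 75 m cells and a
#' 400 m radius this is 450 m.
#'
#' @param cell_size Cell edge length (m).
#' @param rules A [movement_rules()] object.
#' @return Distance in metres.
#' @export
min_distance_beyond_accept <- function(cell_size, rules = movement_rules()) {
  (floor(rules$escape_accept_dist_m / cell_size) + 1) * cell_size
}
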