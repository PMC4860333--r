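test_that("candidate lists are shuffled Moore neighbourhoods minus the previous cell", {
  land <- all_escape_landscape(5, 5)
  set.seed(1)
  cand <- neighbor_candidates(land, c(3, 3))
  expect_equal(nrow(cand), 8)
  expect_setequal(paste(cand$row, cand$col),
                  paste(c(2, 2, 2, 3, 3, 4, 4, 4), c(2, 3, 4, 2, 4, 2, 3, 4)))
  expect_true(all(cand$in_extent))

  cand7 <- neighbor_candidates(land, c(3, 3), previous = c(2, 3))
  expect_equal(nrow(cand7), 7)
  expect_false(any(cand7$row == 2 & cand7$col == 3))

  corner <- neighbor_candidates(land, c(1, 1))
  expect_equal(nrow(corner), 8)
  expect_equal(sum(corner$in_extent), 3)   # 3 real neighbours
  expect_equal(sum(!corner$in_extent), 5)  # 5 exit markers

  # order is a uniform random permutation: each of the 8 cells appears
  # first ~1/8 of the time
  set.seed(2)
  firsts <- replicate(4000, {
    cc <- neighbor_candidates(land, c(3, 3))
    paste(cc$row[1], cc$col[1])
  })
  freq <- table(firsts) / 4000
  expect_equal(length(freq), 8)
  se3 <- 3 * sqrt(0.125 * 0.875 / 4000)
  expect_true(all(abs(freq - 0.125) < se3))
})

test_that("candidate evaluation follows the distance-decay acceptance rule", {
  # corridor of cells at controlled distances from a single escape column
  slope <- matrix(0, 1, 9); slope[1, 1] <- 45
  land <- make_toy_landscape(slope = slope, cell_size = 75,
                             rules = movement_rules(distance_metric = "grid_ring"))
  # cells 1..6 are within 450 >= ... wait 400 m: columns 1..6 at 0..375 m
  expect_equal(land$escape_distance[1, 6], 375)
  expect_equal(land$escape_distance[1, 7], 450)

  # within 400 m: accepted deterministically, no random draw consumed
  set.seed(9); state_before <- .Random.seed
  expect_true(evaluate_candidate(land, c(1, 6)))
  expect_identical(.Random.seed, state_before)

  # beyond 400 m: strict comparison against 188.21 * exp(-0.0016 d)
  p450 <- 188.21 * exp(-0.0016 * 450)      # ~91.611
  expect_true(evaluate_candidate(land, c(1, 7), draw = 50))
  expect_true(evaluate_candidate(land, c(1, 7), draw = p450 - 1e-9))
  expect_false(evaluate_candidate(land, c(1, 7), draw = p450 + 1e-9))
  expect_false(evaluate_candidate(land, c(1, 7), draw = 95))

  # impassable cells are rejected regardless of distance
  roads <- matrix(0, 1, 9); roads[1, 2] <- 1
  land2 <- make_toy_landscape(slope = slope, roads = roads,
                              rules = land$rules)
  expect_false(evaluate_candidate(land2, c(1, 2), draw = 1))
})

test_that("empirical acceptance frequency matches min(1, p/100) at fixed distance", {
  slope <- matrix(0, 1, 9); slope[1, 1] <- 45
  land <- make_toy_landscape(slope = slope, cell_size = 75,
                             rules = movement_rules(distance_metric = "grid_ring"))
  n <- 1e5
  set.seed(77)
  acc <- sum(replicate(n, evaluate_candidate(land, c(1, 7))))
  p <- min(1, 188.21 * exp(-0.0016 * 450) / 100)
  se3 <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(acc / n - p), se3)
})

test_that("agents are removed when stuck, at the step cap, or on leaving the extent", {
  sealed <- sealed_landscape()
  agent <- list(current = c(2, 2), previous = NULL, steps_taken = 0L)
  set.seed(1)
  out <- step_agent(sealed, agent)
  expect_equal(out$kind, "removed")
  expect_equal(out$reason, "stuck")

  land <- all_escape_landscape(5, 5)
  agent$steps_taken <- land$rules$max_steps
  out <- step_agent(land, agent)
  expect_equal(out$reason, "max_steps")

  # an agent in a corner eventually draws an exit marker first
  set.seed(4)
  agent <- list(current = c(1, 1), previous = NULL, steps_taken = 0L)
  reasons <- replicate(50, step_agent(land, agent)$kind)
  expect_true("removed" %in% reasons)  # left_extent happens

  # a normal move lands on an 8-adjacent cell
  set.seed(2)
  agent <- list(current = c(3, 3), previous = c(2, 2), steps_taken = 1L)
  out <- step_agent(land, agent)
  expect_equal(out$kind, "moved")
  expect_true(max(abs(out$destination - c(3, 3))) == 1)
  expect_false(all(out$destination == c(2, 2)))
})

test_that("a sealed seed yields a one-cell trajectory; the corridor walk is forced", {
  traj <- run_agent(sealed_landscape(), c(2, 2), rng_seed = 1)
  expect_equal(nrow(traj), 1)
  expect_equal(attr(traj, "removal_reason"), "stuck")

  # unique legal move at every step: the brute-force oracle is the straight
  # eastward march from column 2 to column n-1
  n <- 12
  land <- corridor_landscape(n)
  traj <- run_agent(land, c(2, 2), rng_seed = 42)
  expect_equal(traj$row, rep(2L, n - 2))
  expect_equal(traj$col, 2:(n - 1))
  expect_equal(attr(traj, "removal_reason"), "stuck")
})

test_that("trajectories are deterministic given the seed and respect the step cap", {
  land <- mixed_landscape(seed = 3)
  start <- which(hornwalk:::passability_matrix(land, land$rules),
                 arr.ind = TRUE)[200, ]
  t1 <- run_agent(land, start, rng_seed = 99)
  t2 <- run_agent(land, start, rng_seed = 99)
  expect_identical(t1, t2)

  land2 <- all_escape_landscape(201, 201,
                                rules = movement_rules(max_steps = 300))
  t3 <- run_agent(land2, c(101, 101), rng_seed = 5)
  expect_equal(nrow(t3), 301)
  expect_equal(attr(t3, "removal_reason"), "max_steps")

  expect_error(run_agent(sealed_landscape(), c(1, 1)), "not passable")
  expect_error(run_agent(land, c(0, 5)), "extent")
})

test_that("step-by-step output equals an independent re-implementation", {
  # same RNG stream, toy 5x5 landscape with mixed barriers and a distant
  # escape cell so both deterministic and probabilistic branches trigger
  slope <- matrix(0, 5, 5); slope[1, 1] <- 50
  cover <- matrix(0, 5, 5); cover[4, 4] <- 60
  water <- matrix(0, 5, 5); water[3, 1] <- 1
  rules <- movement_rules(escape_accept_dist_m = 100, max_steps = 50,
                          distance_metric = "euclidean")
  land <- make_toy_landscape(slope = slope, cover = cover, water = water,
                             rules = rules)
  for (s in 1:25) {
    set.seed(s)
    ref <- ref_run_agent(land, c(3, 3))
    got <- run_agent(land, c(3, 3), rng_seed = s)
    expect_equal(cbind(got$row, got$col), unname(ref$path),
                 label = sprintf("seed %d", s))
    expect_equal(attr(got, "removal_reason"), ref$reason)
  }
})

test_that("trajectory invariants hold over many random walks", {
  land <- mixed_landscape(seed = 8)
  pass <- hornwalk:::passability_matrix(land, land$rules)
  seeds_ok <- which(pass, arr.ind = TRUE)
  set.seed(31)
  starts <- seeds_ok[sample(nrow(seeds_ok), 200), , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    tr <- run_agent(land, starts[i, ], rng_seed = i)
    if (nrow(tr) > 1) {
      dr <- diff(tr$row); dc <- diff(tr$col)
      expect_true(all(pmax(abs(dr), abs(dc)) == 1))      # 8-adjacency
      if (nrow(tr) > 2)                                   # no backtrack
        expect_true(all(tr$row[-(1:2)] != tr$row[-c(nrow(tr) - 1, nrow(tr))] |
                        tr$col[-(1:2)] != tr$col[-c(nrow(tr) - 1, nrow(tr))]))
    }
    # barrier avoidance: no visited cell is road, water, or dense cover
    expect_true(all(pass[cbind(tr$row, tr$col)]))
    expect_lte(nrow(tr), land$rules$max_steps + 1)
  }
})
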