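test_that("problem assembly builds incidence, costs and fallbacks correctly", {
  g <- grid_spec(3, 3, 5)
  env <- tiny_env(g, edaphic = c(-1, -1, 1, -1, 1, 1, 1, 1, 1),
                  geophysical = rep(0, 9), climatic = rnorm(9))
  elc <- build_elc(env, 1:9, k = c(edaphic = 2, geophysical = 1, climatic = 1),
                   species_id = "sp1", seed = 1)
  pa <- rasterize_pa(data.frame(cell_id = c(1, 2), protected = 1), g)

  # species with a 3-cell stable range and 2 scenarios split 2/1
  s1 <- list(species_id = "sp1", pathway = "model",
             current = range_map(1:5, "sp1", "current", "model", g),
             stable = range_map(c(1, 2, 3), "sp1", "stable", "model", g),
             loss = 0.4)
  pr <- build_problem(list(sp1 = s1), list(sp1 = elc), pa, g)
  expect_equal(nrow(pr$combinations), 2)
  inc <- dplyr::left_join(pr$incidence, pr$units, by = "unit_id")
  split_sizes <- sort(table(pr$incidence$combination_id))
  expect_equal(unname(as.vector(split_sizes)), c(1, 2))
  expect_setequal(inc$cell_id, c(1, 2, 3))

  # costs: 10 on protected, 50 elsewhere
  expect_equal(pr$units$cost[pr$units$pa == 1], c(10, 10))
  expect_equal(pr$units$cost[pr$units$pa == 0], 50)

  # full predicted loss: the current range feeds the incidence instead
  s_lost <- list(species_id = "sp1", pathway = "model",
                 current = range_map(4:6, "sp1", "current", "model", g),
                 stable = range_map(integer(0), "sp1", "stable", "model", g),
                 loss = 1)
  pr2 <- build_problem(list(sp1 = s_lost), list(sp1 = elc), pa, g)
  inc2 <- dplyr::left_join(pr2$incidence, pr2$units, by = "unit_id")
  expect_setequal(inc2$cell_id, 4:6)
})

test_that("a combination covered by a single unit is always selected", {
  units <- tibble::tibble(unit_id = 1:4, pa = c(1, 0, 0, 0),
                          cost = c(10, 50, 50, 50))
  inc <- tibble::tibble(combination_id = c(1, 2, 2), unit_id = c(3, 1, 2))
  pr <- new_reserve_problem(units, tibble::tibble(combination_id = 1:2), inc,
                            blm = 0.001)
  ens <- anneal(pr, n_runs = 5, n_iter = 500, seed = 1)
  for (r in ens$runs) {
    expect_true(3 %in% r$selected)
    expect_length(r$unmet, 0)
  }
})

test_that("annealing matches the exhaustive optimum on toy instances", {
  set.seed(11)
  for (i in 1:10) {
    pr <- random_reserve_problem(n_units = 6, n_combos = 4,
                                 blm = sample(c(0, 0.001, 1), 1), seed = 400 + i)
    ens <- anneal(pr, n_runs = 10, n_iter = 800, seed = i)
    oracle <- oracle_enumerate_reserve(pr)
    best_obj <- min(ens$summary$objective)
    expect_equal(best_obj, oracle$objective, tolerance = 1e-9)
    expect_length(ens$best$unmet, 0)
  }
})

test_that("objective decomposition agrees with the from-scratch recomputation", {
  pr <- random_reserve_problem(n_units = 12, n_combos = 6, blm = 0.001, seed = 21)
  ens <- anneal(pr, n_runs = 5, n_iter = 1000, seed = 2)
  for (r in ens$runs) {
    check <- reserve_objective(pr, r$selected)
    expect_equal(r$objective, check$objective, tolerance = 1e-9)
    expect_equal(r$total_cost, check$total_cost)
    expect_equal(r$boundary, check$boundary)
    expect_equal(r$penalty, check$penalty, tolerance = 1e-9)
    expect_setequal(r$unmet, check$unmet)
  }
})

test_that("a large boundary modifier produces more compact solutions", {
  # two spatial clusters of units; the combination set can be met inside one
  units <- tibble::tibble(unit_id = 1:8, pa = 1, cost = 10)
  combos <- tibble::tibble(combination_id = 1:2)
  # combos available in both clusters
  inc <- tibble::tibble(
    combination_id = c(1, 2, 1, 2),
    unit_id = c(1, 2, 5, 8)
  )
  # cluster A: units 1-4 chained; cluster B: units 5-8 chained, far apart
  adj <- tibble::tibble(
    unit_id = c(1, 2, 2, 3, 3, 4, 5, 6, 6, 7, 7, 8),
    neighbour_unit = c(2, 1, 3, 2, 4, 3, 6, 5, 7, 6, 8, 7)
  )
  pr_lo <- new_reserve_problem(units, combos, inc, adj, blm = 0)
  pr_hi <- new_reserve_problem(units, combos, inc, adj, blm = 5)
  lo <- anneal(pr_lo, n_runs = 10, n_iter = 2000, seed = 3)
  hi <- anneal(pr_hi, n_runs = 10, n_iter = 2000, seed = 3)
  expect_lte(hi$best$boundary, lo$best$boundary)
  # under high BLM the solution stays within one adjacent cluster
  expect_true(all(hi$best$selected %in% 1:4) || all(hi$best$selected %in% 5:8))
})

test_that("lowering a selected unit's cost never worsens the optimum", {
  for (i in 1:5) {
    pr <- random_reserve_problem(n_units = 8, n_combos = 4, blm = 0.001,
                                 seed = 600 + i)
    o1 <- oracle_enumerate_reserve(pr)
    u <- o1$selected[1]
    pr2 <- pr
    pr2$units$cost[u] <- 10
    # penalties depend on unit costs: rebuild to keep the problem coherent
    pr2 <- new_reserve_problem(pr2$units, pr2$combinations[, "combination_id"],
                               pr2$incidence, pr2$adjacency, blm = pr2$blm,
                               spf = pr2$spf)
    o2 <- oracle_enumerate_reserve(pr2)
    expect_lte(o2$objective, o1$objective + 1e-9)
  }
})

test_that("runs are ranked by units, then cost, then run index", {
  mk <- function(run, n_units, cost) {
    list(run = run, n_units = n_units, total_cost = cost, boundary = 0,
         penalty = 0, objective = cost, unmet = integer(0),
         selected = seq_len(n_units))
  }
  fake <- structure(
    list(
      runs = list(mk(1, 10, 300), mk(2, 9, 500), mk(3, 9, 480)),
      summary = tibble::tibble(
        run = 1:3, n_units = c(10, 9, 9), total_cost = c(300, 500, 480),
        boundary = 0, penalty = 0, objective = c(300, 500, 480), n_unmet = 0
      )
    ),
    class = "reserve_ensemble"
  )
  expect_equal(rank_runs(fake)$run, 3) # fewest units, then lowest cost
  fake$summary$total_cost <- c(300, 480, 480)
  fake$runs[[2]]$total_cost <- 480
  expect_equal(rank_runs(fake)$run, 2) # tie broken by run index
})

test_that("uncoverable combinations are dropped with a warning, never silent", {
  units <- tibble::tibble(unit_id = 1:2, pa = 1, cost = 10)
  inc <- tibble::tibble(combination_id = 1, unit_id = 1)
  expect_warning(
    pr <- new_reserve_problem(units, tibble::tibble(combination_id = 1:2), inc),
    "no planning unit"
  )
  expect_equal(nrow(pr$combinations), 1)
  ens <- anneal(pr, n_runs = 2, n_iter = 100, seed = 1)
  expect_length(ens$best$unmet, 0)
})
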