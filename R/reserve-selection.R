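#' Assemble a minimum-set reserve planning problem
#'
#' Planning units are analysis grid cells; unit cost is 10 where the cell
#' overlaps a protected area and 50 where it does not, so protected cells are
#' prioritized through the cost differential. Conservation features are
#' species x adaptive-scenario combinations; each must be represented in at
#' least one selected unit (species penalty factor 1 per combination). For
#' species with a valid current and future model the climate-stable range
#' feeds the incidence; species with predicted full range loss, or without a
#' valid model, contribute their current range instead. Adjacency is
#' rook-neighbour on the grid; the boundary length modifier (default 0.001)
#' trades compactness against cost. Combinations that occur in no unit are
#' reported and dropped with a warning.
#'
#' @param sdms Named list of [fit_species_sdm()] results.
#' @param elcs Named list of [build_elc()] maps.
#' @param pa A `pa_mask`.
#' @param grid The [grid_spec()].
#' @param blm Boundary length modifier (default 0.001).
#' @param spf Species penalty factor (default 1).
#' @param cost_pa,cost_outside Unit costs (defaults 10, 50).
#' @return An object of class `reserve_problem`: `units` (tibble `unit_id`,
#'   `cell_id`, `cost`, `pa`), `combinations` (tibble `combination_id`,
#'   `species_id`, `category`, `n_units`, `penalty`), `incidence` (tibble
#'   `combination_id`, `unit_id`), `adjacency` (unit-index pairs), `blm`,
#'   `spf`, `grid`.
#' @export
build_problem <- function(sdms, elcs, pa, grid, blm = 0.001, spf = 1,
                          cost_pa = 10, cost_outside = 50) {
  stopifnot(inherits(grid, "grid_spec"))
  feat <- dplyr::bind_rows(lapply(names(sdms), function(sp) {
    s <- sdms[[sp]]
    cells <- if (!is.null(s$stable) && nrow(s$stable) > 0) {
      s$stable$cell_id # valid future model with surviving range
    } else {
      s$current$cell_id # full predicted loss, buffer pathway, or no futures
    }
    elc <- elcs[[sp]]
    cat <- elc$category[match(cells, elc$cell_id)]
    ok <- !is.na(cat)
    tibble::tibble(species_id = sp, category = cat[ok], cell_id = cells[ok])
  }))
  if (nrow(feat) == 0) stop("no species x scenario combinations to cover")
  feat <- dplyr::distinct(feat)
  combos <- feat |>
    dplyr::distinct(.data$species_id, .data$category) |>
    dplyr::arrange(.data$species_id, .data$category)
  combos$combination_id <- seq_len(nrow(combos))
  unit_cells <- sort(unique(feat$cell_id))
  prot <- pa$protected[unit_cells] == 1
  units <- tibble::tibble(
    unit_id = seq_along(unit_cells),
    cell_id = unit_cells,
    pa = as.integer(prot),
    cost = ifelse(prot, cost_pa, cost_outside)
  )
  incidence <- feat |>
    dplyr::inner_join(combos, by = c("species_id", "category")) |>
    dplyr::inner_join(units[, c("unit_id", "cell_id")], by = "cell_id") |>
    dplyr::distinct(.data$combination_id, .data$unit_id) |>
    dplyr::arrange(.data$combination_id, .data$unit_id)
  adj_cells <- grid_adjacency(grid)
  adjacency <- adj_cells |>
    dplyr::inner_join(units[, c("unit_id", "cell_id")], by = "cell_id") |>
    dplyr::inner_join(
      dplyr::rename(units[, c("unit_id", "cell_id")],
                    neighbour_unit = "unit_id", neighbour_id = "cell_id"),
      by = "neighbour_id"
    ) |>
    dplyr::select(unit_id = "unit_id", neighbour_unit = "neighbour_unit") |>
    dplyr::arrange(.data$unit_id, .data$neighbour_unit)
  new_reserve_problem(units, combos, incidence, adjacency, blm, spf, grid)
}

#' Construct a reserve problem from explicit tables
#'
#' Low-level constructor used for toy and benchmark instances: supply the
#' planning units, the combination incidence, and (optionally) the adjacency
#' directly. The penalty for leaving a combination unmet is the cost of
#' actually meeting it with the cheapest single covering unit, including that
#' unit's full boundary contribution (`min cost + 4 * blm`), so meeting every
#' feasible target is always at least as good as paying the penalty.
#'
#' @param units Tibble `unit_id` (1..n), `cost`, `pa` (0/1).
#' @param combinations Tibble `combination_id` (1..m) plus any id columns.
#' @param incidence Tibble `combination_id`, `unit_id`.
#' @param adjacency Tibble `unit_id`, `neighbour_unit` (both directions), or
#'   NULL for no adjacency (every unit edge is exterior boundary).
#' @param blm,spf Boundary length modifier and species penalty factor.
#' @param grid Optional [grid_spec()] provenance.
#' @return A `reserve_problem`.
#' @export
new_reserve_problem <- function(units, combinations, incidence,
                                adjacency = NULL, blm = 0.001, spf = 1,
                                grid = NULL) {
  units <- tibble::as_tibble(units)
  combinations <- tibble::as_tibble(combinations)
  incidence <- tibble::as_tibble(incidence)
  stopifnot(
    identical(units$unit_id, seq_len(nrow(units))),
    identical(sort(unique(combinations$combination_id)), seq_len(nrow(combinations))),
    all(incidence$unit_id %in% units$unit_id),
    blm >= 0, spf >= 0
  )
  if (is.null(adjacency)) {
    adjacency <- tibble::tibble(unit_id = integer(), neighbour_unit = integer())
  }
  n_per_combo <- table(factor(incidence$combination_id,
                              levels = combinations$combination_id))
  uncoverable <- combinations$combination_id[n_per_combo == 0]
  if (length(uncoverable) > 0) {
    warning(sprintf("%d combination(s) occur in no planning unit; dropped",
                    length(uncoverable)))
    combinations <- combinations[!(combinations$combination_id %in% uncoverable), ]
    old <- combinations$combination_id
    combinations$combination_id <- seq_len(nrow(combinations))
    incidence$combination_id <- match(incidence$combination_id, old)
    incidence <- incidence[!is.na(incidence$combination_id), ]
    n_per_combo <- table(factor(incidence$combination_id,
                                levels = combinations$combination_id))
  }
  combinations$n_units <- as.integer(n_per_combo)
  min_cost <- incidence |>
    dplyr::left_join(units[, c("unit_id", "cost")], by = "unit_id") |>
    dplyr::group_by(.data$combination_id) |>
    dplyr::summarise(min_cost = min(.data$cost), .groups = "drop")
  combinations$penalty <-
    min_cost$min_cost[match(combinations$combination_id, min_cost$combination_id)] +
    4 * blm
  structure(
    list(units = units, combinations = combinations,
         incidence = dplyr::arrange(incidence, .data$combination_id, .data$unit_id),
         adjacency = adjacency, blm = blm, spf = spf, grid = grid),
    class = "reserve_problem"
  )
}

#' @export
print.reserve_problem <- function(x, ...) {
  cat(sprintf(
    "<reserve_problem> %d units, %d combinations, blm %g, spf %g\n",
    nrow(x$units), nrow(x$combinations), x$blm, x$spf
  ))
  invisible(x)
}

# internal: CSR pointers (0-based) for a grouped id -> values mapping
make_csr <- function(group, value, n_groups) {
  ord <- order(group, value)
  counts <- tabulate(group[ord], n_groups)
  list(ptr = as.integer(c(0, cumsum(counts))), idx = as.integer(value[ord] - 1L))
}

#' Recompute a reserve objective from scratch
#'
#' Independent of the annealer's incremental bookkeeping: sums selected unit
#' costs, counts boundary edges (selected edges facing unselected units or
#' the exterior; perimeter 4 per unit), and adds the penalty of every unmet
#' combination.
#'
#' @param problem A `reserve_problem`.
#' @param selected Integer vector of selected `unit_id`s.
#' @return A list: `n_units`, `total_cost`, `boundary`, `penalty`,
#'   `objective`, `unmet` (combination ids).
#' @export
reserve_objective <- function(problem, selected) {
  selected <- unique(as.integer(selected))
  sel <- problem$units$unit_id %in% selected
  total_cost <- sum(problem$units$cost[sel])
  adj <- problem$adjacency
  internal_edges <- sum(sel[adj$unit_id] & sel[adj$neighbour_unit]) # directed
  boundary <- 4 * sum(sel) - internal_edges
  covered <- unique(problem$incidence$combination_id[
    problem$incidence$unit_id %in% selected
  ])
  unmet <- setdiff(problem$combinations$combination_id, covered)
  penalty <- problem$spf * sum(problem$combinations$penalty[
    match(unmet, problem$combinations$combination_id)
  ])
  list(
    n_units = sum(sel), total_cost = total_cost, boundary = boundary,
    penalty = penalty,
    objective = total_cost + problem$blm * boundary + penalty,
    unmet = unmet
  )
}

#' Solve a reserve problem by simulated annealing
#'
#' Runs `n_runs` independent annealing chains (random initial selections,
#' single-unit add/remove proposals accepted when they improve the objective
#' or with probability `exp(-delta / T)` under a geometric cooling schedule),
#' each followed by a greedy repair pass guaranteeing every coverable target
#' is met and a trim pass removing strictly wasteful units. Deterministic
#' given `seed`. Runs are ranked by fewest selected units, then lowest total
#' unit cost, then lowest run index.
#'
#' @param problem A `reserve_problem`.
#' @param n_runs Number of independent runs (default 100, as in the original
#'   configuration; scale down for desk-size problems).
#' @param n_iter Proposals per run (default 10000; the original cluster-scale
#'   configuration used 1e8).
#' @param seed Integer seed.
#' @param t_init,t_final Cooling schedule endpoints; defaults adapt `t_init`
#'   to the largest single-move objective change.
#' @return An object of class `reserve_ensemble`: `runs` (list of solutions:
#'   `selected`, `n_units`, `total_cost`, `boundary`, `penalty`, `objective`,
#'   `unmet`, `run`), `best` (top-ranked solution), `summary` tibble,
#'   `problem`.
#' @export
anneal <- function(problem, n_runs = 100, n_iter = 10000, seed = 1,
                   t_init = NULL, t_final = 0.1) {
  stopifnot(inherits(problem, "reserve_problem"), n_runs >= 1, n_iter >= 0)
  n <- nrow(problem$units)
  m <- nrow(problem$combinations)
  uc <- make_csr(problem$incidence$unit_id, problem$incidence$combination_id, n)
  # CSR over units for adjacency (unit -> neighbour unit indices)
  adj <- make_csr(problem$adjacency$unit_id, problem$adjacency$neighbour_unit, n)
  if (is.null(t_init)) {
    t_init <- max(problem$units$cost) + problem$spf * max(problem$combinations$penalty) +
      4 * problem$blm
  }
  runs <- with_seed(seed, {
    lapply(seq_len(n_runs), function(r) {
      init <- stats::runif(n) < 0.5
      sol <- .anneal_run_cpp(
        as.integer(problem$units$cost), adj$ptr, adj$idx, uc$ptr, uc$idx,
        as.numeric(problem$combinations$penalty),
        problem$blm, problem$spf, as.integer(n_iter),
        t_init, t_final, init
      )
      sol$run <- r
      sol
    })
  })
  summary <- dplyr::bind_rows(lapply(runs, function(s) {
    tibble::tibble(
      run = s$run, n_units = s$n_units, total_cost = s$total_cost,
      boundary = s$boundary, penalty = s$penalty, objective = s$objective,
      n_unmet = length(s$unmet)
    )
  }))
  ens <- structure(
    list(runs = runs, summary = summary, problem = problem),
    class = "reserve_ensemble"
  )
  ens$best <- rank_runs(ens)
  ens
}

#' Pick the best annealing run
#'
#' Lexicographic ranking: fewest selected planning units, then lowest total
#' unit cost, then lowest run index.
#'
#' @param ensemble A [anneal()] result.
#' @return The best run (list with `selected`, `objective`, ...).
#' @export
rank_runs <- function(ensemble) {
  stopifnot(inherits(ensemble, "reserve_ensemble"), length(ensemble$runs) >= 1)
  s <- ensemble$summary
  ord <- order(s$n_units, s$total_cost, s$run)
  ensemble$runs[[s$run[ord[1]]]]
}

#' @export
print.reserve_ensemble <- function(x, ...) {
  cat(sprintf(
    "<reserve_ensemble> %d run(s); best: %d units, cost %g, objective %g, %d unmet\n",
    length(x$runs), x$best$n_units, x$best$total_cost, x$best$objective,
    length(x$best$unmet)
  ))
  invisible(x)
}

#' @rdname tidy.maxent_model
#' @export
tidy.reserve_ensemble <- function(x, ...) x$summary

#' @rdname glance.maxent_model
#' @export
glance.reserve_ensemble <- function(x, ...) {
  tibble::tibble(
    n_runs = length(x$runs), n_units = x$best$n_units,
    total_cost = x$best$total_cost, boundary = x$best$boundary,
    penalty = x$best$penalty, objective = x$best$objective,
    n_unmet = length(x$best$unmet)
  )
}

#' Plot an annealing ensemble
#' @param object A [anneal()] result.
#' @param ... Unused.
#' @return A ggplot of per-run objective vs selected units.
#' @export
autoplot.reserve_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$n_units, .data$objective)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = object$summary[object$summary$run == object$best$run, ],
      colour = "red", size = 3
    ) +
    ggplot2::labs(x = "selected planning units", y = "objective",
                  title = "Annealing runs (best in red)")
}
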