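#' Greedy complementarity ranking of planning units
#'
#' Orders sites by iterative complementarity: the first site is the one
#' richest in species x adaptive-scenario combinations; each subsequent site
#' is the one adding the most combinations not yet represented. Two modes:
#' `"adaptive"` ranks over all units; `"pragmatic"` first ranks units
#' overlapping protected areas (until no protected unit adds coverage), then
#' continues over the remaining units for combinations not represented inside
#' protected areas. Ties break by more unique species added, then lowest unit
#' id. Ranking halts when no unit adds coverage, so the final network
#' represents every coverable combination at least once.
#'
#' @param units Tibble `unit_id`, `pa` (0/1), e.g. a `reserve_problem`'s
#'   `units` restricted to the chosen solution.
#' @param incidence Tibble `combination_id`, `unit_id`, `species_id`.
#' @param mode `"pragmatic"` (default) or `"adaptive"`.
#' @return A tibble of class `site_ranking`: `rank`, `unit_id`, `pa`,
#'   `n_cwr` (species present in the unit), `n_new_cwr` (species added),
#'   `n_new_combos` (combinations added), `cum_combos`, `cum_coverage`
#'   (fraction of all coverable combinations). Attribute `totals` records the
#'   universe sizes.
#' @export
greedy_rank <- function(units, incidence, mode = c("pragmatic", "adaptive")) {
  mode <- match.arg(mode)
  stopifnot(all(c("unit_id", "pa") %in% names(units)),
            all(c("combination_id", "unit_id", "species_id") %in% names(incidence)),
            nrow(incidence) > 0)
  incidence <- incidence[incidence$unit_id %in% units$unit_id, ]
  unit_ids <- sort(unique(units$unit_id))
  combos_of <- split(incidence$combination_id, incidence$unit_id)
  species_of <- lapply(split(incidence$species_id, incidence$unit_id), unique)
  n_combos_total <- dplyr::n_distinct(incidence$combination_id)
  pa_flag <- units$pa[match(unit_ids, units$unit_id)] == 1

  covered_combos <- integer(0)
  covered_species <- character(0)
  remaining <- unit_ids
  rows <- list()
  phase_pa <- mode == "pragmatic"
  repeat {
    candidates <- if (phase_pa) {
      remaining[pa_flag[match(remaining, unit_ids)]]
    } else {
      remaining
    }
    gains <- vapply(as.character(candidates), function(u) {
      length(setdiff(combos_of[[u]], covered_combos))
    }, integer(1))
    if (length(candidates) == 0 || all(gains == 0)) {
      if (phase_pa) {
        phase_pa <- FALSE # protected units exhausted: open up outside sites
        next
      }
      break
    }
    top <- candidates[gains == max(gains)]
    if (length(top) > 1) {
      sp_gain <- vapply(as.character(top), function(u) {
        length(setdiff(species_of[[u]], covered_species))
      }, integer(1))
      top <- top[sp_gain == max(sp_gain)]
    }
    pick <- min(top)
    key <- as.character(pick)
    new_combos <- setdiff(combos_of[[key]], covered_combos)
    new_species <- setdiff(species_of[[key]], covered_species)
    covered_combos <- c(covered_combos, new_combos)
    covered_species <- c(covered_species, new_species)
    rows[[length(rows) + 1]] <- tibble::tibble(
      unit_id = pick,
      pa = as.integer(pa_flag[match(pick, unit_ids)]),
      n_cwr = length(species_of[[key]]),
      n_new_cwr = length(new_species),
      n_new_combos = length(new_combos),
      cum_combos = length(covered_combos)
    )
    remaining <- setdiff(remaining, pick)
  }
  out <- dplyr::bind_rows(rows)
  out$rank <- seq_len(nrow(out))
  out$cum_coverage <- out$cum_combos / n_combos_total
  out <- out[, c("rank", "unit_id", "pa", "n_cwr", "n_new_cwr",
                 "n_new_combos", "cum_combos", "cum_coverage")]
  structure(
    out,
    totals = list(
      n_combinations = n_combos_total,
      n_species = dplyr::n_distinct(incidence$species_id)
    ),
    mode = mode,
    class = c("site_ranking", class(tibble::tibble()))
  )
}

#' @export
print.site_ranking <- function(x, ...) {
  cat(sprintf(
    "<site_ranking> [%s] %d sites covering %d combination(s)\n",
    attr(x, "mode"), nrow(x), max(c(0, x$cum_combos))
  ))
  NextMethod()
}

#' Plot cumulative coverage of a site ranking
#' @param object A [greedy_rank()] result.
#' @param ... Unused.
#' @return A ggplot accumulation curve, coloured by protected-area overlap.
#' @export
autoplot.site_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rank, .data$cum_coverage)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$pa))) +
    ggplot2::scale_colour_manual(
      values = c(`0` = "goldenrod", `1` = "steelblue"),
      labels = c(`0` = "outside PA", `1` = "inside PA"), name = NULL
    ) +
    ggplot2::labs(x = "site rank", y = "cumulative combination coverage")
}

#' Extract the top priority sites
#'
#' The first `n_pa` ranked sites inside protected areas and the first `n_out`
#' ranked sites outside them (the pragmatic ranking places all productive
#' protected sites first). Emits all available sites with a warning when a
#' slice is shorter than requested.
#'
#' @param ranking A pragmatic-mode [greedy_rank()] result.
#' @param n_pa,n_out Slice sizes (defaults 100 and 50, as in the global
#'   150-site analysis).
#' @return The subset of ranking rows, `site_no` numbered within each slice.
#' @export
top_sites <- function(ranking, n_pa = 100, n_out = 50) {
  stopifnot(inherits(ranking, "site_ranking"))
  if (!identical(attr(ranking, "mode"), "pragmatic")) {
    stop("top_sites() expects a pragmatic-mode ranking")
  }
  pa_rows <- ranking[ranking$pa == 1, ]
  out_rows <- ranking[ranking$pa == 0, ]
  if (nrow(pa_rows) < n_pa || nrow(out_rows) < n_out) {
    warning(sprintf(
      "requested %d + %d sites but only %d protected and %d outside available",
      n_pa, n_out, nrow(pa_rows), nrow(out_rows)
    ))
  }
  sel <- dplyr::bind_rows(
    utils::head(pa_rows, n_pa),
    utils::head(out_rows, n_out)
  )
  sel |>
    dplyr::group_by(.data$pa) |>
    dplyr::mutate(site_no = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$rank)
}

#' Combined statistics for a slice of priority sites
#'
#' Aggregates a set of sites into the headline numbers reported for top-site
#' tables: combined unique species (union of per-site species sets), combined
#' unique species x scenario combinations, and their percentages of the
#' assessed totals (round-half-up, one decimal).
#'
#' @param site_ids Unit ids of the slice.
#' @param incidence Tibble `combination_id`, `unit_id`, `species_id`.
#' @param n_species_total Assessed species count (percentage denominator).
#' @param n_combinations_total Total combination count.
#' @return One-row tibble: `n_sites`, `n_unique_cwr`, `pct_unique_cwr`,
#'   `n_combinations`, `pct_combinations`.
#' @export
headline_stats <- function(site_ids, incidence, n_species_total,
                           n_combinations_total) {
  if (n_species_total <= 0 || n_combinations_total <= 0) {
    stop("totals must be positive")
  }
  inc <- incidence[incidence$unit_id %in% site_ids, ]
  n_sp <- dplyr::n_distinct(inc$species_id)
  n_cb <- dplyr::n_distinct(inc$combination_id)
  tibble::tibble(
    n_sites = length(unique(site_ids)),
    n_unique_cwr = n_sp,
    pct_unique_cwr = headline_percentages(n_sp, n_species_total),
    n_combinations = n_cb,
    pct_combinations = headline_percentages(n_cb, n_combinations_total)
  )
}
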