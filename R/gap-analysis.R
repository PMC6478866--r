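#' Rasterize protected-area geometries to the analysis grid
#'
#' Turns a protected-area layer into a presence/absence mask on the grid. A
#' cell is protected iff its centre lies inside any polygon (cell-centre
#' rule, even-odd winding). Point-type geometries (fewer than three vertices)
#' cannot cover a cell centre and are dropped, with the drop count recorded on
#' the result. A ready-made 0/1 mask passes through after validation.
#'
#' @param x Either a list of polygons (each a data frame with vertex columns
#'   `x`, `y` in km) or a data frame with `cell_id`, `protected` (0/1).
#' @param grid The [grid_spec()].
#' @return A `pa_mask` tibble (`cell_id`, `protected`) with attributes `grid`
#'   and `n_points_dropped`.
#' @export
rasterize_pa <- function(x, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.data.frame(x)) {
    stopifnot(all(c("cell_id", "protected") %in% names(x)))
    prot <- integer(n_cells(grid))
    stopifnot(all(x$protected %in% c(0, 1)))
    prot[x$cell_id] <- as.integer(x$protected)
    return(structure(
      tibble::tibble(cell_id = seq_len(n_cells(grid)), protected = prot),
      grid = grid, n_points_dropped = 0L,
      class = c("pa_mask", class(tibble::tibble()))
    ))
  }
  stopifnot(is.list(x))
  is_point <- vapply(x, function(g) nrow(g) < 3, logical(1))
  n_dropped <- sum(is_point)
  polys <- x[!is_point]
  if (length(polys) == 0 && n_dropped > 0) {
    warning(sprintf("dropped %d point-type geometrie(s); no polygons remain", n_dropped))
  } else if (length(x) == 0) {
    warning("empty protected-area input: all-zero mask")
  }
  ctr <- grid_cells(grid)
  prot <- rep(FALSE, nrow(ctr))
  for (g in polys) {
    prot <- prot | point_in_polygon(ctr$x, ctr$y, g$x, g$y)
  }
  structure(
    tibble::tibble(cell_id = ctr$cell_id, protected = as.integer(prot)),
    grid = grid, n_points_dropped = n_dropped,
    class = c("pa_mask", class(tibble::tibble()))
  )
}

# internal: even-odd ray-casting point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# internal: protected cell ids from a pa_mask
pa_cells <- function(pa) pa$cell_id[pa$protected == 1]

#' Protected-area coverage of a range
#'
#' Percentage of a species' range cells that fall inside protected areas.
#' An empty range yields `NA` (the species cannot be assessed).
#'
#' @param range A [range_map()] or integer vector of cell ids.
#' @param pa A `pa_mask` (see [rasterize_pa()] / [generate_protected_areas()]).
#' @return Percentage in [0, 100], or `NA_real_` for an empty range.
#' @examples
#' g <- grid_spec(2, 5)
#' pa <- rasterize_pa(data.frame(cell_id = 1:3, protected = 1), g)
#' coverage(range_map(1:10, "sp1", "current", "model", g), pa) # 30
#' @export
coverage <- function(range, pa) {
  cells <- if (inherits(range, "range_map")) range$cell_id else as.integer(range)
  if (length(cells) == 0) return(NA_real_)
  100 * sum(pa$protected[cells]) / length(cells)
}

#' Scenario (genetic-diversity proxy) coverage and loss in protected areas
#'
#' `scenario_coverage()` is the percentage of the adaptive scenarios present
#' in the current range that also occur in its protected part.
#' `scenario_loss()` is the percentage of currently protected scenarios that
#' do not survive into the protected part of the climate-stable range.
#' Empty reference sets yield `NA`.
#'
#' @param scenarios_current Categories in the current range
#'   (see [scenarios_in_range()]).
#' @param scenarios_protected Categories in the protected part of the current
#'   range.
#' @return Percentage in [0, 100] or `NA_real_`.
#' @export
scenario_coverage <- function(scenarios_current, scenarios_protected) {
  if (length(scenarios_current) == 0) return(NA_real_)
  100 * length(intersect(scenarios_protected, scenarios_current)) /
    length(scenarios_current)
}

#' @rdname scenario_coverage
#' @param scenarios_protected_current Currently protected categories.
#' @param scenarios_protected_stable Categories in the protected part of the
#'   stable range.
#' @export
scenario_loss <- function(scenarios_protected_current, scenarios_protected_stable) {
  if (length(scenarios_protected_current) == 0) return(NA_real_)
  surviving <- intersect(scenarios_protected_stable, scenarios_protected_current)
  100 * (1 - length(surviving) / length(scenarios_protected_current))
}

#' Per-species in situ gap analysis
#'
#' Assembles the one-row-per-species gap table: protected-area coverage of the
#' current range, climate-driven range loss, scenario (genetic-diversity
#' proxy) coverage and loss inside protected areas, and the conservation
#' adequacy flag. A species is `under_conserved` when less than 50% of its
#' adaptive scenarios fall within protected areas; it is
#' `exclusively_outside` when its range does not touch a protected cell.
#' Buffer-pathway species have no future model, so their loss fields are `NA`.
#'
#' @param sdms Named list of [fit_species_sdm()] results (or a list with the
#'   same fields), one per analyzed species.
#' @param elcs Named list of [build_elc()] maps, one per species.
#' @param pa A `pa_mask`.
#' @param report Optional QC report (adds `n_occurrences` from
#'   `final_unique`).
#' @return A tibble of class `gap_table`, one row per species.
#' @export
gap_analysis <- function(sdms, elcs, pa, report = NULL) {
  rows <- lapply(names(sdms), function(sp) {
    s <- sdms[[sp]]
    elc <- elcs[[sp]]
    cur <- s$current$cell_id
    prot <- pa_cells(pa)
    cur_pa <- intersect(cur, prot)
    scen_cur <- scenarios_in_range(elc, cur)
    scen_cur_pa <- scenarios_in_range(elc, cur_pa)
    has_future <- !is.null(s$stable)
    stab_pa <- if (has_future) intersect(s$stable$cell_id, prot) else integer(0)
    pct_cover <- coverage(cur, pa)
    pct_pa_cover_loss <- if (has_future && length(cur_pa) > 0) {
      100 * (1 - length(stab_pa) / length(cur_pa))
    } else {
      NA_real_
    }
    scen_cov <- scenario_coverage(scen_cur, scen_cur_pa)
    tibble::tibble(
      species_id = sp,
      pathway = s$pathway,
      pct_range_in_pa_current = pct_cover,
      pct_range_loss_2070 = if (has_future) 100 * s$loss else NA_real_,
      pct_pa_cover_loss_2070 = pct_pa_cover_loss,
      n_scenarios_current = length(scen_cur),
      pct_scenarios_in_pa_current = scen_cov,
      pct_scenario_loss_in_pa_2070 = if (has_future) {
        scenario_loss(scen_cur_pa, scenarios_in_range(elc, stab_pa))
      } else {
        NA_real_
      },
      exclusively_outside = !is.na(pct_cover) && pct_cover == 0,
      under_conserved = !is.na(scen_cov) & scen_cov < 50
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(report)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(report, "species_id", n_occurrences = "final_unique"),
      by = "species_id"
    )
    out <- dplyr::relocate(out, "n_occurrences", .after = "species_id")
  }
  class(out) <- c("gap_table", class(tibble::tibble()))
  out
}

#' Consolidate gap results by crop type
#'
#' Aggregates per-species gap records into one row per crop type: number of
#' crops and CWR, species-count breakdowns by record availability, the count
#' of species losing more than half their current distribution by 2070, and
#' mean protected-area cover and mean loss of protected cover. Species in
#' several genepools are counted once per crop type but may appear under
#' several types; species with `NA` loss (buffer pathway) are excluded from
#' loss means but still counted. Species present in `crop_map` but absent
#' from `records` (e.g. zero-record species never analyzed) contribute to the
#' `n_cwr` and `n_no_records` counts only.
#'
#' @param records A [gap_analysis()] table (needs `n_occurrences`; join a QC
#'   report or supply the column).
#' @param crop_map Tibble mapping species to crops: columns `species_id`,
#'   `crop`, `crop_type`.
#' @return Tibble with one row per crop type.
#' @export
summarize_by_crop_type <- function(records, crop_map) {
  stopifnot(all(c("species_id", "crop", "crop_type") %in% names(crop_map)))
  unmapped <- setdiff(records$species_id, crop_map$species_id)
  if (length(unmapped) > 0) {
    stop("species not mapped to any crop: ", paste(unmapped, collapse = ", "))
  }
  if (!"n_occurrences" %in% names(records)) {
    stop("records need an n_occurrences column (join the QC report)")
  }
  all_sp <- dplyr::left_join(crop_map, records, by = "species_id")
  all_sp$n_occurrences[is.na(all_sp$n_occurrences)] <- 0L
  all_sp |>
    dplyr::group_by(.data$crop_type) |>
    dplyr::summarise(
      n_crops = dplyr::n_distinct(.data$crop),
      n_cwr = dplyr::n_distinct(.data$species_id),
      n_no_records = dplyr::n_distinct(.data$species_id[.data$n_occurrences == 0]),
      n_records_1_9 = dplyr::n_distinct(
        .data$species_id[.data$n_occurrences >= 1 & .data$n_occurrences <= 9]
      ),
      n_loss_gt50 = dplyr::n_distinct(
        .data$species_id[!is.na(.data$pct_range_loss_2070) &
                           .data$pct_range_loss_2070 > 50]
      ),
      mean_pct_pa_cover = mean_over_species(
        .data$species_id, .data$pct_range_in_pa_current
      ),
      mean_pct_pa_cover_loss = mean_over_species(
        .data$species_id, .data$pct_pa_cover_loss_2070
      ),
      .groups = "drop"
    )
}

# internal: mean of a per-species value with genepool duplicates collapsed
mean_over_species <- function(species_id, value) {
  first <- !duplicated(species_id)
  v <- value[first]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Round half up
#'
#' Deterministic decimal rounding with halves away from zero, matching how
#' headline percentages are printed (base R's `round()` uses banker's
#' rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Headline percentage as printed in reports
#'
#' `100 * numerator / denominator`, rounded half-up to the requested number of
#' decimals (one by default; zero where reports print integers).
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param digits Decimal places (default 1).
#' @return A single numeric percentage.
#' @examples
#' headline_percentages(829, 1261) # 65.7
#' @export
headline_percentages <- function(numerator, denominator, digits = 1) {
  stopifnot(numerator >= 0, denominator >= 0)
  if (denominator == 0) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, digits)
}
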