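#' Configure an end-to-end pipeline run
#'
#' Collects every stage parameter with its study default in one structured
#' object: coordinate-uncertainty cutoff 10 km, modelling eligibility 10
#' unique records, 10,000 background points, 5 cross-validation folds, VIF
#' threshold 10, 50-km buffer fallback, the 50% scenario-coverage adequacy
#' rule, planning-unit costs 10/50, species penalty factor 1, boundary length
#' modifier 0.001, 100 annealing runs, and the 100 + 50 top-site split. Every
#' value is echoed into the run manifest for provenance. Unknown parameter
#' names are rejected.
#'
#' @param seed Root seed; each stage draws from a named substream of it.
#' @param ... Overrides of the defaults listed in the return value.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed,
    # synthetic world
    n_rows = 60, n_cols = 60, cell_size_km = 5,
    n_species = 20, pa_fraction = 0.15, native_fraction = 0.35,
    autocorr_length_km = 50, n_future_realizations = 5,
    future_shift = 0.5, future_realization_sd = 0.2, future_cell_sd = 0.1,
    # occurrence QC
    max_uncertainty_km = 10, min_records_for_model = 10,
    # distribution modelling
    n_background = 10000, k_folds = 5, vif_threshold = 10, buffer_km = 50,
    auc_min = 0.7, auc_sd_max = 0.15,
    # ELC
    k_elc = c(edaphic = 3, geophysical = 3, climatic = 3),
    # gap analysis
    adequacy_pct = 50,
    # reserve selection
    cost_pa = 10, cost_outside = 50, spf = 1, blm = 0.001,
    n_runs = 100, n_iterations = 10000,
    # prioritization
    top_pa = 100, top_out = 50
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  defaults$seed <- seed
  structure(defaults, class = "pipeline_config")
}

#' Run the full conservation-planning pipeline
#'
#' Executes simulate -> qc -> sdm -> elc -> gap -> select -> rank -> report on
#' a synthetic world (or a supplied one), returning every stage result and,
#' when `out_dir` is given, writing the declared file contracts: occurrence
#' and QC CSVs, per-species model cards, ELC category and codebook CSVs, the
#' species gap table and crop-type summary, reserve problem/solution CSVs,
#' ranked-site CSVs, and a JSON manifest echoing every parameter and seed.
#' Output bytes are a pure function of the configuration, so a rerun with the
#' same seed reproduces every file exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param world Optional pre-built [simulate_world()] world; by default one is
#'   simulated from `config`.
#' @param quiet Suppress per-stage progress messages (default TRUE).
#' @return A list of class `pipeline_result`: `world`, `qc`, `sdms`, `elcs`,
#'   `gap`, `crop_summary`, `problem`, `ensemble`, `ranking`, `sites`,
#'   `report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         world = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage simulate")
  if (is.null(world)) {
    cfg <- landscape_config(
      grid_spec(config$n_rows, config$n_cols, config$cell_size_km),
      autocorr_length_km = config$autocorr_length_km,
      future_shift = config$future_shift,
      future_realization_sd = config$future_realization_sd,
      future_cell_sd = config$future_cell_sd,
      n_future_realizations = config$n_future_realizations,
      seed = config$seed
    )
    world <- simulate_world(cfg, n_species = config$n_species,
                            pa_fraction = config$pa_fraction,
                            native_fraction = config$native_fraction)
  }
  grid <- world$grid

  say("stage qc")
  qc <- qc_clean(world$occurrences, world$native_ranges, grid,
                 max_uncertainty_km = config$max_uncertainty_km)
  qc$report$pathway <- assign_pathway(qc$report$final_unique,
                                      config$min_records_for_model)

  say("stage sdm")
  analyzed <- qc$report$species_id[qc$report$pathway != "excluded"]
  sdms <- lapply(analyzed, function(sp) {
    fit_species_sdm(
      qc$records[qc$records$species_id == sp, ],
      world$env, world$futures, world$native_ranges[[sp]], sp,
      n_background = config$n_background,
      min_records_for_model = config$min_records_for_model,
      vif_threshold = config$vif_threshold, k = config$k_folds,
      buffer_km = config$buffer_km, auc_min = config$auc_min,
      auc_sd_max = config$auc_sd_max,
      seed = substream(config$seed, 4000 + match(sp, analyzed))
    )
  })
  names(sdms) <- analyzed

  say("stage elc")
  # one collinearity screen over a uniform grid sample feeds every ELC map
  screen_cells <- sample_background(seq_len(n_cells(grid)), 5000,
                                    seed = substream(config$seed, 17))
  global_screen <- screen_vif(env_matrix(world$env, cells = screen_cells),
                              threshold = config$vif_threshold)
  vs <- env_var_sets(world$env)
  elc_vars <- lapply(
    stats::setNames(c("edaphic", "geophysical", "climatic"),
                    c("edaphic", "geophysical", "climatic")),
    function(s) intersect(global_screen$retained, vs$variable[vs$set == s])
  )
  elcs <- lapply(analyzed, function(sp) {
    build_elc(world$env, world$native_ranges[[sp]], k = config$k_elc,
              vars = elc_vars, species_id = sp,
              seed = substream(config$seed, 5000 + match(sp, analyzed)))
  })
  names(elcs) <- analyzed

  say("stage gap")
  gap <- gap_analysis(sdms, elcs, world$pa, report = qc$report)
  crop_summary <- summarize_by_crop_type(gap, world$crop_map)

  say("stage select")
  problem <- build_problem(sdms, elcs, world$pa, grid,
                           blm = config$blm, spf = config$spf,
                           cost_pa = config$cost_pa,
                           cost_outside = config$cost_outside)
  ensemble <- anneal(problem, n_runs = config$n_runs,
                     n_iter = config$n_iterations,
                     seed = substream(config$seed, 23))

  say("stage rank")
  best_units <- problem$units[problem$units$unit_id %in% ensemble$best$selected, ]
  inc_sp <- dplyr::left_join(
    problem$incidence,
    problem$combinations[, c("combination_id", "species_id")],
    by = "combination_id"
  )
  ranking <- greedy_rank(best_units, inc_sp, mode = "pragmatic")
  sites <- suppressWarnings(
    top_sites(ranking, n_pa = config$top_pa, n_out = config$top_out)
  )

  say("stage report")
  n_assessed <- length(analyzed)
  n_combos <- nrow(problem$combinations)
  report <- list(
    n_species = nrow(qc$report),
    n_excluded = sum(qc$report$pathway == "excluded"),
    n_assessed = n_assessed,
    pct_excluded = headline_percentages(
      sum(qc$report$pathway == "excluded"), nrow(qc$report)
    ),
    n_under_conserved = sum(gap$under_conserved, na.rm = TRUE),
    pct_well_represented = headline_percentages(
      sum(!gap$under_conserved & !is.na(gap$pct_scenarios_in_pa_current)),
      sum(!is.na(gap$pct_scenarios_in_pa_current)), digits = 0
    ),
    n_exclusively_outside = sum(gap$exclusively_outside, na.rm = TRUE),
    # the exclusively-outside share is reported against both plausible
    # denominators (all listed species vs assessed species)
    pct_exclusively_outside_all = headline_percentages(
      sum(gap$exclusively_outside, na.rm = TRUE), nrow(qc$report)
    ),
    pct_exclusively_outside_assessed = headline_percentages(
      sum(gap$exclusively_outside, na.rm = TRUE), n_assessed
    ),
    top_sites = headline_stats(sites$unit_id, inc_sp, n_assessed, n_combos),
    network = headline_stats(ranking$unit_id, inc_sp, n_assessed, n_combos)
  )

  result <- structure(
    list(world = world, qc = qc, sdms = sdms, elcs = elcs, gap = gap,
         crop_summary = crop_summary, problem = problem, ensemble = ensemble,
         ranking = ranking, sites = sites, report = report, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d species (%d assessed); reserve of %d units covering %d combination(s)\n",
    x$report$n_species, x$report$n_assessed, x$ensemble$best$n_units,
    max(c(0, x$ranking$cum_combos))
  ))
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' Emits the pipeline's file contracts under `out_dir`: `occurrences.csv`,
#' `qc_report.csv`, `model_cards.csv`, `elc_categories.csv`,
#' `elc_codebook.csv`, `gap_species.csv`, `gap_crop_types.csv`,
#' `reserve_units.csv`, `reserve_incidence.csv`, `reserve_runs.csv`,
#' `reserve_best.csv`, `site_ranking.csv`, `top_sites.csv`, `truth.csv`,
#' `env_layers.csv` (long format, the package's plain-text raster container),
#' `pa_mask.csv`, and `manifest.json` (parameters and seeds; no timestamps,
#' so identical configurations write identical bytes).
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name))

  w(result$world$occurrences, "occurrences.csv")
  w(result$world$truth, "truth.csv")
  env_long <- tidyr::pivot_longer(
    tibble::as_tibble(result$world$env),
    cols = -dplyr::all_of(c("cell_id", "row", "col", "x", "y")),
    names_to = "variable", values_to = "value"
  )
  w(env_long, "env_layers.csv")
  w(tibble::as_tibble(result$world$pa), "pa_mask.csv")
  w(result$qc$report, "qc_report.csv")
  w(dplyr::bind_rows(lapply(result$sdms, glance)), "model_cards.csv")
  w(dplyr::bind_rows(lapply(names(result$elcs), function(sp) {
    dplyr::mutate(tibble::as_tibble(result$elcs[[sp]]), species_id = sp)
  })), "elc_categories.csv")
  w(dplyr::bind_rows(lapply(names(result$elcs), function(sp) {
    dplyr::mutate(attr(result$elcs[[sp]], "codebook"), species_id = sp)
  })), "elc_codebook.csv")
  w(result$gap, "gap_species.csv")
  w(result$crop_summary, "gap_crop_types.csv")
  w(result$problem$units, "reserve_units.csv")
  w(result$problem$incidence, "reserve_incidence.csv")
  w(result$ensemble$summary, "reserve_runs.csv")
  w(tibble::tibble(unit_id = result$ensemble$best$selected), "reserve_best.csv")
  w(tibble::as_tibble(result$ranking), "site_ranking.csv")
  w(tibble::as_tibble(result$sites), "top_sites.csv")
  manifest <- c(
    unclass(result$config),
    list(
      report = result$report,
      n_units_best = result$ensemble$best$n_units,
      objective_best = result$ensemble$best$objective
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
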