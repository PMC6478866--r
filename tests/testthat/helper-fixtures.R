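# Shared fixtures, built in code and memoized for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# hand-built stack: explicit per-set values on a small grid (one variable per
# set unless more are supplied)
tiny_env <- function(grid, edaphic, geophysical = NULL, climatic = NULL) {
  n <- n_cells(grid)
  if (is.null(geophysical)) geophysical <- rep(0, n)
  if (is.null(climatic)) climatic <- rep(0, n)
  vals <- tibble::tibble(
    cell_id = seq_len(n),
    edaphic_01 = edaphic, geophysical_01 = geophysical, climatic_01 = climatic
  )
  env_stack(vals, grid, tibble::tibble(
    variable = c("edaphic_01", "geophysical_01", "climatic_01"),
    set = c("edaphic", "geophysical", "climatic")
  ))
}

# small default world shared across test files (40 x 40 grid, 12 species)
small_world <- function() {
  fixture("small_world", function() {
    cfg <- landscape_config(grid_spec(40, 40, 5), seed = 42)
    simulate_world(cfg, n_species = 12)
  })
}

# one well-sampled modelled species on the small world
small_sdm <- function() {
  fixture("small_sdm", function() {
    w <- small_world()
    sp <- w$truth$species_id[which(w$truth$n_records >= 300)[1]]
    qc <- qc_clean(w$occurrences[w$occurrences$species_id == sp, ],
                   w$native_ranges[sp], w$grid)
    list(
      world = w, species = sp, qc = qc,
      fit = fit_species_sdm(qc$records, w$env, w$futures,
                            w$native_ranges[[sp]], sp,
                            n_background = 2000, seed = 7)
    )
  })
}
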