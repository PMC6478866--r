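# cwrinsitu

Systematic in situ conservation planning for crop wild relatives (CWR) —
the wild cousins of cultivated crops that supply breeding programmes with
traits for yield, nutrition and climate tolerance, and that are chronically
under-conserved in the wild.

`cwrinsitu` implements the full analysis chain used in global CWR gap
analysis and reserve design as a reusable, testable R pipeline:

1. **Occurrence QC** — dedupe records, drop records without coordinates,
   outside the native range, or with coordinate uncertainty > 10 km; route
   each species to a modelling pathway (≥ 10 unique records), a 50-km
   circular-buffer fallback (1–9 records), or exclusion (0 records).
2. **Species distribution models** — a presence–background maximum-entropy
   (MaxEnt-type) model per species: the Gibbs distribution over 10,000
   background cells of the native range whose feature expectations match the
   presence feature means under an L1 penalty,

   `max_η  η·E_pres[f] − log E_bg[exp(η·f)] − β‖η‖₁`,

   with linear + quadratic features, variance-inflation-factor screening
   (VIF ≥ 10 removed) of the environmental predictors, 5-fold
   cross-validated adequacy checks, and binarization at the maximum training
   sensitivity plus specificity (MAXTRSS) threshold.
3. **Climate futures** — continuous projections onto an ensemble of future
   climate realizations are averaged cellwise and re-thresholded; the
   intersection of current and future ranges is the climate-stable range and
   `loss = 1 − |stable|/|current|`.
4. **Ecogeographic land characterization (ELC)** — per-species k-means
   clustering of the edaphic, geophysical and climatic variable sets,
   combined into composite categories ("adaptive scenarios"), the proxy for
   intraspecific genetic diversity.
5. **Gap analysis** — protected-area coverage of ranges and adaptive
   scenarios, climate-driven losses, the 50% scenario-coverage adequacy
   rule, and crop-type summary tables.
6. **Reserve selection** — a Marxan-style simulated-annealing minimum-set
   solver (unit cost 10 inside / 50 outside protected areas, species penalty
   factor 1, boundary length modifier 0.001, ≥ 1 unit per species×scenario
   combination), with runs ranked by fewest units then lowest cost.
7. **Prioritization** — greedy complementarity ranking of the chosen
   network's planning units, in adaptive or pragmatic (protected-areas
   first) mode, and top-site tables (100 sites inside + 50 outside
   protected areas by default).

A synthetic-landscape generator (`simulate_world()`) produces ground-truth
worlds — autocorrelated environmental stacks, known logistic niches, skewed
occurrence samples with injected QC defects, blob protected areas, shifted
future climates — so the entire pipeline is verifiable against known truth
without downloading occurrence, climate or protected-area databases.

## Worked example

```r
library(cwrinsitu)

cfg <- pipeline_config(seed = 11, n_rows = 50, n_cols = 50,
                       n_species = 15, n_runs = 25)
res <- run_pipeline(cfg)

res
#> <pipeline_result> 15 species (12 assessed); reserve of 100 units covering 188 combination(s)
res$qc
#> <qc_result> 15 species: 2947 records in, 2323 clean (9 model / 3 buffer / 3 excluded)
glance(res$ensemble)
#> # A tibble: 1 × 7
#>   n_runs n_units total_cost boundary penalty objective n_unmet
#> 1     25     100       4000      370       0     4000.       0
head(res$sites[, c("rank", "unit_id", "pa", "n_cwr", "n_new_cwr", "n_new_combos")], 3)
#>    rank unit_id    pa n_cwr n_new_cwr n_new_combos
#> 1     1     803     1     6         6            6
#> 2     2     744     1     4         2            4
#> 3     3     823     1     4         0            4
```

Reading: of 15 simulated species, 3 had no records and were excluded; 9 had
enough records for distribution models and 3 fell back to 50-km buffers.
The annealer found a 100-unit network (total unit cost 4000, no unmet
species×scenario targets). The greedy ranking then orders those units: the
top site contains 6 species and contributes 6 new species×scenario
combinations to the network; the per-species gap table
(`res$gap`) holds protected-area coverage and projected 2070 losses
(`NA` for buffer-pathway species, which carry no future model).

## Package layout

| Area | Functions |
| --- | --- |
| Grid & containers | `grid_spec()`, `grid_cells()`, `env_stack()`, `range_map()` |
| Synthetic worlds | `landscape_config()`, `generate_env_stack()`, `generate_future()`, `sample_occurrences()`, `generate_protected_areas()`, `simulate_world()`, `true_loss()` |
| Occurrence QC | `qc_clean()`, `assign_pathway()` |
| Distribution models | `screen_vif()`, `fit_maxent()`, `crossvalidate()`, `maxtrss_threshold()`, `binarize()`, `buffer_range()`, `future_ensemble()`, `stable_range()`, `fit_species_sdm()` |
| Genetic-diversity proxy | `build_elc()`, `scenarios_in_range()` |
| Gap analysis | `rasterize_pa()`, `coverage()`, `scenario_coverage()`, `scenario_loss()`, `gap_analysis()`, `summarize_by_crop_type()`, `headline_percentages()` |
| Reserve selection | `build_problem()`, `anneal()`, `rank_runs()`, `reserve_objective()` |
| Prioritization | `greedy_rank()`, `top_sites()`, `headline_stats()` |
| Pipeline | `pipeline_config()`, `run_pipeline()`, `write_pipeline_outputs()` |

See `vignettes/conservation-planning.Rmd` for the methods account: model
assumptions, parameter defaults and their rationale, what the synthetic
worlds do and do not emulate, and known limitations.
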