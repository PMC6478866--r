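test_that("environmental layers are standardized, seeded, and spatially structured", {
  g <- grid_spec(100, 100, 5)
  cfg <- landscape_config(g, seed = 3)
  env <- generate_env_stack(cfg)

  expect_equal(length(env_vars(env)), 27)
  expect_equal(as.vector(table(env_var_sets(env)$set)[c("edaphic", "geophysical", "climatic")]),
               c(9, 6, 12))
  m <- env_matrix(env)
  expect_true(all(abs(colMeans(m)) < 1e-8))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-8))

  # determinism: same config -> bit-identical stacks
  expect_identical(env_matrix(generate_env_stack(cfg)), m)

  # the 50-km correlation length shows up in the empirical variogram
  rng <- oracle_variogram_range(env$climatic_01, env[, c("x", "y")])
  expect_gt(rng, 50 * 0.7)
  expect_lt(rng, 50 * 1.3)
})

test_that("zero autocorrelation length yields independent cell values", {
  g <- grid_spec(100, 100, 5)
  env <- generate_env_stack(landscape_config(g, autocorr_length_km = 0, seed = 5))
  v <- matrix(env$edaphic_01[order(env$cell_id)], nrow = 100, byrow = TRUE)
  # lag-1 Moran-style autocorrelation in both grid directions
  r_row <- cor(as.vector(v[, -100]), as.vector(v[, -1]))
  r_col <- cor(as.vector(v[-100, ]), as.vector(v[-1, ]))
  expect_lt(abs(r_row), 0.05)
  expect_lt(abs(r_col), 0.05)
  expect_error(landscape_config(g, autocorr_length_km = -1), "non-negative")
})

test_that("future realizations shift climatic layers only, by the configured amount", {
  g <- grid_spec(50, 50, 5)
  cfg <- landscape_config(g, seed = 9, future_shift = 1,
                          future_realization_sd = 0, future_cell_sd = 0,
                          n_future_realizations = 3)
  env <- generate_env_stack(cfg)
  futs <- generate_future(env, cfg)
  expect_length(futs, 3)
  for (f in futs) {
    # edaphic/geophysical invariant across realizations
    expect_identical(f$edaphic_03, env$edaphic_03)
    expect_identical(f$geophysical_01, env$geophysical_01)
    expect_equal(mean(f$climatic_05) - mean(env$climatic_05), 1, tolerance = 1e-10)
  }

  # zero shift, zero noise -> futures identical to baseline
  cfg0 <- landscape_config(g, seed = 9, future_shift = 0,
                           future_realization_sd = 0, future_cell_sd = 0,
                           n_future_realizations = 2)
  f0 <- generate_future(env, cfg0)
  expect_equal(f0[[1]]$climatic_01, env$climatic_01)

  expect_error(generate_future(env, cfg, shift_vars = "edaphic_01"),
               "non-climatic")
})

test_that("occurrence sampling follows suitability and handles edge cases", {
  g <- grid_spec(10, 10, 5)
  env <- tiny_env(g, edaphic = rnorm(100), climatic = rnorm(100))
  nat <- 1:100

  # flat niche: counts consistent with a uniform multinomial
  flat <- true_niche("flat", c(climatic_01 = 0), intercept = 0)
  occ <- sample_occurrences(flat, env, 10000, nat, dup_fraction = 0,
                            outside_fraction = 0, uncertain_fraction = 0,
                            nocoord_fraction = 0, nontarget_fraction = 0,
                            seed = 2)
  counts <- table(factor(cell_at(g, occ$x, occ$y), levels = 1:100))
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # n = 0 -> typed empty set
  expect_equal(nrow(sample_occurrences(flat, env, 0, nat)), 0)

  # degenerate niche concentrated on one cell
  suit <- rep(0, 100)
  spike <- tiny_env(g, edaphic = rep(0, 100), climatic = c(50, rep(-50, 99)))
  sharp <- true_niche("sharp", c(climatic_01 = 1), intercept = 0)
  occ1 <- sample_occurrences(sharp, spike, 50, nat, dup_fraction = 0,
                             outside_fraction = 0, uncertain_fraction = 0,
                             nocoord_fraction = 0, nontarget_fraction = 0,
                             seed = 3)
  expect_true(all(cell_at(g, occ1$x, occ1$y) == 1))

  # all-zero suitability is impossible with a logistic niche; emulate by
  # restricting to cells where plogis underflows to 0
  frozen <- tiny_env(g, edaphic = rep(0, 100), climatic = rep(-5000, 100))
  expect_error(sample_occurrences(sharp, frozen, 5, nat), "zero")
})

test_that("protected-area blobs hit the target fraction and are seeded", {
  g <- grid_spec(200, 200, 5)
  pa <- generate_protected_areas(g, 0.15, seed = 4)
  frac <- mean(pa$protected)
  expect_gte(frac, 0.13)
  expect_lte(frac, 0.17)
  expect_identical(generate_protected_areas(g, 0.15, seed = 4)$protected,
                   pa$protected)

  expect_true(all(generate_protected_areas(g, 0)$protected == 0))
  expect_true(all(generate_protected_areas(g, 1)$protected == 1))
  expect_error(generate_protected_areas(g, 0.2, n_blobs = 0), "n_blobs")
})

test_that("true loss matches cell enumeration and its boundary cases", {
  g <- grid_spec(2, 2, 5)
  # suitability = plogis(value): cells 1,2 currently suitable
  base <- tiny_env(g, edaphic = rep(0, 4), climatic = c(5, 5, -5, -5))
  niche <- true_niche("sp", c(climatic_01 = 1), intercept = 0)

  expect_equal(true_loss(niche, base, base, 1:4), 0)

  gone <- tiny_env(g, edaphic = rep(0, 4), climatic = c(-5, -5, 5, 5))
  expect_equal(true_loss(niche, base, gone, 1:4), 1)

  half <- tiny_env(g, edaphic = rep(0, 4), climatic = c(5, -5, -5, -5))
  expect_equal(true_loss(niche, base, half, 1:4), 0.5)

  cold <- true_niche("none", c(climatic_01 = 1), intercept = -100)
  expect_error(true_loss(cold, base, base, 1:4), "empty")
})

test_that("a simulated world is internally consistent", {
  w <- small_world()
  expect_length(w$niches, 12)
  expect_equal(nrow(w$truth), 12)
  expect_true(all(w$truth$true_loss >= 0 & w$truth$true_loss <= 1, na.rm = TRUE))
  expect_true(abs(mean(w$pa$protected) - 0.15) <= 0.02)
  # clean base occurrences fall inside their native ranges
  for (sp in unique(w$occurrences$species_id)) {
    occ <- w$occurrences[w$occurrences$species_id == sp &
                           w$occurrences$source == "niche", ]
    cid <- cell_at(w$grid, occ$x, occ$y)
    expect_true(all(cid %in% w$native_ranges[[sp]]))
  }
  # every species is mapped to at least one crop
  expect_true(all(w$truth$species_id %in% w$crop_map$species_id))
})
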