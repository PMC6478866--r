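test_that("polygon rasterization follows the cell-centre rule", {
  g <- grid_spec(3, 3, 5)
  whole <- list(data.frame(x = c(-1, 16, 16, -1), y = c(-1, -1, 16, 16)))
  expect_true(all(rasterize_pa(whole, g)$protected == 1))

  # square covering exactly the centres of the lower-left 2 x 2 block
  four <- list(data.frame(x = c(1, 9, 9, 1), y = c(1, 1, 9, 9)))
  m4 <- rasterize_pa(four, g)
  expect_equal(m4$cell_id[m4$protected == 1], c(1, 2, 4, 5))

  # point-type geometries are dropped with a logged count
  expect_warning(
    pts <- rasterize_pa(list(data.frame(x = 1, y = 1),
                             data.frame(x = c(1, 2), y = c(1, 2))), g),
    "point-type"
  )
  expect_true(all(pts$protected == 0))
  expect_equal(attr(pts, "n_points_dropped"), 2)

  # a ready-made mask passes through
  mk <- rasterize_pa(data.frame(cell_id = 1:2, protected = 1), g)
  expect_equal(sum(mk$protected), 2)
})

test_that("coverage percentages count protected range cells", {
  g <- grid_spec(2, 5, 5)
  pa <- rasterize_pa(data.frame(cell_id = 1:3, protected = 1), g)
  r10 <- range_map(1:10, "sp", "current", "model", g)
  expect_equal(coverage(r10, pa), 30)

  all_pa <- rasterize_pa(data.frame(cell_id = 1:10, protected = 1), g)
  expect_equal(coverage(r10, all_pa), 100)

  outside <- range_map(4:10, "sp", "current", "model", g)
  expect_equal(coverage(outside, pa), 0)
  expect_true(is.na(coverage(integer(0), pa)))

  # complement identity: coverage under pa plus under its complement is 100
  not_pa <- pa
  not_pa$protected <- 1L - not_pa$protected
  set.seed(6)
  for (i in 1:10) {
    r <- sample(1:10, sample(1:10, 1))
    expect_equal(coverage(r, pa) + coverage(r, not_pa), 100)
  }

  # adding protected cells never decreases coverage
  bigger <- rasterize_pa(data.frame(cell_id = 1:5, protected = 1), g)
  expect_gte(coverage(r10, bigger), coverage(r10, pa))
})

test_that("scenario coverage and loss count category sets", {
  expect_equal(scenario_coverage(1:4, 1:4), 100)
  expect_equal(scenario_coverage(1:4, c(1, 3)), 50)
  expect_true(is.na(scenario_coverage(integer(0), 1:2)))

  expect_equal(scenario_loss(1:4, 1:4), 0)
  expect_equal(scenario_loss(1:4, c(2, 4)), 50)
  expect_true(is.na(scenario_loss(integer(0), integer(0))))
})

test_that("per-species gap records carry the 50% adequacy rule", {
  g <- grid_spec(4, 4, 5)
  env <- tiny_env(g, edaphic = rep(c(-1, 1), 8), geophysical = rnorm(16),
                  climatic = rep(c(-1, -1, 1, 1), 4))
  elc <- build_elc(env, 1:16, k = c(edaphic = 2, geophysical = 1, climatic = 2),
                   species_id = "sp1", seed = 1)
  pa <- rasterize_pa(data.frame(cell_id = 1:4, protected = 1), g)
  sdm_like <- list(
    species_id = "sp1", pathway = "model",
    current = range_map(1:8, "sp1", "current", "model", g),
    stable = range_map(1:4, "sp1", "stable", "model", g),
    loss = 0.5
  )
  gt <- gap_analysis(list(sp1 = sdm_like), list(sp1 = elc), pa)
  expect_equal(gt$pct_range_in_pa_current, 50)
  expect_equal(gt$pct_range_loss_2070, 50)
  expect_false(gt$exclusively_outside)
  # categories in rows 1-2 all occur within protected row 1
  expect_equal(gt$pct_scenarios_in_pa_current, 100)
  expect_false(gt$under_conserved)

  # a buffer-pathway species has null loss fields
  buf <- list(species_id = "sp2", pathway = "buffer",
              current = range_map(9:16, "sp2", "current", "buffer", g),
              stable = NULL, loss = NA_real_)
  gb <- gap_analysis(list(sp2 = buf), list(sp2 = elc), pa)
  expect_true(is.na(gb$pct_range_loss_2070))
  expect_true(is.na(gb$pct_scenario_loss_in_pa_2070))
  expect_equal(gb$pct_range_in_pa_current, 0)
  expect_true(gb$exclusively_outside)
  expect_true(gb$under_conserved)
})

test_that("crop-type summaries aggregate species once per type", {
  recs <- tibble::tibble(
    species_id = c("a", "b", "c", "d"),
    n_occurrences = c(20, 5, 300, 12),
    pathway = c("model", "buffer", "model", "model"),
    pct_range_in_pa_current = c(10, 20, 30, 40),
    pct_range_loss_2070 = c(60, NA, 20, 10),
    pct_pa_cover_loss_2070 = c(10, NA, 30, 20),
    pct_scenarios_in_pa_current = c(60, 40, 80, 90),
    pct_scenario_loss_in_pa_2070 = c(0, NA, 10, 5),
    exclusively_outside = FALSE, under_conserved = c(FALSE, TRUE, FALSE, FALSE)
  )
  crop_map <- tibble::tibble(
    species_id = c("a", "b", "c", "a", "d", "zero1"),
    crop = c("wheat", "wheat", "rye", "pea", "pea", "pea"),
    crop_type = c("cereals", "cereals", "cereals", "legumes", "legumes", "legumes")
  )
  s <- summarize_by_crop_type(recs, crop_map)
  cer <- s[s$crop_type == "cereals", ]
  expect_equal(cer$n_crops, 2)
  expect_equal(cer$n_cwr, 3)
  expect_equal(cer$n_records_1_9, 1)
  expect_equal(cer$n_loss_gt50, 1)
  expect_equal(cer$mean_pct_pa_cover, mean(c(10, 20, 30)))
  # species with NA loss excluded from the loss mean but still counted
  expect_equal(cer$mean_pct_pa_cover_loss, mean(c(10, 30)))

  leg <- s[s$crop_type == "legumes", ]
  expect_equal(leg$n_cwr, 3) # a, d, zero1
  expect_equal(leg$n_no_records, 1) # unanalyzed species counted as zero-record

  expect_error(
    summarize_by_crop_type(recs, crop_map[crop_map$species_id != "b", ]),
    "\\bb\\b"
  )
})

test_that("headline percentages round half-up at printed precision", {
  expect_equal(headline_percentages(829, 1261), 65.7)
  expect_equal(headline_percentages(164, 1425), 11.5)
  expect_equal(headline_percentages(0, 10), 0)
  expect_equal(headline_percentages(1, 16), 6.3) # 6.25 rounds up
  expect_equal(headline_percentages(1149, 1261, digits = 0), 91)
  expect_error(headline_percentages(1, 0), "positive")
  expect_equal(round_half_up(c(0.05, -0.05), 1), c(0.1, -0.1))
  expect_equal(round_half_up(2.5, 0), 3)
})
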