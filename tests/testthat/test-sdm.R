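test_that("VIF screening matches a least-squares oracle and handles edge cases", {
  set.seed(1)
  # exactly uncorrelated variables (principal component scores): nothing removed
  x <- stats::prcomp(matrix(rnorm(200 * 4), 200, 4))$x
  colnames(x) <- paste0("v", 1:4)
  s <- screen_vif(x)
  expect_equal(s$retained, paste0("v", 1:4))
  expect_true(all(abs(s$vif - 1) < 1e-6))

  # engineered collinearity: x3 = x1 + x2 + tiny noise goes first
  set.seed(2)
  x1 <- rnorm(100); x2 <- rnorm(100)
  xc <- cbind(x1 = x1, x2 = x2, x3 = x1 + x2 + rnorm(100, sd = 1e-6),
              x4 = rnorm(100))
  sc <- screen_vif(xc)
  expect_true(sc$removed$variable[1] %in% c("x1", "x2", "x3"))
  expect_true(all(sc$vif < 10))
  # agreement with the regression oracle
  o <- oracle_vif_screen(xc)
  expect_equal(sc$retained, o$retained)
  expect_equal(sc$removed$variable, o$removed)

  # single variable retained unconditionally with VIF defined as 1
  s1 <- screen_vif(matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "a")))
  expect_equal(s1$retained, "a")
  expect_equal(unname(s1$vif), 1)
})

test_that("VIF screening equals the oracle on random collinear instances", {
  for (i in 1:25) {
    set.seed(100 + i)
    n <- 120
    base <- matrix(rnorm(n * 4), n, 4)
    x <- cbind(
      base,
      base %*% rnorm(4) + rnorm(n, sd = runif(1, 0.05, 1)),
      base[, 1] * 0.9 + rnorm(n, sd = runif(1, 0.05, 1))
    )
    colnames(x) <- paste0("v", 1:6)
    s <- screen_vif(x)
    o <- oracle_vif_screen(x)
    expect_equal(s$retained, o$retained)
    expect_equal(s$removed$variable, o$removed)
  }
})

test_that("the maximum-entropy fit matches closed-form/grid-search behaviour", {
  # constant feature only: uniform suitability over the background
  bg <- matrix(1, nrow = 10, ncol = 1, dimnames = list(NULL, "v"))
  pres <- matrix(1, nrow = 5, ncol = 1, dimnames = list(NULL, "v"))
  m <- fit_maxent(pres, bg, beta = 0.01)
  expect_equal(var(predict(m, bg)), 0)

  # 2-cell world, one binary feature, all presences in cell A
  bg2 <- matrix(c(1, 0), ncol = 1, dimnames = list(NULL, "v"))
  presA <- matrix(1, nrow = 20, ncol = 1, dimnames = list(NULL, "v"))
  # near-zero penalty: probability concentrates on A
  m_free <- fit_maxent(presA, bg2, beta = 1e-4, max_iter = 20000)
  qA <- predict(m_free, bg2, type = "raw")[1]
  expect_gt(qA, 0.95)

  # finite penalty: weight matches a 1-D brute-force optimum on the same
  # standardized feature
  beta <- 0.2
  m_pen <- fit_maxent(presA, bg2, beta = beta, quadratic = FALSE)
  z <- c(1, -1) / sqrt(2) # background-standardized binary feature (sd of {0,1})
  obj <- function(eta) eta * z[1] - log(mean(exp(eta * z))) - beta * abs(eta)
  grid <- seq(-5, 5, by = 1e-4)
  eta_star <- grid[which.max(vapply(grid, obj, numeric(1)))]
  eta_fit <- sum(m_pen$eta) # single non-constant feature
  expect_equal(eta_fit, eta_star, tolerance = 1e-3)
})

test_that("fitted suitability recovers a known synthetic niche", {
  fs <- small_sdm()
  w <- fs$world
  expect_equal(fs$fit$pathway, "model")
  nat <- w$native_ranges[[fs$species]]
  suit_true <- niche_suitability(w$niches[[fs$species]], w$env, cells = nat)
  suit_fit <- predict(fs$fit$model, env_matrix(w$env, fs$fit$model$vars, cells = nat))
  expect_gte(cor(suit_true, suit_fit, method = "spearman"), 0.8)
})

test_that("cross-validation separates signal from noise and is seeded", {
  set.seed(3)
  # strongly separated toy: presences at high feature values
  bg <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "v"))
  pres <- matrix(rnorm(40, mean = 2.5), ncol = 1, dimnames = list(NULL, "v"))
  cv <- crossvalidate(pres, bg, k = 5, seed = 1)
  expect_gt(cv$mean_auc, 0.9)
  expect_true(all(cv$folds$converged))
  expect_true(cv$adequate)

  # pure noise: mean AUC near chance, inadequate
  pres_n <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "v"))
  cv_n <- crossvalidate(pres_n, bg, k = 5, seed = 1)
  expect_lt(abs(cv_n$mean_auc - 0.5), 0.15)
  expect_false(cv_n$adequate)

  # determinism of fold assignment
  expect_identical(crossvalidate(pres, bg, k = 5, seed = 9)$fold_assignment,
                   crossvalidate(pres, bg, k = 5, seed = 9)$fold_assignment)
  expect_error(crossvalidate(pres[1:3, , drop = FALSE], bg, k = 5), "exceeds")
})

test_that("MAXTRSS thresholding equals the exhaustive scan", {
  # separable case
  t1 <- maxtrss_threshold(c(0.9, 0.9), c(0.1, 0.1))
  expect_equal(t1$threshold, 0.9)
  expect_equal(t1$objective, 2)

  # the worked 3 + 3 example against the brute-force scan
  p <- c(0.2, 0.6, 0.8); b <- c(0.1, 0.3, 0.7)
  got <- maxtrss_threshold(p, b)
  want <- oracle_maxtrss(p, b)
  expect_equal(got$threshold, want$threshold)
  expect_equal(got$objective, want$objective)

  expect_error(maxtrss_threshold(c(0.5), numeric(0)), "non-empty")
  expect_warning(r <- maxtrss_threshold(c(0.4, 0.4), c(0.4)), "identical")
  expect_equal(r$threshold, 0.4)

  # random property check incl. tie rule (smallest threshold)
  for (i in 1:30) {
    set.seed(i)
    p <- round(runif(sample(1:40, 1)), 2)
    b <- round(runif(sample(1:40, 1)), 2)
    got <- maxtrss_threshold(p, b)
    want <- oracle_maxtrss(p, b)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$objective, want$objective, tolerance = 1e-12)
  }
})

test_that("binarization matches hand enumeration on a printed 3x3 grid", {
  g <- grid_spec(3, 3, 5)
  suit <- c(0.1, 0.5, 0.9, 0.4, 0.6, 0.2, 0.55, 0.5, 0.05)
  r <- binarize(suit, 1:9, 0.5, "sp", g)
  expect_equal(r$cell_id, c(2, 3, 5, 7, 8))
  expect_equal(nrow(binarize(suit, 1:9, 0, "sp", g)), 9)
  expect_warning(r0 <- binarize(suit, 1:9, 0.99, "sp", g), "empty")
  expect_equal(nrow(r0), 0)
})

test_that("circular buffers match the per-cell distance oracle", {
  g <- grid_spec(60, 60, 5)
  nat <- seq_len(n_cells(g))
  ctr <- cell_centres(g, nat)
  one <- tibble::tibble(x = 150, y = 150)
  b1 <- buffer_range(one, g, nat, radius_km = 50, species_id = "sp")
  # area of a 50-km disc in 25 km^2 cells
  expect_lt(abs(nrow(b1) - pi * 50^2 / 25), 0.05 * pi * 50^2 / 25)
  # oracle: explicit distance test per cell centre
  oracle <- nat[(ctr$x - 150)^2 + (ctr$y - 150)^2 <= 50^2]
  expect_equal(b1$cell_id, oracle)

  # coincident points add nothing
  two_same <- tibble::tibble(x = c(150, 150), y = c(150, 150))
  expect_equal(buffer_range(two_same, g, nat, 50, "sp")$cell_id, b1$cell_id)

  # overlapping discs: union strictly smaller than twice one disc
  two <- tibble::tibble(x = c(150, 180), y = c(150, 150))
  b2 <- buffer_range(two, g, nat, 50, "sp")
  expect_lt(nrow(b2), 2 * nrow(b1))
  expect_gt(nrow(b2), nrow(b1))

  expect_error(buffer_range(one[0, ], g, nat, 50, "sp"), "excluded")
})

test_that("future ensembling averages continuous projections before thresholding", {
  fs <- small_sdm()
  w <- fs$world
  nat <- w$native_ranges[[fs$species]]
  model <- fs$fit$model
  thr <- fs$fit$threshold

  # futures identical to baseline reproduce the current range
  fe <- future_ensemble(model, list(w$env, w$env), thr, nat, w$grid)
  expect_equal(fe$cell_id, fs$fit$current$cell_id)

  # manual mean of per-realization projections is the ensemble surface
  futs <- w$futures[1:2]
  proj <- sapply(futs, function(f) predict(model, env_matrix(f, model$vars, cells = nat)))
  manual <- binarize(rowMeans(proj), nat, thr, fs$species, w$grid,
                     epoch = "future_ensemble")
  auto <- future_ensemble(model, futs, thr, nat, w$grid)
  expect_equal(auto$cell_id, manual$cell_id)

  # single realization: ensemble is that projection
  single <- future_ensemble(model, futs[1], thr, nat, w$grid)
  expect_equal(single$cell_id,
               binarize(proj[, 1], nat, thr, fs$species, w$grid,
                        epoch = "future_ensemble")$cell_id)

  other_grid <- grid_spec(10, 10, 5)
  bad <- tiny_env(other_grid, edaphic = rnorm(100))
  expect_error(future_ensemble(model, list(bad), thr, nat, w$grid), "grid")
})

test_that("stable ranges are intersections with the right loss fraction", {
  g <- grid_spec(4, 4, 5)
  cur <- range_map(1:8, "sp", "current", "model", g)
  same <- range_map(1:8, "sp", "future_ensemble", "model", g)
  st <- stable_range(cur, same)
  expect_equal(st$loss, 0)
  expect_equal(st$stable$cell_id, 1:8)

  disjoint <- range_map(9:16, "sp", "future_ensemble", "model", g)
  expect_equal(stable_range(cur, disjoint)$loss, 1)

  half <- range_map(c(1:4, 9:12), "sp", "future_ensemble", "model", g)
  sh <- stable_range(cur, half)
  expect_equal(sh$loss, 0.5)
  expect_equal(sh$stable$cell_id, 1:4)
  expect_equal(attr(sh$stable, "epoch"), "stable")

  empty <- range_map(integer(0), "sp", "current", "model", g)
  expect_error(stable_range(empty, same), "empty")
})

test_that("range nesting invariants hold for modelled species", {
  fs <- small_sdm()
  f <- fs$fit
  nat <- fs$world$native_ranges[[fs$species]]
  expect_true(all(f$stable$cell_id %in% f$current$cell_id))
  expect_true(all(f$current$cell_id %in% nat))
  expect_true(all(f$future$cell_id %in% nat))
})
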