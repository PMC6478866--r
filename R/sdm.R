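#' Screen collinear variables by the variance inflation factor
#'
#' Iteratively removes the single variable with the highest VIF (recomputed
#' after every removal) until all remaining VIFs fall below the threshold.
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing variable `j`
#' on all other retained variables. Perfectly collinear variables have
#' infinite VIF and are removed first; among tied VIFs the variable latest in
#' input order is removed, so earlier variables are kept — a deterministic
#' tie-break. A single remaining variable has VIF defined as 1 and is always
#' retained.
#'
#' @param x Data frame or matrix of variable values (observations x variables),
#'   e.g. environmental layers sampled at background points.
#' @param threshold Removal threshold; variables with `VIF >= threshold` are
#'   candidates (default 10).
#' @return A list of class `vif_screen`: `retained` (character), `removed`
#'   (tibble `variable`, `vif`, `step` in removal order), `threshold`, and
#'   `vif` (named VIFs of the retained set).
#' @examples
#' x <- data.frame(a = rnorm(50), b = rnorm(50))
#' screen_vif(x)$retained
#' @export
screen_vif <- function(x, threshold = 10) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), ncol(x) >= 1, threshold > 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (nrow(x) <= ncol(x)) stop("need more observations than variables")
  vars <- colnames(x)
  removed <- list()
  step <- 0L
  while (length(vars) > 1) {
    vifs <- compute_vifs(x[, vars, drop = FALSE])
    if (max(vifs) < threshold) break
    worst <- max(which(vifs == max(vifs))) # ties: drop the latest in order
    step <- step + 1L
    removed[[step]] <- tibble::tibble(
      variable = vars[worst], vif = vifs[worst], step = step
    )
    vars <- vars[-worst]
  }
  final_vif <- if (length(vars) > 1) compute_vifs(x[, vars, drop = FALSE]) else {
    stats::setNames(1, vars)
  }
  structure(
    list(
      retained = vars,
      removed = if (step > 0) dplyr::bind_rows(removed) else
        tibble::tibble(variable = character(), vif = numeric(), step = integer()),
      threshold = threshold,
      vif = final_vif
    ),
    class = "vif_screen"
  )
}

# internal: VIF of every column of a numeric matrix (>= 2 columns)
compute_vifs <- function(m) {
  p <- ncol(m)
  vifs <- numeric(p)
  for (j in seq_len(p)) {
    y <- m[, j]
    X <- cbind(1, m[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) {
      vifs[j] <- Inf # constant column: degenerate, flag for removal
    } else {
      r2 <- 1 - rss / tss
      vifs[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  stats::setNames(vifs, colnames(m))
}

#' @export
print.vif_screen <- function(x, ...) {
  cat(sprintf(
    "<vif_screen> retained %d variable(s) (threshold %g); removed %d\n",
    length(x$retained), x$threshold, nrow(x$removed)
  ))
  invisible(x)
}

#' Sample background cells from a native-range mask
#'
#' Uniform sample without replacement of cells from the species' native range,
#' used as the background ("pseudo-absence") domain of the presence-background
#' model. Capped at the number of available cells.
#'
#' @param native_cells Integer vector of native-range cell ids.
#' @param n Target number of background cells (default 10000).
#' @param seed Integer seed.
#' @return Integer vector of background cell ids.
#' @export
sample_background <- function(native_cells, n = 10000, seed = 1) {
  stopifnot(length(native_cells) >= 1, n >= 1)
  with_seed(seed, {
    if (length(native_cells) <= n) {
      sort(as.integer(native_cells))
    } else {
      sort(sample(as.integer(native_cells), n))
    }
  })
}

# internal: linear + quadratic feature expansion, standardized against the
# background sample. Returns list(fun, names): fun maps a raw variable matrix
# to the feature matrix.
make_feature_transform <- function(bg_raw, quadratic = TRUE) {
  mu <- colMeans(bg_raw)
  sd0 <- apply(bg_raw, 2, stats::sd)
  sd0[sd0 == 0] <- 1
  build <- function(raw) {
    z <- sweep(sweep(raw, 2, mu), 2, sd0, "/")
    if (quadratic) cbind(z, z^2) else z
  }
  f_bg <- build(bg_raw)
  f_mu <- colMeans(f_bg)
  f_sd <- apply(f_bg, 2, stats::sd)
  f_sd[f_sd == 0] <- 1
  nm <- c(colnames(bg_raw), if (quadratic) paste0(colnames(bg_raw), "^2"))
  list(
    fun = function(raw) {
      f <- sweep(sweep(build(raw), 2, f_mu), 2, f_sd, "/")
      colnames(f) <- nm
      f
    },
    names = nm
  )
}

#' Fit a presence-background maximum-entropy niche model
#'
#' Fits the Gibbs distribution over background cells whose feature
#' expectations match the presence feature means under an L1 penalty: the
#' convex problem `max_eta eta . m_pres - log mean_bg exp(F eta) - beta ||eta||_1`,
#' solved by proximal gradient descent with backtracking. Features are linear
#' plus quadratic terms of the supplied variables, standardized against the
#' background sample. Suitability is reported on the logistic scale
#' `exp(H) q(x) / (1 + exp(H) q(x))` where `q` is the normalized Gibbs density
#' and `H` its entropy over the background, so values lie in (0, 1).
#'
#' @param presence Data frame/matrix of variable values at presence records.
#' @param background Data frame/matrix of variable values at background cells
#'   (defines the model's domain).
#' @param beta L1 regularization strength; default `sqrt(log(p) / n_presence)`
#'   where `p` is the feature count.
#' @param quadratic Include quadratic features (default TRUE).
#' @param max_iter,tol Optimizer budget and stationarity tolerance (KKT
#'   residual norm; default 1e-6).
#' @param species_id Optional species label stored on the model.
#' @return An object of class `maxent_model` with elements `eta` (feature
#'   weights), `beta`, `converged`, `n_iter`, `logZ`, `entropy`, and the
#'   feature transform used for prediction.
#' @export
fit_maxent <- function(presence, background, beta = NULL, quadratic = TRUE,
                       max_iter = 2000, tol = 1e-6, species_id = NA_character_) {
  pres_raw <- as.matrix(presence)
  bg_raw <- as.matrix(background)
  stopifnot(ncol(pres_raw) == ncol(bg_raw), nrow(bg_raw) >= 1, nrow(pres_raw) >= 1)
  if (!all(is.finite(pres_raw)) || !all(is.finite(bg_raw))) {
    stop("features must be finite")
  }
  if (is.null(colnames(bg_raw))) {
    colnames(bg_raw) <- colnames(pres_raw) <- paste0("v", seq_len(ncol(bg_raw)))
  }
  tr <- make_feature_transform(bg_raw, quadratic = quadratic)
  Fb <- tr$fun(bg_raw)
  Fp <- tr$fun(pres_raw)
  m_pres <- colMeans(Fp)
  p <- ncol(Fb)
  if (is.null(beta)) beta <- sqrt(log(max(p, 2)) / nrow(Fp))

  # negative objective: f(eta) = log mean exp(Fb eta) - eta.m_pres  (+ beta|eta|)
  neg_ll <- function(lp) {
    mx <- max(lp)
    mx + log(mean(exp(lp - mx)))
  }
  eta <- numeric(p)
  lp <- drop(Fb %*% eta)
  fval <- neg_ll(lp) - sum(eta * m_pres)
  step_size <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    grad <- drop(crossprod(Fb, w)) - m_pres
    # KKT residual of the penalized problem
    kkt <- ifelse(eta == 0, pmax(abs(grad) - beta, 0), grad + beta * sign(eta))
    if (sqrt(sum(kkt^2)) < tol) {
      converged <- TRUE
      break
    }
    repeat {
      cand <- eta - step_size * grad
      cand <- sign(cand) * pmax(abs(cand) - step_size * beta, 0) # soft threshold
      lp_c <- drop(Fb %*% cand)
      f_c <- neg_ll(lp_c) - sum(cand * m_pres)
      d <- cand - eta
      if (f_c <= fval + sum(grad * d) + sum(d^2) / (2 * step_size) + 1e-12) break
      step_size <- step_size / 2
      if (step_size < 1e-12) break
    }
    if (max(abs(cand - eta)) == 0 && step_size < 1e-12) break
    eta <- cand
    lp <- lp_c
    fval <- f_c
    step_size <- min(step_size * 1.3, 10)
  }
  if (!converged) {
    warning("maxent optimizer did not reach stationarity tolerance; model flagged")
  }
  lZ <- neg_ll(lp) # log mean_bg exp(lp)
  q <- exp(lp - lZ) / nrow(Fb) # Gibbs density over background, sums to 1
  H <- -sum(q * log(pmax(q, 1e-300)))
  structure(
    list(
      species_id = species_id,
      eta = stats::setNames(eta, tr$names),
      beta = beta, converged = converged, n_iter = iter,
      logZ = lZ, entropy = H, n_background = nrow(Fb), n_presence = nrow(Fp),
      transform = tr$fun, vars = colnames(bg_raw), quadratic = quadratic
    ),
    class = "maxent_model"
  )
}

#' Predict suitability from a fitted niche model
#' @param object A [fit_maxent()] model.
#' @param newdata Data frame/matrix of variable values (same columns the model
#'   was fitted on).
#' @param type `"logistic"` (default, in (0,1)) or `"raw"` (Gibbs density
#'   relative to the background normalization).
#' @param ... Unused.
#' @return Numeric suitability vector.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  raw <- as.matrix(newdata)[, object$vars, drop = FALSE]
  f <- object$transform(raw)
  lp <- drop(f %*% object$eta)
  q <- exp(lp - object$logZ) / object$n_background
  if (type == "raw") return(q)
  eq <- exp(object$entropy) * q
  eq / (1 + eq)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %s: %d features (%d nonzero), beta %.4g, %s in %d iters\n",
    x$species_id, length(x$eta), sum(x$eta != 0), x$beta,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted niche model
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `term`, `estimate`.
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(term = names(x$eta), estimate = unname(x$eta))
}

#' One-row model summary
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with fit diagnostics.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id, n_presence = x$n_presence,
    n_background = x$n_background, n_features = length(x$eta),
    n_nonzero = sum(x$eta != 0), beta = x$beta,
    entropy = x$entropy, converged = x$converged, n_iter = x$n_iter
  )
}

# internal: area under the ROC curve by rank statistic
auc_score <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validate a niche model and flag adequacy
#'
#' Presences are assigned to `k` random folds (seeded); for each fold the
#' model is refitted on the remaining presences against the full background
#' and scored by AUC of held-out presences vs background cells as
#' pseudo-absences. The model is adequate when the mean test AUC reaches
#' `auc_min`, the fold sd stays within `auc_sd_max` (the configurable
#' stand-in for standard model-adequacy criteria), and every fold's optimizer
#' converged.
#'
#' @param presence,background Variable values as in [fit_maxent()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param auc_min,auc_sd_max Adequacy cutoffs (defaults 0.7 and 0.15).
#' @param ... Passed to [fit_maxent()].
#' @return A list of class `sdm_cv`: `folds` (tibble `fold`, `n_test`, `auc`),
#'   `mean_auc`, `sd_auc`, `adequate`, `fold_assignment`.
#' @export
crossvalidate <- function(presence, background, k = 5, seed = 1,
                          auc_min = 0.7, auc_sd_max = 0.15, ...) {
  pres <- as.matrix(presence)
  n <- nrow(pres)
  if (k > n) stop("k exceeds the number of presences")
  assignment <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  res <- lapply(seq_len(k), function(f) {
    fit <- fit_maxent(pres[assignment != f, , drop = FALSE], background, ...)
    list(
      auc = auc_score(
        predict(fit, pres[assignment == f, , drop = FALSE]),
        predict(fit, background)
      ),
      converged = fit$converged
    )
  })
  aucs <- vapply(res, `[[`, numeric(1), "auc")
  converged <- vapply(res, `[[`, logical(1), "converged")
  folds <- tibble::tibble(
    fold = seq_len(k), n_test = tabulate(assignment, k), auc = aucs,
    converged = converged
  )
  mean_auc <- mean(aucs)
  sd_auc <- stats::sd(aucs)
  structure(
    list(
      folds = folds, mean_auc = mean_auc, sd_auc = sd_auc,
      adequate = (mean_auc >= auc_min) && (sd_auc <= auc_sd_max) &&
        all(converged),
      fold_assignment = assignment
    ),
    class = "sdm_cv"
  )
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Scans every observed score as a candidate threshold and returns the one
#' maximizing sensitivity (fraction of presences scored at or above `t`) plus
#' specificity (fraction of background scored below `t`), breaking ties toward
#' the smallest threshold (the largest, most conservative range).
#'
#' @param presence_scores,background_scores Numeric suitability scores in
#'   [0, 1]; both non-empty.
#' @return A list of class `maxtrss`: `threshold`, `sensitivity`,
#'   `specificity`, `objective`.
#' @examples
#' maxtrss_threshold(c(0.8, 0.9), c(0.1, 0.2))$threshold
#' @export
maxtrss_threshold <- function(presence_scores, background_scores) {
  p <- presence_scores
  b <- background_scores
  if (length(p) == 0 || length(b) == 0) stop("both score sets must be non-empty")
  if (any(p < 0) || any(p > 1) || any(b < 0) || any(b > 1)) {
    stop("scores must lie in [0, 1]")
  }
  cand <- sort(unique(c(p, b)))
  if (length(cand) == 1) {
    warning("all scores identical; threshold degenerate")
    return(structure(
      list(threshold = cand, sensitivity = 1, specificity = 0, objective = 1),
      class = "maxtrss"
    ))
  }
  # suffix counts: number of scores >= each ascending candidate
  cnt_p <- tabulate(match(p, cand), length(cand))
  cnt_b <- tabulate(match(b, cand), length(cand))
  ge_p <- rev(cumsum(rev(cnt_p)))
  ge_b <- rev(cumsum(rev(cnt_b)))
  sens <- ge_p / length(p)
  spec <- (length(b) - ge_b) / length(b)
  obj <- sens + spec
  best <- which.max(obj) # first index = smallest candidate on ties
  structure(
    list(
      threshold = cand[best], sensitivity = sens[best],
      specificity = spec[best], objective = obj[best]
    ),
    class = "maxtrss"
  )
}

#' Binarize continuous suitability into a range map
#'
#' A cell enters the range iff its suitability is at or above the threshold;
#' the domain is the background extent (the species' native range).
#'
#' @param scores Numeric suitability for each cell of `cells`.
#' @param cells Integer cell ids the scores refer to.
#' @param threshold MAXTRSS threshold `t*`.
#' @param species_id Species label.
#' @param grid The [grid_spec()].
#' @param epoch Epoch label for the resulting [range_map()].
#' @return A [range_map()] with origin `"model"`.
#' @export
binarize <- function(scores, cells, threshold, species_id, grid, epoch = "current") {
  stopifnot(length(scores) == length(cells))
  keep <- cells[scores >= threshold]
  if (length(keep) == 0) warning("threshold above all suitabilities: empty range")
  range_map(keep, species_id, epoch = epoch, origin = "model", grid = grid)
}

#' Circular buffer range around occurrence records
#'
#' The fallback distribution for species that cannot be modelled (fewer than
#' 10 unique records, or an inadequate model): the union of discs of
#' `radius_km` around each record, rasterized by the cell-centre rule and
#' clipped to the native range.
#'
#' @param occurrences Data frame with point coordinates `x`, `y` (km) of the
#'   species' cleaned records.
#' @param grid The [grid_spec()].
#' @param native_cells Native-range cell ids (clip extent).
#' @param radius_km Buffer radius (default 50).
#' @param species_id Species label.
#' @return A [range_map()] with origin `"buffer"`, epoch `"current"`.
#' @export
buffer_range <- function(occurrences, grid, native_cells, radius_km = 50,
                         species_id = NA_character_) {
  if (nrow(occurrences) == 0) stop("no occurrence records: species is excluded")
  ctr <- cell_centres(grid, native_cells)
  r2 <- radius_km^2
  within <- rep(FALSE, nrow(ctr))
  for (i in seq_len(nrow(occurrences))) {
    within <- within |
      ((ctr$x - occurrences$x[i])^2 + (ctr$y - occurrences$y[i])^2 <= r2)
  }
  range_map(native_cells[within], species_id, epoch = "current",
            origin = "buffer", grid = grid)
}

#' Project a model onto future realizations and ensemble
#'
#' Continuous suitability is projected onto each future stack, averaged
#' cellwise across realizations, and binarized at the current model's MAXTRSS
#' threshold.
#'
#' @param model A fitted [fit_maxent()] model.
#' @param futures Non-empty list of future [env_stack()]s.
#' @param threshold The current model's `t*`.
#' @param cells Cell ids of the model's domain (native range / background
#'   extent).
#' @param grid The [grid_spec()].
#' @return A [range_map()] with epoch `"future_ensemble"`.
#' @export
future_ensemble <- function(model, futures, threshold, cells, grid) {
  stopifnot(length(futures) >= 1)
  for (f in futures) {
    if (!identical(attr(f, "grid"), grid)) stop("future stack on a different grid")
  }
  acc <- numeric(length(cells))
  for (f in futures) {
    acc <- acc + predict(model, env_matrix(f, model$vars, cells = cells))
  }
  binarize(acc / length(futures), cells, threshold, model$species_id, grid,
           epoch = "future_ensemble")
}

#' Climate-stable range and loss fraction
#'
#' Cells suitable in both the current and the future-ensemble range; the
#' complement of the loss fraction `1 - |stable| / |current|`.
#'
#' @param current,future [range_map()]s of the same species on the same grid.
#' @return A list: `stable` ([range_map()], epoch `"stable"`), `loss` in [0, 1].
#' @export
stable_range <- function(current, future) {
  stopifnot(inherits(current, "range_map"), inherits(future, "range_map"))
  if (!identical(attr(current, "grid"), attr(future, "grid"))) {
    stop("range maps on different grids")
  }
  if (nrow(current) == 0) stop("current range is empty")
  stable_cells <- intersect(current$cell_id, future$cell_id)
  list(
    stable = range_map(stable_cells, attr(current, "species_id"),
                       epoch = "stable", origin = attr(current, "origin"),
                       grid = attr(current, "grid")),
    loss = 1 - length(stable_cells) / nrow(current)
  )
}

#' Run the full distribution-modelling pathway for one species
#'
#' Convenience driver used by the pipeline: samples background, screens
#' variables by VIF, fits and cross-validates the niche model, applies the
#' MAXTRSS threshold, and either binarizes the model (adequate) or falls back
#' to the 50-km occurrence buffer (inadequate or fewer than
#' `min_records_for_model` unique records). Adequate models are projected onto
#' the future realizations, ensembled, and intersected into a climate-stable
#' range; buffer-pathway species are treated as climate-invariant and carry no
#' future or stable epoch (their loss is `NA`).
#'
#' @param occurrences Cleaned records for one species (`x`, `y` in km).
#' @param env Baseline [env_stack()].
#' @param futures List of future [env_stack()]s (possibly empty).
#' @param native_cells Native-range cell ids.
#' @param species_id Species label.
#' @param n_background Background sample size (default 10000).
#' @param min_records_for_model Modelling eligibility cutoff (default 10).
#' @param vif_threshold VIF removal threshold (default 10).
#' @param k Cross-validation folds (default 5).
#' @param buffer_km Buffer radius for the fallback pathway (default 50).
#' @param auc_min,auc_sd_max Adequacy cutoffs (defaults 0.7, 0.15).
#' @param seed Integer seed (background sample, folds).
#' @return A list of class `species_sdm`: `species_id`, `pathway`
#'   (`"model"`/`"buffer"`), `model` (or NULL), `cv`, `screen`, `threshold`,
#'   `current`, `future` (or NULL), `stable` (or NULL), `loss` (or `NA`).
#' @export
fit_species_sdm <- function(occurrences, env, futures, native_cells, species_id,
                            n_background = 10000, min_records_for_model = 10,
                            vif_threshold = 10, k = 5, buffer_km = 50,
                            auc_min = 0.7, auc_sd_max = 0.15, seed = 1) {
  grid <- attr(env, "grid")
  res <- list(species_id = species_id, model = NULL, cv = NULL, screen = NULL,
              threshold = NA_real_, future = NULL, stable = NULL,
              loss = NA_real_)
  n_rec <- nrow(occurrences)
  use_model <- n_rec >= min_records_for_model
  if (use_model) {
    bg_cells <- sample_background(native_cells, n_background,
                                  seed = substream(seed, 1))
    bg_vals <- env_matrix(env, cells = bg_cells)
    screen <- screen_vif(bg_vals, threshold = vif_threshold)
    occ_cells <- cell_at(grid, occurrences$x, occurrences$y)
    pres_vals <- env_matrix(env, screen$retained, cells = occ_cells)
    bg_ret <- bg_vals[, screen$retained, drop = FALSE]
    cv <- crossvalidate(pres_vals, bg_ret, k = min(k, n_rec),
                        seed = substream(seed, 2),
                        auc_min = auc_min, auc_sd_max = auc_sd_max)
    if (cv$adequate) {
      model <- fit_maxent(pres_vals, bg_ret, species_id = species_id)
      nat_vals <- env_matrix(env, screen$retained, cells = native_cells)
      suit <- predict(model, nat_vals)
      thr <- maxtrss_threshold(predict(model, pres_vals), predict(model, bg_ret))
      res$model <- model
      res$cv <- cv
      res$screen <- screen
      res$threshold <- thr$threshold
      res$pathway <- "model"
      res$current <- binarize(suit, native_cells, thr$threshold, species_id, grid)
      if (length(futures) > 0) {
        res$future <- future_ensemble(model, futures, thr$threshold,
                                      native_cells, grid)
        st <- stable_range(res$current, res$future)
        res$stable <- st$stable
        res$loss <- st$loss
      }
      return(structure(res, class = "species_sdm"))
    }
    res$cv <- cv
    res$screen <- screen
  }
  res$pathway <- "buffer"
  res$current <- buffer_range(occurrences, grid, native_cells,
                              radius_km = buffer_km, species_id = species_id)
  structure(res, class = "species_sdm")
}

#' @export
print.species_sdm <- function(x, ...) {
  cat(sprintf(
    "<species_sdm> %s [%s]: current %d cells%s\n",
    x$species_id, x$pathway, nrow(x$current),
    if (!is.na(x$loss)) sprintf(", loss %.2f", x$loss) else ""
  ))
  invisible(x)
}

#' @rdname glance.maxent_model
#' @export
glance.species_sdm <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id, pathway = x$pathway,
    adequate = if (is.null(x$cv)) NA else x$cv$adequate,
    mean_cv_auc = if (is.null(x$cv)) NA_real_ else x$cv$mean_auc,
    sd_cv_auc = if (is.null(x$cv)) NA_real_ else x$cv$sd_auc,
    threshold = x$threshold,
    n_current = nrow(x$current),
    n_stable = if (is.null(x$stable)) NA_integer_ else nrow(x$stable),
    loss = x$loss
  )
}
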