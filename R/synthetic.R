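#' Configure a synthetic landscape
#'
#' The synthetic-landscape generator builds ground-truth worlds with the
#' statistical structure the downstream analysis assumes: spatially
#' autocorrelated standardized environmental layers in three named sets,
#' species presences drawn from known logistic niches, blob-shaped protected
#' areas, and future climates as shifted/perturbed climatic layers. Defaults
#' mirror the study conditions: 27 variables split 9 edaphic / 6 geophysical /
#' 12 climatic on a 5-km grid.
#'
#' @param grid A [grid_spec()].
#' @param n_vars Named integer vector with entries `edaphic`, `geophysical`,
#'   `climatic` giving the number of layers per set (default `c(9, 6, 12)`).
#' @param autocorr_length_km Practical correlation range of each layer in km
#'   (distance at which spatial correlation decays to 0.05). `0` gives
#'   independent cell values. Default 50.
#' @param future_shift Mean shift (in layer sd units) applied to every
#'   climatic layer in future realizations. Default 0.5.
#' @param future_realization_sd Sd of the per-realization mean shift around
#'   `future_shift` (emulates disagreement among circulation models). Default 0.2.
#' @param future_cell_sd Sd of cellwise noise added per realization. Default 0.1.
#' @param n_future_realizations Number of future realizations (default 5; the
#'   global study averaged 30 circulation models).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(grid,
                             n_vars = c(edaphic = 9, geophysical = 6, climatic = 12),
                             autocorr_length_km = 50,
                             future_shift = 0.5,
                             future_realization_sd = 0.2,
                             future_cell_sd = 0.1,
                             n_future_realizations = 5,
                             seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!setequal(names(n_vars), c("edaphic", "geophysical", "climatic"))) {
    stop("n_vars must be named exactly {edaphic, geophysical, climatic}")
  }
  if (autocorr_length_km < 0) stop("autocorr_length_km must be non-negative")
  stopifnot(n_future_realizations >= 0, future_realization_sd >= 0, future_cell_sd >= 0)
  structure(
    list(
      grid = grid, n_vars = n_vars,
      autocorr_length_km = autocorr_length_km,
      future_shift = future_shift,
      future_realization_sd = future_realization_sd,
      future_cell_sd = future_cell_sd,
      n_future_realizations = as.integer(n_future_realizations),
      seed = seed
    ),
    class = "landscape_config"
  )
}

# internal: one standardized Gaussian random field as a vector in cell_id order.
# White noise is smoothed by circular FFT convolution with a Gaussian kernel
# whose sd is chosen so the field's correlation falls to 0.05 at `length_km`
# (the practical variogram range).
gaussian_field <- function(grid, length_km) {
  nr <- grid$n_rows
  nc <- grid$n_cols
  noise <- matrix(stats::rnorm(nr * nc), nrow = nr, ncol = nc)
  if (length_km > 0) {
    sigma <- length_km / (2 * sqrt(log(20)))
    dx <- pmin(0:(nc - 1), nc - (0:(nc - 1))) * grid$cell_size_km
    dy <- pmin(0:(nr - 1), nr - (0:(nr - 1))) * grid$cell_size_km
    kern <- exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma^2))
    f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
  } else {
    f <- noise
  }
  v <- as.vector(t(f)) # row-major -> cell_id order
  as.vector(scale(v))
}

#' Generate a baseline environmental stack
#'
#' One standardized (mean 0, sd 1) spatially autocorrelated layer per
#' configured variable; deterministic given the config seed.
#'
#' @param config A [landscape_config()].
#' @return An [env_stack()] with epoch `"baseline"`.
#' @examples
#' cfg <- landscape_config(grid_spec(20, 20), seed = 1)
#' env <- generate_env_stack(cfg)
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  grid <- config$grid
  sets <- c("edaphic", "geophysical", "climatic")
  vars <- unlist(lapply(sets, function(s) {
    k <- config$n_vars[[s]]
    if (k == 0) character(0) else sprintf("%s_%02d", s, seq_len(k))
  }))
  var_sets <- tibble::tibble(
    variable = vars,
    set = rep(sets, times = config$n_vars[sets])
  )
  vals <- with_seed(config$seed, {
    m <- vapply(
      seq_along(vars),
      function(i) gaussian_field(grid, config$autocorr_length_km),
      numeric(n_cells(grid))
    )
    colnames(m) <- vars
    m
  })
  out <- tibble::as_tibble(as.data.frame(vals))
  out$cell_id <- seq_len(n_cells(grid))
  env_stack(out, grid, var_sets, epoch = "baseline")
}

#' Generate future climate realizations
#'
#' Each realization shifts every named climatic layer by a realization-level
#' mean (drawn around the configured shift) plus cellwise noise; edaphic and
#' geophysical layers are carried through unchanged.
#'
#' @param env Baseline [env_stack()].
#' @param config A [landscape_config()] (shift magnitudes, realization count).
#' @param shift_vars Variables to shift; must all be climatic. Default: every
#'   climatic variable.
#' @return Named list of [env_stack()]s (`future_01`, ...).
#' @export
generate_future <- function(env, config, shift_vars = env_vars(env, "climatic")) {
  stopifnot(inherits(env, "env_stack"), inherits(config, "landscape_config"))
  non_clim <- setdiff(shift_vars, env_vars(env, "climatic"))
  if (length(non_clim) > 0) {
    stop("shift requested on non-climatic layer(s): ", paste(non_clim, collapse = ", "))
  }
  grid <- attr(env, "grid")
  vs <- attr(env, "var_sets")
  n_real <- config$n_future_realizations
  with_seed(substream(config$seed, 101), {
    futures <- lapply(seq_len(n_real), function(r) {
      vals <- tibble::as_tibble(env)[, c("cell_id", vs$variable)]
      for (v in shift_vars) {
        delta <- stats::rnorm(1, config$future_shift, config$future_realization_sd)
        vals[[v]] <- vals[[v]] + delta +
          stats::rnorm(nrow(vals), 0, config$future_cell_sd)
      }
      env_stack(vals, grid, vs, epoch = sprintf("future_%02d", r))
    })
    names(futures) <- sprintf("future_%02d", seq_len(n_real))
    futures
  })
}

#' Define a true species niche
#'
#' Ground-truth suitability is `plogis(intercept + sum(coef * variable))`;
#' the true range is the set of native-range cells with suitability at or
#' above the threshold `s_star`.
#'
#' @param species_id Species identifier.
#' @param coefficients Named numeric vector of variable coefficients.
#' @param intercept Intercept on the logit scale.
#' @param s_star Suitability threshold defining the true range (default 0.5).
#' @return A list of class `true_niche`.
#' @export
true_niche <- function(species_id, coefficients, intercept, s_star = 0.5) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            s_star > 0, s_star < 1)
  structure(
    list(species_id = species_id, coefficients = coefficients,
         intercept = intercept, s_star = s_star),
    class = "true_niche"
  )
}

#' True suitability of a niche over a stack
#' @param niche A [true_niche()].
#' @param env An [env_stack()].
#' @param cells Optional cell ids to restrict to.
#' @return Numeric suitability vector in (0, 1).
#' @export
niche_suitability <- function(niche, env, cells = NULL) {
  vars <- names(niche$coefficients)
  missing_v <- setdiff(vars, env_vars(env))
  if (length(missing_v) > 0) {
    stop("niche uses variables absent from stack: ", paste(missing_v, collapse = ", "))
  }
  m <- env_matrix(env, vars, cells = cells)
  stats::plogis(niche$intercept + drop(m %*% niche$coefficients))
}

#' True range cells of a niche
#' @inheritParams niche_suitability
#' @param native_cells Cell ids of the species' native range.
#' @return Integer vector of cell ids with suitability >= `s_star`.
#' @export
true_range_cells <- function(niche, env, native_cells) {
  s <- niche_suitability(niche, env, cells = native_cells)
  as.integer(native_cells[s >= niche$s_star])
}

#' Draw a random niche with a target prevalence
#'
#' Coefficients are drawn for a few active variables per set and the intercept
#' is set so that about `prevalence` of the native range has suitability at or
#' above `s_star` under the baseline stack.
#'
#' @param species_id Species identifier.
#' @param env Baseline [env_stack()].
#' @param native_cells Native-range cell ids.
#' @param n_active Named counts of active variables per set
#'   (default climatic 3, edaphic 1, geophysical 1).
#' @param coef_sd Sd of the normal coefficient draw (default 1.5).
#' @param prevalence Target fraction of the native range in the true range
#'   (default 0.15).
#' @param s_star Suitability threshold (default 0.5).
#' @param seed Integer seed.
#' @return A [true_niche()].
#' @export
simulate_niche <- function(species_id, env, native_cells,
                           n_active = c(climatic = 3, edaphic = 1, geophysical = 1),
                           coef_sd = 1.5, prevalence = 0.15, s_star = 0.5,
                           seed = 1) {
  with_seed(seed, {
    vars <- unlist(lapply(names(n_active), function(s) {
      pool <- env_vars(env, s)
      sample(pool, min(n_active[[s]], length(pool)))
    }))
    coefs <- stats::rnorm(length(vars), 0, coef_sd)
    names(coefs) <- vars
    lp <- drop(env_matrix(env, vars, cells = native_cells) %*% coefs)
    # place the (1 - prevalence) quantile of the linear predictor at logit(s_star)
    intercept <- stats::qlogis(s_star) - stats::quantile(lp, 1 - prevalence, names = FALSE)
    true_niche(species_id, coefs, intercept, s_star = s_star)
  })
}

#' Generate a blob-shaped native range
#'
#' The `fraction * n_cells` cells nearest a random centre — a compact disc
#' clipped at the grid border.
#'
#' @param grid A [grid_spec()].
#' @param fraction Fraction of the grid in the range (default 0.3).
#' @param seed Integer seed.
#' @return Integer vector of cell ids.
#' @export
generate_native_range <- function(grid, fraction = 0.3, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  cells <- grid_cells(grid)
  with_seed(seed, {
    centre <- cells[sample.int(nrow(cells), 1), ]
    d <- (cells$x - centre$x)^2 + (cells$y - centre$y)^2
    k <- max(1L, round(fraction * nrow(cells)))
    sort(cells$cell_id[order(d)][seq_len(k)])
  })
}

#' Generate a blob-shaped protected-area mask
#'
#' A union of random compact blobs (discs of varying radius) covering a target
#' fraction of the grid; stands in for a rasterized protected-area polygon
#' layer. A common radius multiplier is solved so that coverage matches the
#' target to within one cell.
#'
#' @param grid A [grid_spec()].
#' @param target_fraction Fraction of cells to protect, in [0, 1].
#' @param n_blobs Number of blobs (default 10).
#' @param seed Integer seed.
#' @return A tibble (`cell_id`, `protected`) of class `pa_mask` with the grid
#'   attached; `protected` is 0/1.
#' @export
generate_protected_areas <- function(grid, target_fraction, n_blobs = 10, seed = 1) {
  stopifnot(target_fraction >= 0, target_fraction <= 1)
  nc <- n_cells(grid)
  if (target_fraction > 0 && target_fraction < 1 && n_blobs == 0) {
    stop("cannot reach a positive target_fraction with n_blobs = 0")
  }
  prot <- if (target_fraction == 0) {
    rep(0L, nc)
  } else if (target_fraction == 1) {
    rep(1L, nc)
  } else {
    cells <- grid_cells(grid)
    with_seed(seed, {
      centres <- cells[sample.int(nc, n_blobs, replace = TRUE), ]
      radii <- stats::runif(n_blobs, 0.5, 1.5)
      # scaled distance to nearest blob: cell is protected iff s <= multiplier
      s <- rep(Inf, nc)
      for (i in seq_len(n_blobs)) {
        d <- sqrt((cells$x - centres$x[i])^2 + (cells$y - centres$y[i])^2)
        s <- pmin(s, d / radii[i])
      }
      m <- stats::quantile(s, target_fraction, type = 1, names = FALSE)
      as.integer(s <= m)
    })
  }
  structure(
    tibble::tibble(cell_id = seq_len(nc), protected = prot),
    grid = grid,
    class = c("pa_mask", class(tibble::tibble()))
  )
}

#' Sample occurrence records from a true niche
#'
#' Presence cells are drawn with probability proportional to true suitability
#' within the native range; each point is jittered uniformly inside its cell
#' and carries a sampled coordinate-uncertainty value (exponential, mean
#' `uncertainty_mean_km`, capped at 10 km so base records survive the
#' strict ">10 km" QC rule). Known-bad records are injected for QC testing and
#' carried with truth flags: exact duplicates, points outside the native
#' range, points with uncertainty in (10, 50] km, records without coordinates,
#' and records flagged non-target/cultivated.
#'
#' @param niche A [true_niche()].
#' @param env Baseline [env_stack()].
#' @param n Number of clean presence records (>= 0).
#' @param native_cells Native-range cell ids.
#' @param uncertainty_mean_km Mean of the base uncertainty draw (default 3).
#' @param dup_fraction,outside_fraction,uncertain_fraction,nocoord_fraction,nontarget_fraction
#'   Injection rates, as fractions of `n` (defaults 0.10, 0.05, 0.05, 0.02, 0.03).
#' @param seed Integer seed.
#' @return Tibble of records: `species_id`, `x`, `y`, `uncertainty_km`,
#'   `flagged_nontarget`, `source` (provenance tag) and logical truth columns
#'   `injected_duplicate`, `injected_outside`, `injected_uncertain`,
#'   `injected_nocoord`.
#' @export
sample_occurrences <- function(niche, env, n, native_cells,
                               uncertainty_mean_km = 3,
                               dup_fraction = 0.10, outside_fraction = 0.05,
                               uncertain_fraction = 0.05, nocoord_fraction = 0.02,
                               nontarget_fraction = 0.03,
                               seed = 1) {
  stopifnot(n >= 0)
  grid <- attr(env, "grid")
  empty <- tibble::tibble(
    species_id = character(), x = numeric(), y = numeric(),
    uncertainty_km = numeric(), flagged_nontarget = logical(),
    source = character(), injected_duplicate = logical(),
    injected_outside = logical(), injected_uncertain = logical(),
    injected_nocoord = logical()
  )
  if (n == 0) return(empty)
  suit <- niche_suitability(niche, env, cells = native_cells)
  if (all(suit == 0)) stop("niche suitability is zero everywhere in the native range")
  cs <- grid$cell_size_km
  with_seed(seed, {
    draw_points <- function(k, weights, cells) {
      idx <- sample.int(length(cells), k, replace = TRUE, prob = weights)
      ctr <- cell_centres(grid, cells[idx])
      tibble::tibble(
        x = ctr$x + stats::runif(k, -cs / 2, cs / 2),
        y = ctr$y + stats::runif(k, -cs / 2, cs / 2)
      )
    }
    base <- draw_points(n, suit, native_cells)
    base$uncertainty_km <- pmin(stats::rexp(n, 1 / uncertainty_mean_km), 10)
    base$source <- "niche"
    base$flagged_nontarget <- FALSE
    n_nt <- ceiling(nontarget_fraction * n)
    if (n_nt > 0) {
      # flag clean base records as non-target/cultivated (QC drops on the flag)
      base$flagged_nontarget[sample.int(n, min(n_nt, n))] <- TRUE
    }
    base$injected_duplicate <- FALSE
    base$injected_outside <- FALSE
    base$injected_uncertain <- FALSE
    base$injected_nocoord <- FALSE

    extras <- list()
    n_dup <- ceiling(dup_fraction * n)
    keepers <- which(!base$flagged_nontarget) # a duplicate must shadow a record
    if (n_dup > 0 && length(keepers) > 0) {   # that survives the other filters
      d <- base[sample(keepers, n_dup, replace = TRUE), ]
      d <- d[!duplicated(d[, c("x", "y")]), ]
      d$source <- "injected_duplicate"
      d$injected_duplicate <- TRUE
      extras$dup <- d
    }
    outside_cells <- setdiff(seq_len(n_cells(grid)), native_cells)
    n_out <- ceiling(outside_fraction * n)
    if (n_out > 0 && length(outside_cells) > 0) {
      o <- draw_points(n_out, rep(1, length(outside_cells)), outside_cells)
      o$uncertainty_km <- pmin(stats::rexp(n_out, 1 / uncertainty_mean_km), 10)
      o$source <- "injected_outside"
      o$injected_duplicate <- FALSE
      o$injected_outside <- TRUE
      o$injected_uncertain <- FALSE
      o$injected_nocoord <- FALSE
      extras$out <- o
    }
    n_unc <- ceiling(uncertain_fraction * n)
    if (n_unc > 0) {
      u <- draw_points(n_unc, suit, native_cells)
      u$uncertainty_km <- stats::runif(n_unc, 10 + 1e-6, 50)
      u$source <- "injected_uncertain"
      u$injected_duplicate <- FALSE
      u$injected_outside <- FALSE
      u$injected_uncertain <- TRUE
      u$injected_nocoord <- FALSE
      extras$unc <- u
    }
    n_noc <- ceiling(nocoord_fraction * n)
    if (n_noc > 0) {
      m <- tibble::tibble(
        x = NA_real_, y = NA_real_,
        uncertainty_km = pmin(stats::rexp(n_noc, 1 / uncertainty_mean_km), 10),
        source = "injected_nocoord",
        injected_duplicate = FALSE, injected_outside = FALSE,
        injected_uncertain = FALSE, injected_nocoord = TRUE
      )
      extras$noc <- m
    }
    out <- dplyr::bind_rows(c(list(base = base), extras))
    out$flagged_nontarget[is.na(out$flagged_nontarget)] <- FALSE
    out$species_id <- niche$species_id
    out[, names(empty)]
  })
}

#' Generate a synthetic species-to-crop genepool table
#'
#' Assigns every species to one crop (and 10% of species to a second crop of
#' a different type, emulating membership in several genepools); crops are
#' spread over a small set of crop types.
#'
#' @param species_ids Character vector of species ids.
#' @param n_crops Number of crops (default 8).
#' @param crop_types Crop-type labels to cycle crops through.
#' @param second_crop_fraction Fraction of species in two genepools (default 0.1).
#' @param seed Integer seed.
#' @return Tibble `species_id`, `crop`, `crop_type`.
#' @export
simulate_crop_map <- function(species_ids, n_crops = 8,
                              crop_types = c("cereals", "legumes",
                                             "roots and tubers", "fruits"),
                              second_crop_fraction = 0.1, seed = 1) {
  stopifnot(length(species_ids) >= 1, n_crops >= 1)
  crops <- tibble::tibble(
    crop = sprintf("crop%02d", seq_len(n_crops)),
    crop_type = rep(crop_types, length.out = n_crops)
  )
  with_seed(seed, {
    first <- crops[sample.int(n_crops, length(species_ids), replace = TRUE), ]
    out <- dplyr::bind_cols(tibble::tibble(species_id = species_ids), first)
    n_second <- floor(second_crop_fraction * length(species_ids))
    if (n_second > 0) {
      sp2 <- sample(species_ids, n_second)
      extra <- lapply(sp2, function(sp) {
        cur <- out$crop[out$species_id == sp][1]
        pool <- crops[crops$crop != cur, ]
        dplyr::bind_cols(tibble::tibble(species_id = sp),
                         pool[sample.int(nrow(pool), 1), ])
      })
      out <- dplyr::bind_rows(out, dplyr::bind_rows(extra))
    }
    dplyr::arrange(out, .data$species_id, .data$crop)
  })
}

#' True range-loss fraction under a future climate
#'
#' Ground truth for the pipeline's range-loss estimates: the fraction of the
#' true current range (cells at or above `s_star` under the baseline) that is
#' no longer suitable under the mean future stack.
#'
#' @param niche A [true_niche()].
#' @param env_baseline Baseline [env_stack()].
#' @param env_future_mean Mean future [env_stack()] (see [env_mean()]).
#' @param native_cells Native-range cell ids.
#' @return Loss fraction in [0, 1].
#' @export
true_loss <- function(niche, env_baseline, env_future_mean, native_cells) {
  cur <- true_range_cells(niche, env_baseline, native_cells)
  if (length(cur) == 0) stop("true current range is empty")
  fut <- true_range_cells(niche, env_future_mean, native_cells)
  1 - length(intersect(cur, fut)) / length(cur)
}

#' Simulate a complete synthetic world
#'
#' Bundles every generator: a baseline stack, future realizations and their
#' mean, per-species native ranges, niches, occurrence sets with QC injections,
#' a protected-area mask, and the per-species truth table (true current/future
#' range sizes and true loss).
#'
#' Per-species occurrence counts are drawn from a mixture emulating the highly
#' skewed availability of real records: 10% of species get 0 records, 20% get
#' 1–9, 30% get 10–150, 40% get 300–600.
#'
#' @param config A [landscape_config()].
#' @param n_species Number of species (default 20).
#' @param pa_fraction Protected fraction of the grid (default 0.15).
#' @param native_fraction Fraction of the grid in each native range (default 0.35).
#' @param n_occurrences Optional integer vector (length `n_species`) of clean
#'   record counts; default draws from the mixture above.
#' @param prevalence True-range prevalence within the native range (default 0.15).
#' @return A list of class `synthetic_world` with elements `grid`, `env`,
#'   `futures`, `env_future_mean`, `native_ranges`, `niches`, `occurrences`,
#'   `pa`, `truth`.
#' @export
simulate_world <- function(config, n_species = 20, pa_fraction = 0.15,
                           native_fraction = 0.35, n_occurrences = NULL,
                           prevalence = 0.15) {
  stopifnot(inherits(config, "landscape_config"), n_species >= 1)
  env <- generate_env_stack(config)
  futures <- generate_future(env, config)
  env_future_mean <- if (length(futures) > 0) env_mean(futures) else env
  pa <- generate_protected_areas(config$grid, pa_fraction,
                                 seed = substream(config$seed, 7))
  sp_ids <- sprintf("sp%03d", seq_len(n_species))
  if (is.null(n_occurrences)) {
    n_occurrences <- with_seed(substream(config$seed, 11), {
      cat_draw <- sample.int(4, n_species, replace = TRUE, prob = c(.1, .2, .3, .4))
      vapply(cat_draw, function(k) {
        switch(k, 0L, sample(1:9, 1), sample(10:150, 1), sample(300:600, 1))
      }, integer(1))
    })
  }
  stopifnot(length(n_occurrences) == n_species)

  native_ranges <- lapply(seq_len(n_species), function(i) {
    generate_native_range(config$grid, native_fraction,
                          seed = substream(config$seed, 1000 + i))
  })
  names(native_ranges) <- sp_ids
  niches <- lapply(seq_len(n_species), function(i) {
    simulate_niche(sp_ids[i], env, native_ranges[[i]],
                   prevalence = prevalence,
                   seed = substream(config$seed, 2000 + i))
  })
  names(niches) <- sp_ids
  occ <- dplyr::bind_rows(lapply(seq_len(n_species), function(i) {
    sample_occurrences(niches[[i]], env, n_occurrences[i], native_ranges[[i]],
                       seed = substream(config$seed, 3000 + i))
  }))
  has_future <- length(futures) > 0
  truth <- dplyr::bind_rows(lapply(seq_len(n_species), function(i) {
    cur <- true_range_cells(niches[[i]], env, native_ranges[[i]])
    fut <- if (has_future) {
      true_range_cells(niches[[i]], env_future_mean, native_ranges[[i]])
    } else {
      NULL
    }
    tibble::tibble(
      species_id = sp_ids[i],
      n_records = n_occurrences[i],
      n_true_current = length(cur),
      n_true_future = if (has_future) length(fut) else NA_integer_,
      true_loss = if (has_future && length(cur) > 0) {
        1 - length(intersect(cur, fut)) / length(cur)
      } else {
        NA_real_
      }
    )
  }))
  crop_map <- simulate_crop_map(sp_ids, seed = substream(config$seed, 13))
  structure(
    list(
      grid = config$grid, config = config, env = env, futures = futures,
      env_future_mean = env_future_mean, native_ranges = native_ranges,
      niches = niches, occurrences = occ, pa = pa, crop_map = crop_map,
      truth = truth
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d species on a %d x %d grid; %d occurrence records; %d future realization(s)\n",
    length(x$niches), x$grid$n_rows, x$grid$n_cols, nrow(x$occurrences),
    length(x$futures)
  ))
  invisible(x)
}
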