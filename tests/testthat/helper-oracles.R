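# Independent oracles: deliberately naive re-implementations used to verify
# the package's algorithms. They share no code with the implementation paths.

# exhaustive sensitivity+specificity threshold scan (double loop)
oracle_maxtrss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  best_t <- NA_real_
  best_obj <- -Inf
  for (t in cand) {
    sens <- sum(pres >= t) / length(pres)
    spec <- sum(bg < t) / length(bg)
    if (sens + spec > best_obj + 1e-12) {
      best_obj <- sens + spec
      best_t <- t
    }
  }
  list(threshold = best_t, objective = best_obj)
}

# stepwise VIF removal using lm() R-squared directly
oracle_vif_screen <- function(x, threshold = 10) {
  x <- as.data.frame(x)
  removed <- character(0)
  repeat {
    vars <- setdiff(colnames(x), removed)
    if (length(vars) <= 1) break
    vifs <- sapply(vars, function(v) {
      r2 <- summary(stats::lm(
        stats::reformulate(setdiff(vars, v), response = v),
        data = x
      ))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    })
    if (max(vifs) < threshold) break
    worst <- max(which(vifs == max(vifs)))
    removed <- c(removed, vars[worst])
  }
  list(retained = setdiff(colnames(x), removed), removed = removed)
}

# empirical semivariogram range from random cell pairs: first binned distance
# at which the semivariance reaches 95% of the field variance
oracle_variogram_range <- function(values, xy, n_pairs = 200000, bin_km = 5,
                                   seed = 1) {
  set.seed(seed)
  i <- sample.int(nrow(xy), n_pairs, replace = TRUE)
  j <- sample.int(nrow(xy), n_pairs, replace = TRUE)
  d <- sqrt((xy$x[i] - xy$x[j])^2 + (xy$y[i] - xy$y[j])^2)
  gamma2 <- (values[i] - values[j])^2 / 2
  keep <- d > 0 & d < max(xy$x) / 2
  bins <- floor(d[keep] / bin_km)
  gam <- tapply(gamma2[keep], bins, mean)
  dist_mid <- (as.numeric(names(gam)) + 0.5) * bin_km
  sill <- stats::var(values)
  idx <- which(gam >= 0.95 * sill)
  if (length(idx) == 0) return(Inf)
  dist_mid[min(idx)]
}

# exhaustive 2^n enumeration of a reserve problem, vectorized over subsets;
# recomputes cost + blm*boundary + penalty directly from the problem tables
oracle_enumerate_reserve <- function(problem) {
  n <- nrow(problem$units)
  m <- nrow(problem$combinations)
  stopifnot(n <= 16)
  masks <- 0:(2^n - 1)
  S <- sapply(seq_len(n), function(b) bitwAnd(masks, bitwShiftL(1L, b - 1L)) != 0)
  if (n == 1) S <- matrix(S, ncol = 1)
  storage.mode(S) <- "numeric"
  cost <- drop(S %*% problem$units$cost)
  n_sel <- rowSums(S)
  adj <- problem$adjacency
  internal <- if (nrow(adj) > 0) {
    acc <- numeric(length(masks))
    for (e in seq_len(nrow(adj))) { # directed edges
      acc <- acc + S[, adj$unit_id[e]] * S[, adj$neighbour_unit[e]]
    }
    acc
  } else {
    0
  }
  boundary <- 4 * n_sel - internal
  M <- matrix(0, n, m)
  M[cbind(problem$incidence$unit_id, problem$incidence$combination_id)] <- 1
  covered <- S %*% M > 0
  pen <- drop((!covered) %*% (problem$spf * problem$combinations$penalty))
  obj <- cost + problem$blm * boundary + pen
  best <- which.min(obj)
  best_sel <- which(S[best, ] == 1)
  list(objective = obj[best], selected = best_sel,
       unmet = reserve_objective(problem, best_sel)$unmet)
}

# naive greedy complementarity trace re-evaluating every candidate each step
oracle_greedy <- function(units, incidence, mode = "adaptive") {
  combos_of <- function(u) unique(incidence$combination_id[incidence$unit_id == u])
  species_of <- function(u) unique(incidence$species_id[incidence$unit_id == u])
  covered <- integer(0)
  covered_sp <- character(0)
  remaining <- sort(unique(units$unit_id))
  pa_of <- function(u) units$pa[match(u, units$unit_id)] == 1
  order_out <- integer(0)
  gains_out <- integer(0)
  phase_pa <- mode == "pragmatic"
  repeat {
    cands <- if (phase_pa) remaining[pa_of(remaining)] else remaining
    gains <- vapply(cands, function(u) length(setdiff(combos_of(u), covered)),
                    integer(1))
    if (length(cands) == 0 || all(gains == 0)) {
      if (phase_pa) {
        phase_pa <- FALSE
        next
      }
      break
    }
    top <- cands[gains == max(gains)]
    if (length(top) > 1) {
      spg <- vapply(top, function(u) length(setdiff(species_of(u), covered_sp)),
                    integer(1))
      top <- top[spg == max(spg)]
    }
    pick <- min(top)
    gains_out <- c(gains_out, length(setdiff(combos_of(pick), covered)))
    covered <- union(covered, combos_of(pick))
    covered_sp <- union(covered_sp, species_of(pick))
    order_out <- c(order_out, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(order = order_out, gains = gains_out, covered = sort(covered))
}

# random small reserve instance (costs in {10, 50}, grid-free random adjacency)
random_reserve_problem <- function(n_units, n_combos, blm, seed) {
  set.seed(seed)
  units <- tibble::tibble(
    unit_id = seq_len(n_units),
    pa = rbinom(n_units, 1, 0.4)
  )
  units$cost <- ifelse(units$pa == 1, 10, 50)
  inc <- do.call(rbind, lapply(seq_len(n_combos), function(c) {
    k <- sample(1:max(1, n_units %/% 3), 1)
    data.frame(combination_id = c,
               unit_id = sort(sample(n_units, k)))
  }))
  n_edges <- sample(0:(2 * n_units), 1)
  adj <- NULL
  if (n_edges > 0 && n_units > 1) {
    a <- sample(n_units, n_edges, replace = TRUE)
    b <- sample(n_units, n_edges, replace = TRUE)
    keep <- a != b
    if (any(keep)) {
      e <- unique(data.frame(u = pmin(a[keep], b[keep]),
                             v = pmax(a[keep], b[keep])))
      adj <- tibble::tibble(unit_id = c(e$u, e$v), neighbour_unit = c(e$v, e$u))
    }
  }
  new_reserve_problem(
    units, tibble::tibble(combination_id = seq_len(n_combos)),
    tibble::as_tibble(inc), adjacency = adj, blm = blm, spf = 1
  )
}
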