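#' Build an ecogeographic land characterization (ELC) map
#'
#' Clusters the standardized cell values of each non-collinear variable set
#' (edaphic, geophysical, climatic) independently with seeded k-means, then
#' combines the three cluster labels into a single composite integer category.
#' Each composite category is one "adaptive scenario" — the pipeline's proxy
#' unit of potential genetic diversity within a species' native range. Cells
#' with missing data in any set receive no category and are excluded from all
#' scenario counts.
#'
#' @param env Baseline [env_stack()].
#' @param native_cells Cell ids of the species' native range (the clustering
#'   domain).
#' @param k Named integer vector of cluster counts per set (default 5 each).
#' @param vars Optional named list (`edaphic`, `geophysical`, `climatic`) of
#'   retained (post-VIF) variables per set; default all variables of each set.
#' @param species_id Species label.
#' @param seed Integer seed (k-means initialization).
#' @param nstart Number of k-means restarts (default 10).
#' @return A tibble (`cell_id`, `category`) of class `elc_map` with attributes
#'   `codebook` (tibble `category`, `edaphic`, `geophysical`, `climatic`
#'   cluster labels), `k`, `centers` (per-set centroid matrices), `species_id`,
#'   `grid`.
#' @export
build_elc <- function(env, native_cells, k = c(edaphic = 5, geophysical = 5, climatic = 5),
                      vars = NULL, species_id = NA_character_, seed = 1,
                      nstart = 10) {
  stopifnot(inherits(env, "env_stack"), length(native_cells) >= 1)
  sets <- c("edaphic", "geophysical", "climatic")
  if (!all(sets %in% names(k))) stop("k must name edaphic, geophysical, climatic")
  if (any(k[sets] < 1)) stop("k must be >= 1 per set")
  if (is.null(vars)) {
    vars <- lapply(sets, function(s) env_vars(env, s))
    names(vars) <- sets
  }
  labels <- list()
  centers <- list()
  for (s in sets) {
    v <- vars[[s]]
    if (length(v) < 1) stop("no retained variables in set ", s)
    m <- env_matrix(env, v, cells = native_cells)
    complete <- stats::complete.cases(m)
    mz <- scale(m[complete, , drop = FALSE])
    mz[, attr(mz, "scaled:scale") == 0] <- 0
    ks <- k[[s]]
    n_distinct_rows <- nrow(unique(mz))
    if (ks > n_distinct_rows) {
      stop(sprintf("k = %d exceeds the %d distinct cell profiles in set %s",
                   ks, n_distinct_rows, s))
    }
    lab <- rep(NA_integer_, length(native_cells))
    if (ks == 1) {
      lab[complete] <- 1L
      centers[[s]] <- matrix(colMeans(mz), nrow = 1,
                             dimnames = list(NULL, colnames(mz)))
    } else {
      km <- with_seed(substream(seed, match(s, sets)),
                      stats::kmeans(mz, centers = ks, nstart = nstart,
                                    iter.max = 100))
      lab[complete] <- km$cluster
      centers[[s]] <- km$centers
    }
    labels[[s]] <- lab
  }
  ke <- k[["edaphic"]]; kg <- k[["geophysical"]]; kc <- k[["climatic"]]
  complete_all <- !is.na(labels$edaphic) & !is.na(labels$geophysical) &
    !is.na(labels$climatic)
  category <- rep(NA_integer_, length(native_cells))
  category[complete_all] <-
    (labels$edaphic[complete_all] - 1L) * kg * kc +
    (labels$geophysical[complete_all] - 1L) * kc +
    labels$climatic[complete_all]
  codebook <- tidyr::expand_grid(
    edaphic = seq_len(ke), geophysical = seq_len(kg), climatic = seq_len(kc)
  )
  codebook$category <- (codebook$edaphic - 1L) * kg * kc +
    (codebook$geophysical - 1L) * kc + codebook$climatic
  codebook <- codebook[, c("category", "edaphic", "geophysical", "climatic")]
  structure(
    tibble::tibble(cell_id = as.integer(native_cells), category = category),
    codebook = codebook, k = k[sets], centers = centers,
    species_id = species_id, grid = attr(env, "grid"),
    class = c("elc_map", class(tibble::tibble()))
  )
}

#' @export
print.elc_map <- function(x, ...) {
  cat(sprintf(
    "<elc_map> %s: %d categories occupied over %d cells (k = %s)\n",
    attr(x, "species_id"), dplyr::n_distinct(x$category[!is.na(x$category)]),
    nrow(x), paste(attr(x, "k"), collapse = "x")
  ))
  invisible(x)
}

#' Plot an ELC map
#' @param object An [build_elc()] map.
#' @param ... Unused.
#' @return A ggplot tile map of composite categories.
#' @export
autoplot.elc_map <- function(object, ...) {
  grid <- attr(object, "grid")
  pts <- dplyr::bind_cols(
    cell_centres(grid, object$cell_id)[, c("x", "y")],
    category = factor(object$category)
  )
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y, fill = .data$category)) +
    ggplot2::geom_tile(width = grid$cell_size_km, height = grid$cell_size_km) +
    ggplot2::coord_equal() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = sprintf("ELC categories: %s", attr(object, "species_id")))
}

#' Adaptive scenarios present in a range
#'
#' The set of ELC categories occurring in at least one cell of a range map:
#' the species' breadth of adaptive scenarios at that epoch. An empty range
#' yields an empty set (not an error).
#'
#' @param elc An [build_elc()] map.
#' @param range A [range_map()] (or an integer vector of cell ids) on the same
#'   grid.
#' @return Sorted integer vector of categories present.
#' @export
scenarios_in_range <- function(elc, range) {
  stopifnot(inherits(elc, "elc_map"))
  cells <- if (inherits(range, "range_map")) range$cell_id else as.integer(range)
  cat <- elc$category[match(cells, elc$cell_id)]
  sort(unique(cat[!is.na(cat)]))
}
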