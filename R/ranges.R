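#' Binary species range maps
#'
#' A `range_map` is the pipeline's binary presence raster: the set of grid
#' cells occupied by one species at one epoch, carrying its provenance
#' (`origin`): a thresholded distribution model or a circular occurrence
#' buffer. Stored tidily as a one-column tibble of occupied `cell_id`s.
#'
#' @param cell_id Integer vector of occupied cell ids (deduplicated, sorted).
#' @param species_id Species identifier.
#' @param epoch One of `"current"`, `"future_ensemble"`, `"stable"`.
#' @param origin One of `"model"`, `"buffer"`.
#' @param grid The [grid_spec()].
#' @return A tibble of class `range_map`.
#' @export
range_map <- function(cell_id, species_id, epoch, origin, grid) {
  epoch <- match.arg(epoch, c("current", "future_ensemble", "stable"))
  origin <- match.arg(origin, c("model", "buffer"))
  stopifnot(inherits(grid, "grid_spec"))
  cell_id <- sort(unique(as.integer(cell_id)))
  if (length(cell_id) > 0) {
    stopifnot(min(cell_id) >= 1, max(cell_id) <= n_cells(grid))
  }
  structure(
    tibble::tibble(cell_id = cell_id),
    species_id = species_id, epoch = epoch, origin = origin, grid = grid,
    class = c("range_map", class(tibble::tibble()))
  )
}

#' @export
print.range_map <- function(x, ...) {
  cat(sprintf(
    "<range_map> %s [%s, %s]: %d cells\n",
    attr(x, "species_id"), attr(x, "epoch"), attr(x, "origin"), nrow(x)
  ))
  invisible(x)
}

#' Cells of a range map
#' @param range A [range_map()].
#' @return Integer vector of occupied cell ids.
#' @export
range_cells <- function(range) {
  stopifnot(inherits(range, "range_map"))
  range$cell_id
}

#' Plot a range map
#' @param object A [range_map()].
#' @param ... Unused.
#' @return A ggplot tile map of the occupied cells.
#' @export
autoplot.range_map <- function(object, ...) {
  grid <- attr(object, "grid")
  pts <- cell_centres(grid, object$cell_id)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(
      width = grid$cell_size_km, height = grid$cell_size_km, fill = "forestgreen"
    ) +
    ggplot2::coord_equal(
      xlim = grid$origin[1] + c(0, grid$n_cols * grid$cell_size_km),
      ylim = grid$origin[2] + c(0, grid$n_rows * grid$cell_size_km)
    ) +
    ggplot2::labs(
      title = sprintf("%s (%s, %s)", attr(object, "species_id"),
                      attr(object, "epoch"), attr(object, "origin")),
      x = "x (km)", y = "y (km)"
    )
}
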