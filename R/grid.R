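#' Define the analysis grid
#'
#' All spatial layers in the pipeline live on a flat Cartesian equal-area grid
#' of square cells, indexed row-major by an integer `cell_id`. The global
#' analysis this package emulates works on a 5 km x 5 km terrestrial grid, so
#' `cell_size_km` defaults to 5. Coordinates are in kilometres; geodesy is
#' deliberately out of scope (every cell has area `cell_size_km^2`).
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size_km Edge length of a cell in km (default 5).
#' @param origin Numeric length-2, `(x0, y0)` of the grid's lower-left corner
#'   in km.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 10)
#' n_cells(g)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 5, origin = c(0, 0)) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    is.numeric(cell_size_km), length(cell_size_km) == 1, cell_size_km > 0,
    is.numeric(origin), length(origin) == 2
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size_km = as.numeric(cell_size_km),
      origin = as.numeric(origin)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g km (origin %g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size_km, x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$n_rows * grid$n_cols
}

#' Cell index table for a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `cell_id` (row-major integer id),
#'   `row`, `col`, and cell-centre coordinates `x`, `y` in km.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    cell_id = seq_len(grid$n_rows * grid$n_cols),
    row = row,
    col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size_km,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size_km
  )
}

#' Locate points on the grid
#'
#' Maps continuous `(x, y)` km coordinates to the containing cell.
#'
#' @param grid A [grid_spec()].
#' @param x,y Numeric vectors of point coordinates in km.
#' @return Integer vector of `cell_id`s, `NA` for points off the grid.
#' @export
cell_at <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"), length(x) == length(y))
  col <- floor((x - grid$origin[1]) / grid$cell_size_km) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size_km) + 1
  ok <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols
  out <- rep(NA_integer_, length(x))
  out[ok] <- (row[ok] - 1L) * grid$n_cols + col[ok]
  as.integer(out)
}

#' Cell-centre coordinates for given cell ids
#' @param grid A [grid_spec()].
#' @param cell_id Integer vector of cell ids.
#' @return Tibble with `cell_id`, `x`, `y`.
#' @export
cell_centres <- function(grid, cell_id) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- (cell_id - 1L) %% grid$n_cols + 1L
  row <- (cell_id - 1L) %/% grid$n_cols + 1L
  tibble::tibble(
    cell_id = as.integer(cell_id),
    x = grid$origin[1] + (col - 0.5) * grid$cell_size_km,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size_km
  )
}

#' Rook (horizontal + vertical) neighbours of every cell
#'
#' Used for the reserve-selection boundary file: each planning unit lists its
#' horizontal and vertical neighbours; grid-exterior edges count as boundary.
#'
#' @param grid A [grid_spec()].
#' @return Tibble with columns `cell_id`, `neighbour_id` (each undirected edge
#'   appears twice, once per direction).
#' @export
grid_adjacency <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  nr <- grid$n_rows
  nc <- grid$n_cols
  id <- seq_len(nr * nc)
  col <- (id - 1L) %% nc + 1L
  row <- (id - 1L) %/% nc + 1L
  edges <- list(
    tibble::tibble(cell_id = id[col < nc], neighbour_id = id[col < nc] + 1L),
    tibble::tibble(cell_id = id[col > 1], neighbour_id = id[col > 1] - 1L),
    tibble::tibble(cell_id = id[row < nr], neighbour_id = id[row < nr] + nc),
    tibble::tibble(cell_id = id[row > 1], neighbour_id = id[row > 1] - nc)
  )
  dplyr::arrange(dplyr::bind_rows(edges), .data$cell_id, .data$neighbour_id)
}

# internal: logical presence vector (length n_cells) from a set of cell ids
cells_to_mask <- function(grid, cell_id) {
  m <- logical(n_cells(grid))
  m[cell_id] <- TRUE
  m
}
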