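#' Environmental layer stacks
#'
#' An `env_stack` is a tidy raster container: a tibble with one row per grid
#' cell (`cell_id`, `row`, `col`, `x`, `y`) and one column per environmental
#' variable. Variables are grouped into the three ecogeographic sets used
#' throughout the pipeline — `edaphic`, `geophysical` and `climatic` — and the
#' stack carries its [grid_spec()] and an epoch label (`"baseline"` or a named
#' future realization).
#'
#' @param values A data frame with `cell_id` and one numeric column per
#'   variable, one row per grid cell.
#' @param grid The [grid_spec()] the layers live on.
#' @param var_sets A data frame with columns `variable`, `set` assigning every
#'   variable column to one of `edaphic`, `geophysical`, `climatic`.
#' @param epoch Epoch label, default `"baseline"`.
#'
#' @return A tibble of class `env_stack`.
#' @export
env_stack <- function(values, grid, var_sets, epoch = "baseline") {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(values), is.data.frame(var_sets))
  var_sets <- tibble::as_tibble(var_sets)
  stopifnot(all(c("variable", "set") %in% names(var_sets)))
  bad <- setdiff(unique(var_sets$set), c("edaphic", "geophysical", "climatic"))
  if (length(bad) > 0) {
    stop("unknown variable set(s): ", paste(bad, collapse = ", "))
  }
  missing_cols <- setdiff(var_sets$variable, names(values))
  if (length(missing_cols) > 0) {
    stop("variables missing from values: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(values) != n_cells(grid)) {
    stop("values must have one row per grid cell")
  }
  out <- dplyr::left_join(grid_cells(grid), tibble::as_tibble(values), by = "cell_id")
  structure(
    out,
    grid = grid, var_sets = var_sets, epoch = epoch,
    class = c("env_stack", class(tibble::tibble()))
  )
}

#' @export
print.env_stack <- function(x, ...) {
  vs <- attr(x, "var_sets")
  cat(sprintf(
    "<env_stack> epoch '%s': %d variables (%s) on %d cells\n",
    attr(x, "epoch"), nrow(vs),
    paste(sprintf("%s %d", names(table(vs$set)), table(vs$set)), collapse = ", "),
    nrow(x)
  ))
  NextMethod()
}

#' Variable names of an environmental stack
#' @param env An [env_stack()].
#' @param set Optional set filter (`"edaphic"`, `"geophysical"`, `"climatic"`).
#' @return Character vector of variable names.
#' @export
env_vars <- function(env, set = NULL) {
  vs <- attr(env, "var_sets")
  if (!is.null(set)) vs <- vs[vs$set %in% set, ]
  vs$variable
}

#' @rdname env_vars
#' @return For `env_var_sets()`, the `variable`/`set` lookup tibble.
#' @export
env_var_sets <- function(env) attr(env, "var_sets")

#' Extract a numeric matrix of layer values
#' @param env An [env_stack()].
#' @param vars Variables to extract (default: all).
#' @param cells Optional cell ids to restrict rows to.
#' @return Numeric matrix (cells x variables) with rownames set to cell ids.
#' @export
env_matrix <- function(env, vars = env_vars(env), cells = NULL) {
  tbl <- env
  if (!is.null(cells)) tbl <- tbl[match(cells, tbl$cell_id), , drop = FALSE]
  m <- as.matrix(tbl[, vars, drop = FALSE])
  rownames(m) <- tbl$cell_id
  m
}

#' Cellwise mean of several stacks
#'
#' Averages variable layers across a list of stacks on the same grid; used to
#' build the mean future climate surface over an ensemble of realizations.
#'
#' @param stacks A non-empty list of [env_stack()] objects sharing a grid and
#'   variable set.
#' @param epoch Epoch label for the averaged stack.
#' @return An [env_stack()].
#' @export
env_mean <- function(stacks, epoch = "future_mean") {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  grid <- attr(stacks[[1]], "grid")
  vs <- attr(stacks[[1]], "var_sets")
  vars <- vs$variable
  acc <- matrix(0, nrow = n_cells(grid), ncol = length(vars))
  for (s in stacks) {
    stopifnot(identical(attr(s, "var_sets")$variable, vars))
    acc <- acc + env_matrix(s, vars)
  }
  vals <- tibble::as_tibble(as.data.frame(acc / length(stacks)))
  names(vals) <- vars
  vals$cell_id <- seq_len(n_cells(grid))
  env_stack(vals, grid, vs, epoch = epoch)
}

#' Plot the layers of an environmental stack
#'
#' @param object An [env_stack()].
#' @param vars Variables to draw (default: first 6).
#' @param ... Unused.
#' @return A ggplot object (tile map faceted by variable).
#' @export
autoplot.env_stack <- function(object, vars = utils::head(env_vars(object), 6), ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("x", "y", vars)],
    cols = dplyr::all_of(vars), names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~variable) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = NULL)
}

# internal: run expr with a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# internal: derive a reproducible substream seed below 2^31 from a root seed
substream <- function(seed, offset) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483647
}
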