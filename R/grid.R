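#' Global 1-degree density grid
#'
#' A lightweight container for a global 1 x 1 degree latitude/longitude
#' raster, the common currency of the exposure pipeline: bird utilisation
#' distributions aggregated from fine equal-area grids, plastic-density
#' model layers, and exposure maps all live on this grid.
#'
#' Cells are half-open intervals `[i, i + 1)` in both axes, indexed by their
#' south-west corner: rows are latitude bands from -90 to 89, columns are
#' longitude bands from -180 to 179. `NA` marks missing data (e.g. cells
#' where no plastic model has an estimate).
#'
#' @param values numeric matrix of dimension 180 x 360 (lat bands x lon
#'   bands), or a single number to fill the grid with.
#' @param normalised logical; `TRUE` if the non-missing values sum to one.
#' @return an object of class `global_grid`.
#' @export
global_grid <- function(values = NA_real_, normalised = FALSE) {
  if (!is.matrix(values)) {
    stopifnot(length(values) == 1)
    values <- matrix(as.numeric(values), nrow = 180, ncol = 360)
  }
  if (!all(dim(values) == c(180, 360))) {
    stop("global_grid values must be a 180 x 360 matrix (lat x lon)")
  }
  structure(list(values = values, normalised = isTRUE(normalised)),
            class = "global_grid")
}

#' @export
print.global_grid <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf(
    "<global_grid> 1x1 degree, %d/%d cells non-missing, sum = %.6g%s\n",
    n_ok, length(x$values), sum(x$values, na.rm = TRUE),
    if (x$normalised) " (normalised)" else ""))
  invisible(x)
}

#' Row/column indices of the 1-degree cell containing each point
#'
#' Longitudes are normalised to `[-180, 180)` first; latitude 90 (the pole
#' itself) is folded into the top band so every valid point maps to a cell.
#'
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @return a list with integer vectors `row` (1..180) and `col` (1..360).
#' @export
grid_cell_index <- function(lon, lat) {
  check_lonlat(lon, lat)
  lon <- wrap_lon(lon)
  row <- pmin(floor(lat) + 91L, 180L)
  col <- floor(lon) + 181L
  list(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates for every cell of the global grid
#'
#' @return a list with `lon` (length 360) and `lat` (length 180) centre
#'   coordinates; centres are at half-degrees.
#' @export
grid_centres <- function() {
  list(lon = seq(-179.5, 179.5, by = 1), lat = seq(-89.5, 89.5, by = 1))
}

#' Convert a global grid to a long-format table
#'
#' @param grid a [global_grid()].
#' @param drop_na drop missing cells from the output.
#' @return a tibble with columns `lon`, `lat` (cell centres) and `value`.
#' @export
grid_to_df <- function(grid, drop_na = TRUE) {
  stopifnot(inherits(grid, "global_grid"))
  ctr <- grid_centres()
  df <- tibble::tibble(
    lon = rep(ctr$lon, each = 180),
    lat = rep(ctr$lat, times = 360),
    value = as.vector(grid$values))
  if (drop_na) df <- df[!is.na(df$value), , drop = FALSE]
  df
}

#' Build a global grid from a long-format table
#'
#' Inverse of [grid_to_df()]: any cell not present in the table is missing.
#' Longitudes may use either the `[-180, 180)` or the `[0, 360)`
#' (180-degree-centred) convention; the latter is rewrapped on read.
#'
#' @param df a data frame with columns `lon`, `lat`, `value` (cell centres
#'   or any point inside the cell).
#' @return a [global_grid()].
#' @export
df_to_grid <- function(df) {
  stopifnot(all(c("lon", "lat", "value") %in% names(df)))
  g <- matrix(NA_real_, 180, 360)
  idx <- grid_cell_index(wrap_lon(df$lon), df$lat)
  g[cbind(idx$row, idx$col)] <- df$value
  global_grid(g)
}

#' Normalise a grid to unit sum
#'
#' Divides every non-missing value by the total over non-missing cells so
#' the grid integrates to one, turning a raw density layer into a relative
#' distribution. Missing cells stay missing. Idempotent and invariant to
#' positive rescaling of the input.
#'
#' @param grid a [global_grid()] with at least one positive value.
#' @return a normalised [global_grid()].
#' @export
normalize_unit_sum <- function(grid) {
  stopifnot(inherits(grid, "global_grid"))
  tot <- sum(grid$values, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) {
    stop("cannot normalise: grid total is zero, negative or all missing")
  }
  global_grid(grid$values / tot, normalised = TRUE)
}

#' Total over non-missing cells
#' @param grid a [global_grid()].
#' @return the sum of non-missing cell values.
#' @export
grid_sum <- function(grid) sum(grid$values, na.rm = TRUE)

# ---- shared coordinate helpers ------------------------------------------

#' Wrap longitudes into [-180, 180)
#' @param lon numeric vector of longitudes in degrees.
#' @return wrapped longitudes.
#' @export
wrap_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  # %% can return 360 - eps for values like -1e-14; clamp the edge
  out[out >= 180] <- -180
  out
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("coordinates must be finite")
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of bounds [-90, 90]")
  }
  if (any(lon < -360 | lon > 360)) {
    stop("longitude out of plausible range")
  }
  invisible(TRUE)
}

#' Write / read a global grid as CSV
#'
#' Plain-text serialisation used for all gridded inputs and outputs
#' (plastic model layers, land masks, exposure maps): one row per
#' non-missing cell with cell-centre `lon`, `lat` and `value`.
#'
#' @param grid a [global_grid()].
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns a [global_grid()].
#' @export
write_grid_csv <- function(grid, path) {
  readr::write_csv(grid_to_df(grid, drop_na = TRUE), path)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df_to_grid(df)
}
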