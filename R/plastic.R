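#' Combine three plastic-density model layers by geometric mean
#'
#' Ocean plastic model estimates differ on a log scale, and concentrations
#' through time are treated as lognormal, so the per-cell central tendency
#' across models is the geometric mean rather than the arithmetic mean.
#' Missing-data fallback per cell: with all three models present, the
#' geometric mean of three; with one missing, the geometric mean of the
#' other two; with only one present, that estimate; with none, missing.
#' A zero from any contributing model makes the cell zero (no plastic
#' predicted).
#'
#' @param layers list of three [global_grid()] model layers on the common
#'   grid (reoriented to `[-180, 180)` longitudes at read time).
#' @return a [global_grid()] with attributes `n_models` (integer matrix of
#'   contributing-model counts) and `imputed` (logical matrix, all `FALSE`
#'   until [impute_band()]).
#' @export
combine_models <- function(layers) {
  stopifnot(length(layers) == 3,
            all(vapply(layers, inherits, TRUE, "global_grid")))
  vals <- lapply(layers, function(l) {
    if (any(l$values < 0, na.rm = TRUE)) stop("negative plastic density")
    l$values
  })
  obs <- Reduce(`+`, lapply(vals, function(v) !is.na(v)))
  # geometric mean in log space; any zero contributor forces zero
  logs <- lapply(vals, function(v) log(ifelse(is.na(v), NA, pmax(v, 0))))
  logsum <- Reduce(`+`, lapply(logs, function(lv) ifelse(is.na(lv), 0, lv)))
  gm <- exp(logsum / pmax(obs, 1L))
  zero <- Reduce(`|`, lapply(vals, function(v) !is.na(v) & v == 0))
  gm[zero] <- 0
  gm[obs == 0L] <- NA_real_
  out <- global_grid(gm)
  attr(out, "n_models") <- obs
  attr(out, "imputed") <- matrix(FALSE, 180, 360)
  out
}

#' Impute the corrupted 0-1 degree W band
#'
#' The combined model product is unreliable in the 1-degree band just west
#' of the prime meridian (an artefact of the models' 180-degree-centred
#' native storage). Each cell in that band is replaced, per latitude row,
#' by the arithmetic mean of the non-missing values among the six
#' neighbouring cells at 177-180 degrees E and 1-4 degrees W; if all six
#' are missing the cell stays missing. Imputed cells are flagged.
#'
#' @param layer a combined [global_grid()] from [combine_models()] (or any
#'   global grid).
#' @return the layer with the band imputed and the `imputed` attribute
#'   updated.
#' @export
impute_band <- function(layer) {
  stopifnot(inherits(layer, "global_grid"))
  v <- layer$values
  band_col <- grid_cell_index(-0.5, 0)$col          # cells [-1, 0)
  east_cols <- grid_cell_index(c(177.5, 178.5, 179.5), c(0, 0, 0))$col
  west_cols <- grid_cell_index(c(-1.5, -2.5, -3.5), c(0, 0, 0))$col
  nb <- v[, c(east_cols, west_cols), drop = FALSE]
  imp <- rowMeans(nb, na.rm = TRUE)
  imp[is.nan(imp)] <- NA_real_
  v[, band_col] <- imp
  out <- global_grid(v, normalised = FALSE)
  flags <- attr(layer, "imputed")
  if (is.null(flags)) flags <- matrix(FALSE, 180, 360)
  flags[, band_col] <- !is.na(imp)
  attr(out, "n_models") <- attr(layer, "n_models")
  attr(out, "imputed") <- flags
  out
}

#' Read a plastic-density model layer
#'
#' Tabular CSV form (`lon`, `lat`, `density` columns, one row per cell
#' with an estimate). Model outputs stored in the 180-degree-centred
#' convention (longitudes in `[0, 360)`) are rewrapped to `[-180, 180)`
#' on read.
#'
#' @param path file path.
#' @return a [global_grid()] of densities (pieces per km^2).
#' @export
read_plastic_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("lon", "lat", "density") %in% names(df)))
  df_to_grid(tibble::tibble(lon = wrap_lon(df$lon), lat = df$lat,
                            value = df$density))
}

#' Build the combined, imputed, normalised plastic layer from files
#'
#' Convenience wrapper for the whole plastic stage: read the three model
#' CSVs, fuse by geometric mean with fallback, impute the prime-meridian
#' band, and normalise to unit sum.
#'
#' @param paths character vector of three model CSV paths.
#' @return a list with `combined` (unnormalised, with provenance
#'   attributes) and `normalised` [global_grid()]s.
#' @export
build_plastic_layer <- function(paths) {
  stopifnot(length(paths) == 3)
  layers <- lapply(paths, read_plastic_csv)
  combined <- impute_band(combine_models(layers))
  list(combined = combined, normalised = normalize_unit_sum(combined))
}
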