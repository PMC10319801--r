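#' Spherical centroid of a point set
#'
#' The normalised mean of the unit vectors of the locations — the
#' "geometric mean position" used to centre the equal-area projection for
#' each population-month. If the mean vector is numerically degenerate
#' (e.g. an antipodally symmetric set) the first point is used and a
#' warning is emitted.
#'
#' @param lon,lat coordinates in degrees.
#' @return a named numeric vector `c(lon = , lat = )`.
#' @export
spherical_centroid <- function(lon, lat) {
  check_lonlat(lon, lat)
  stopifnot(length(lon) >= 1)
  rad <- pi / 180
  x <- mean(cos(lat * rad) * cos(lon * rad))
  y <- mean(cos(lat * rad) * sin(lon * rad))
  z <- mean(sin(lat * rad))
  n <- sqrt(x^2 + y^2 + z^2)
  if (n < 1e-9) {
    warning("degenerate spherical centroid; falling back to first point",
            call. = FALSE)
    return(c(lon = wrap_lon(lon[1]), lat = lat[1]))
  }
  c(lon = atan2(y, x) / rad, lat = asin(z / n) / rad)
}

EARTH_RADIUS_KM <- 6371

#' Lambert azimuthal equal-area projection (spherical)
#'
#' Forward and inverse spherical Lambert azimuthal equal-area projection
#' in kilometres, centred on an arbitrary point. Equal-area means planar
#' cell areas equal true areas, which is what makes kernel densities on
#' the projected plane meaningful as time-spent estimates.
#'
#' @param lon,lat coordinates in degrees.
#' @param center projection centre, `c(lon, lat)` in degrees.
#' @return `project_laea`: a two-column matrix `x`, `y` in km.
#' @export
project_laea <- function(lon, lat, center) {
  check_lonlat(lon, lat)
  rad <- pi / 180
  lam <- lon * rad; phi <- lat * rad
  lam0 <- center[1] * rad; phi1 <- center[2] * rad
  denom <- 1 + sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / pmax(denom, 1e-12))
  cbind(x = EARTH_RADIUS_KM * kp * cos(phi) * sin(lam - lam0),
        y = EARTH_RADIUS_KM * kp *
          (cos(phi1) * sin(phi) - sin(phi1) * cos(phi) * cos(lam - lam0)))
}

#' @rdname project_laea
#' @param x,y planar coordinates in km.
#' @return `unproject_laea`: a two-column matrix `lon`, `lat` in degrees.
#' @export
unproject_laea <- function(x, y, center) {
  rad <- pi / 180
  lam0 <- center[1] * rad; phi1 <- center[2] * rad
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  phi <- ifelse(rho < 1e-12, phi1,
                asin(pmin(1, pmax(-1, cos(cc) * sin(phi1) +
                                    y * sin(cc) * cos(phi1) / rho))))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sin(cc),
                             rho * cos(phi1) * cos(cc) -
                               y * sin(phi1) * sin(cc)))
  cbind(lon = wrap_lon(lam / rad), lat = phi / rad)
}

#' Keep only population-months with enough locations
#'
#' Pools locations by population and calendar month (across individuals
#' and years) and drops groups with fewer than `n_min` locations, which
#' are too sparse for a meaningful kernel density.
#'
#' @param points preprocessed track tibble.
#' @param n_min minimum pooled locations per population-month (default 5).
#' @return the tibble restricted to retained groups, with a `month`
#'   column added.
#' @export
month_filter <- function(points, n_min = 5) {
  check_track(points)
  if (!nrow(points)) {
    points$month <- integer(0)
    return(points)
  }
  points$month <- as.integer(format(points$timestamp, "%m", tz = "UTC"))
  dplyr::filter(dplyr::group_by(points, .data$population_id, .data$month),
                dplyr::n() >= n_min) |>
    dplyr::ungroup()
}

#' Fixed-bandwidth Gaussian kernel utilisation distribution
#'
#' Bivariate Gaussian kernel density of projected locations, evaluated on
#' a square grid of `cell`-km cells whose centres lie on multiples of
#' `cell`, covering the points plus a margin of `margin_mult * h` on every
#' side. The kernel is isotropic with standard deviation `h` in both
#' planar axes (default 200 km, matching typical GLS positional error).
#' Per-cell probability mass is density times cell area.
#'
#' The kernel is separable, so the density grid is computed as an outer
#' product of per-axis Gaussian evaluations — algebraically identical to
#' the direct sum over points for every cell.
#'
#' @param xy two-column matrix of projected locations in km.
#' @param h smoothing bandwidth (kernel sd) in km.
#' @param cell grid cell side in km.
#' @param margin_mult grid margin in bandwidths beyond the point extent.
#' @param center projection centre `c(lon, lat)` recorded for
#'   back-projection.
#' @param population_id,month identifiers recorded on the result.
#' @return an object of class `fine_ud`: list with grid vectors `x`, `y`
#'   (cell centres, km), `density` (km^-2) and `mass` matrices indexed
#'   `[x, y]`, the projection `center`, and bookkeeping fields.
#' @export
kernel_ud <- function(xy, h = 200, cell = 10, margin_mult = 6,
                      center = c(0, 0), population_id = NA_character_,
                      month = NA_integer_) {
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 1, h > 0, cell > 0,
            margin_mult >= 3)
  margin <- margin_mult * h
  gx <- grid_axis(xy[, 1], cell, margin)
  gy <- grid_axis(xy[, 2], cell, margin)
  n <- nrow(xy)
  kx <- stats::dnorm(outer(gx, xy[, 1], "-"), sd = h)   # |gx| x n
  ky <- stats::dnorm(outer(gy, xy[, 2], "-"), sd = h)   # |gy| x n
  dens <- (kx %*% t(ky)) / n
  structure(list(population_id = population_id, month = month,
                 center = center, cell = cell, h = h,
                 x = gx, y = gy,
                 density = dens, mass = dens * cell^2,
                 isopleth_level = NA_real_,
                 isopleth_mask = NULL),
            class = "fine_ud")
}

grid_axis <- function(v, cell, margin) {
  lo <- floor((min(v) - margin) / cell) * cell
  hi <- ceiling((max(v) + margin) / cell) * cell
  seq(lo, hi, by = cell)
}

#' @export
print.fine_ud <- function(x, ...) {
  cat(sprintf(
    "<fine_ud> %s month %s: %d x %d cells of %g km, h = %g km, mass = %.6f%s\n",
    x$population_id, x$month, length(x$x), length(x$y), x$cell, x$h,
    sum(x$mass),
    if (!is.na(x$isopleth_level))
      sprintf(", %g%% isopleth applied", 100 * x$isopleth_level) else ""))
  invisible(x)
}

#' Restrict a utilisation distribution to its densest isopleth
#'
#' Selects the smallest set of highest-density cells whose mass reaches
#' `level` of the total (the classic 95% home-range contour) and zeroes
#' mass outside it. Ties at the boundary are broken in stable cell order;
#' retained masses are deliberately not renormalised — global
#' normalisation happens once, at exposure time.
#'
#' @param ud a `fine_ud`.
#' @param level isopleth level in (0, 1], default 0.95.
#' @return the masked `fine_ud` with `isopleth_mask` set.
#' @export
apply_isopleth <- function(ud, level = 0.95) {
  stopifnot(inherits(ud, "fine_ud"), level > 0, level <= 1,
            all(is.finite(ud$mass)))
  m <- as.vector(ud$mass)
  ord <- order(m, decreasing = TRUE)
  csum <- cumsum(m[ord])
  k <- which(csum >= level * sum(m))[1]
  mask <- logical(length(m))
  mask[ord[seq_len(k)]] <- TRUE
  mask <- matrix(mask, nrow = length(ud$x))
  ud$mass[!mask] <- 0
  ud$density[!mask] <- 0
  ud$isopleth_mask <- mask
  ud$isopleth_level <- level
  ud
}

#' Zero utilisation mass over land
#'
#' Sets mass to zero in every fine cell whose centre back-projects onto
#' land. These species do not forage terrestrially, so apparent density
#' over land is device error. The land layer is either a `global_grid`
#' mask (values >= 0.5 are land) or a list of lon/lat polygon matrices.
#'
#' @param ud a `fine_ud`.
#' @param land a [global_grid()] land mask or list of polygon matrices
#'   (two columns lon, lat, closed or open rings).
#' @return the trimmed `fine_ud`.
#' @export
trim_land <- function(ud, land) {
  stopifnot(inherits(ud, "fine_ud"))
  ctr <- fine_cell_centres(ud)
  if (inherits(land, "global_grid")) {
    idx <- grid_cell_index(ctr[, "lon"], ctr[, "lat"])
    v <- land$values[cbind(idx$row, idx$col)]
    on_land <- !is.na(v) & v >= 0.5
  } else if (is.list(land)) {
    on_land <- rep(FALSE, nrow(ctr))
    for (poly in land) {
      on_land <- on_land | mgcv::in.out(as.matrix(poly), ctr)
    }
  } else {
    stop("land must be a global_grid mask or a list of polygons")
  }
  ud$mass[matrix(on_land, nrow = length(ud$x))] <- 0
  ud$density[matrix(on_land, nrow = length(ud$x))] <- 0
  ud
}

fine_cell_centres <- function(ud) {
  xs <- rep(ud$x, times = length(ud$y))
  ys <- rep(ud$y, each = length(ud$x))
  unproject_laea(xs, ys, ud$center)
}

#' Aggregate a fine utilisation distribution onto the global grid
#'
#' Back-projects every fine cell centre to longitude/latitude and adds its
#' mass to the 1-degree cell containing it. Total mass is conserved
#' exactly; cells receiving no mass hold zero (not missing).
#'
#' @param ud a `fine_ud`.
#' @return an unnormalised [global_grid()].
#' @export
aggregate_to_global <- function(ud) {
  stopifnot(inherits(ud, "fine_ud"))
  ctr <- fine_cell_centres(ud)
  if (any(ctr[, "lat"] < -90 | ctr[, "lat"] > 90)) {
    stop("fine cell centre outside valid latitude range")
  }
  idx <- grid_cell_index(ctr[, "lon"], ctr[, "lat"])
  flat <- (idx$col - 1L) * 180L + idx$row
  g <- matrix(0, 180, 360)
  sums <- rowsum(as.vector(ud$mass), flat)
  g[as.integer(rownames(sums))] <- sums[, 1]
  global_grid(g)
}

#' Monthly utilisation distributions for every population
#'
#' The full density stage: filters sparse population-months, then for each
#' retained group projects the pooled locations onto an equal-area plane
#' centred on their spherical centroid, estimates the kernel UD, applies
#' the isopleth, trims land, and aggregates to the global 1-degree grid.
#'
#' @param points preprocessed track tibble (all populations).
#' @param land land layer for [trim_land()], or `NULL` to skip trimming.
#' @param h,cell,level kernel bandwidth (km), fine cell size (km) and
#'   isopleth level.
#' @param n_min minimum pooled locations per population-month.
#' @return a tibble with one row per population-month: `population_id`,
#'   `month`, `n`, and list-columns `fine` (`fine_ud`) and `global`
#'   ([global_grid()], unnormalised).
#' @export
monthly_uds <- function(points, land = NULL, h = 200, cell = 10,
                        level = 0.95, n_min = 5) {
  pts <- month_filter(points, n_min)
  if (!nrow(pts)) {
    return(tibble::tibble(population_id = character(), month = integer(),
                          n = integer(), fine = list(), global = list()))
  }
  groups <- split(pts, interaction(pts$population_id, pts$month,
                                   drop = TRUE))
  rows <- lapply(groups, function(g) {
    ctr <- spherical_centroid(g$lon, g$lat)
    xy <- project_laea(g$lon, g$lat, ctr)
    ud <- kernel_ud(xy, h = h, cell = cell, center = ctr,
                    population_id = g$population_id[1], month = g$month[1])
    ud <- apply_isopleth(ud, level)
    if (!is.null(land)) ud <- trim_land(ud, land)
    tibble::tibble(population_id = g$population_id[1], month = g$month[1],
                   n = nrow(g), fine = list(ud),
                   global = list(aggregate_to_global(ud)))
  })
  dplyr::bind_rows(rows)
}
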