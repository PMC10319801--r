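# Shared fixtures and independent oracles for the suite.

# Quick track-table builder
make_track <- function(lon, lat, hours, device = "GPS",
                       id = "ind1", pop = "pop1",
                       start = "2015-06-01 00:00:00") {
  tibble::tibble(
    individual_id = id,
    timestamp = as.POSIXct(start, tz = "UTC") + hours * 3600,
    lon = lon, lat = lat, device = device, population_id = pop)
}

# Independent haversine oracle (explicit formula, radius 6371 km)
hav_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Point at a bearing/distance from a start point (spherical law of cosines)
point_at <- function(lon, lat, bearing_deg, dist_km) {
  r <- pi / 180
  d <- dist_km / 6371
  b <- bearing_deg * r
  phi1 <- lat * r
  phi2 <- asin(sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(b))
  lam2 <- lon * r + atan2(sin(b) * sin(d) * cos(phi1),
                          cos(d) - sin(phi1) * sin(phi2))
  c(lon = ((lam2 / r + 180) %% 360) - 180, lat = phi2 / r)
}

# Brute-force KDE oracle: direct double loop over cells x points
kde_brute <- function(xy, gx, gy, h) {
  out <- matrix(0, length(gx), length(gy))
  n <- nrow(xy)
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      s <- 0
      for (k in seq_len(n)) {
        s <- s + stats::dnorm(gx[i], xy[k, 1], h) *
          stats::dnorm(gy[j], xy[k, 2], h)
      }
      out[i, j] <- s / n
    }
  }
  out
}

# Brute-force ray-casting point-in-polygon oracle
pip_oracle <- function(poly, x, y) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
  }
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Sparse global grid: values at given (lon, lat) cells, zero elsewhere
sparse_grid <- function(lon, lat, value, fill = 0) {
  m <- matrix(fill, 180, 360)
  idx <- grid_cell_index(lon, lat)
  m[cbind(idx$row, idx$col)] <- value
  global_grid(m)
}

# The demo scenario and its pipeline results are expensive enough to
# build once and share across test files.
.demo_cache <- new.env(parent = emptyenv())

get_demo <- function() {
  if (is.null(.demo_cache$demo)) .demo_cache$demo <- demo_world(42)
  .demo_cache$demo
}

get_demo_run <- function() {
  if (is.null(.demo_cache$run)) {
    dir <- file.path(tempdir(), "plasticrisk-demo")
    paths <- write_world(get_demo(), file.path(dir, "inputs"))
    cfg <- run_config(tracks = paths$tracks, colonies = paths$colonies,
                      plastic = paths$plastic, schedules = paths$schedules,
                      land = paths$land,
                      jurisdictions = paths$jurisdictions,
                      outdir = file.path(dir, "out"), seed = 42)
    .demo_cache$run <- run_pipeline(cfg)
    .demo_cache$paths <- paths
  }
  .demo_cache$run
}

get_demo_paths <- function() {
  get_demo_run()
  .demo_cache$paths
}
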