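test_that("spherical centroid is the normalised mean direction", {
  expect_equal(spherical_centroid(c(10, 20), c(0, 0)),
               c(lon = 15, lat = 0), tolerance = 1e-9)
  expect_equal(spherical_centroid(5, -30), c(lon = 5, lat = -30))
  # symmetric cross about the origin
  expect_equal(spherical_centroid(c(-10, 10, 0, 0), c(0, 0, -10, 10)),
               c(lon = 0, lat = 0), tolerance = 1e-9)
  # antipodal pair degenerates to the first point, with a warning
  expect_warning(ctr <- spherical_centroid(c(0, 180), c(0, 0)),
                 "degenerate")
  expect_equal(ctr, c(lon = 0, lat = 0))
})

test_that("equal-area projection round-trips and preserves distance at the centre", {
  ctr <- c(-42, 17)
  set.seed(3)
  lon <- runif(50, -80, 0); lat <- runif(50, -20, 50)
  xy <- project_laea(lon, lat, ctr)
  back <- unproject_laea(xy[, 1], xy[, 2], ctr)
  expect_equal(back[, "lon"], lon, tolerance = 1e-9)
  expect_equal(back[, "lat"], lat, tolerance = 1e-9)
  # planar distance from the origin equals great-circle distance (the
  # azimuthal property), to first order near the centre
  d_plane <- sqrt(rowSums(project_laea(-42.5, 17.4, ctr)^2))
  expect_equal(d_plane, great_circle_km(-42.5, 17.4, ctr[1], ctr[2]),
               tolerance = 1e-4)
})

test_that("kernel density hits the single-point closed form", {
  h <- 200
  ud <- kernel_ud(cbind(0, 0), h = h, cell = 10)
  peak <- max(ud$density)
  expect_equal(peak, 1 / (2 * pi * h^2), tolerance = 1e-12)
  expect_equal(ud$density[ud$x == 0, ud$y == 0], peak)
  expect_lte(sum(ud$mass), 1 + 1e-9)
})

test_that("two well-separated points give two modes of mass one half", {
  ud <- kernel_ud(rbind(c(-2500, 0), c(2500, 0)), h = 200, cell = 10)
  left <- sum(ud$mass[ud$x < 0, ])
  right <- sum(ud$mass[ud$x > 0, ])
  expect_equal(left, 0.5, tolerance = 1e-6)
  expect_equal(right, 0.5, tolerance = 1e-6)
})

test_that("separable KDE equals the brute-force double-loop oracle", {
  set.seed(7)
  xy <- cbind(runif(12, 0, 60), runif(12, -40, 20))
  ud <- kernel_ud(xy, h = 30, cell = 10, margin_mult = 3)
  oracle <- kde_brute(xy, ud$x, ud$y, h = 30)
  expect_lt(max(abs(ud$density - oracle)), 1e-12)
})

test_that("duplicating the sample leaves the density unchanged", {
  set.seed(8)
  xy <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  ud1 <- kernel_ud(xy, h = 50, cell = 10)
  ud2 <- kernel_ud(rbind(xy, xy), h = 50, cell = 10)
  expect_equal(ud2$density, ud1$density, tolerance = 1e-12)
})

test_that("the 95% isopleth keeps the smallest high-density cell set", {
  # uniform mass over 100 cells: exactly 95 survive
  ud <- kernel_ud(cbind(0, 0), h = 200, cell = 10)
  ud$mass <- matrix(0, length(ud$x), length(ud$y))
  ud$mass[1:10, 1:10] <- 1 / 100
  ud$density <- ud$mass / ud$cell^2
  out <- apply_isopleth(ud, 0.95)
  expect_equal(sum(out$isopleth_mask), 95)
  expect_equal(sum(out$mass), 0.95)
  # single-cell distribution is retained whole
  ud$mass[] <- 0; ud$mass[5, 5] <- 1
  ud$density <- ud$mass / ud$cell^2
  expect_equal(sum(apply_isopleth(ud, 0.95)$mass), 1)
})

test_that("the isotropic-Gaussian isopleth radius matches the Rayleigh quantile", {
  h <- 200
  ud <- apply_isopleth(kernel_ud(cbind(0, 0), h = h, cell = 10), 0.95)
  r_theory <- h * sqrt(2 * log(20))   # ~489.5 km
  centres <- expand.grid(x = ud$x, y = ud$y)
  r_mask <- sqrt(centres$x^2 + centres$y^2)[as.vector(ud$isopleth_mask)]
  expect_lt(abs(max(r_mask) - r_theory), ud$cell)
  full <- kernel_ud(cbind(0, 0), h = h, cell = 10)
  frac <- sum(ud$mass) / sum(full$mass)
  expect_gte(frac, 0.95)
  expect_lt(frac, 0.96)
})

test_that("land trimming zeroes exactly the masked cells", {
  ud <- kernel_ud(cbind(0, 0), h = 100, cell = 10, center = c(0, 0))
  ocean <- global_grid(0)
  expect_equal(trim_land(ud, ocean)$mass, ud$mass)
  land <- global_grid(1)
  expect_true(all(trim_land(ud, land)$mass == 0))
  # half-land world: retained mass equals the pre-trim mass over ocean
  half <- global_grid(0)
  half$values[, 181:360] <- 1   # land at positive longitudes
  tr <- trim_land(ud, half)
  ctr <- plasticrisk:::fine_cell_centres(ud)
  ocean_mass <- sum(ud$mass[matrix(ctr[, "lon"] < 0, nrow = length(ud$x))])
  expect_equal(sum(tr$mass), ocean_mass, tolerance = 1e-12)
})

test_that("aggregation to the global grid conserves mass and places it", {
  set.seed(11)
  xy <- cbind(runif(30, -300, 300), runif(30, -300, 300))
  ud <- kernel_ud(xy, h = 100, cell = 10, center = c(20, -30))
  g <- aggregate_to_global(ud)
  expect_equal(grid_sum(g), sum(ud$mass), tolerance = 1e-9)
  # tight cluster: everything in the centre cell
  ud1 <- kernel_ud(cbind(0, 0), h = 1, cell = 1, center = c(100.5, 10.5))
  g1 <- aggregate_to_global(ud1)
  idx <- grid_cell_index(100.5, 10.5)
  expect_gt(g1$values[idx$row, idx$col], 0.999)
  # assignment agrees with the per-centre oracle
  ctr <- plasticrisk:::fine_cell_centres(ud)
  idx <- grid_cell_index(ctr[, "lon"], ctr[, "lat"])
  oracle <- rowsum(as.vector(ud$mass),
                   paste(idx$row, idx$col))
  for (k in sample(nrow(oracle), 10)) {
    rc <- as.integer(strsplit(rownames(oracle)[k], " ")[[1]])
    expect_equal(g$values[rc[1], rc[2]], as.numeric(oracle[k, 1]),
                 tolerance = 1e-12)
  }
})

test_that("months with fewer than five pooled locations are dropped", {
  tr4 <- make_track(1:4, rep(0, 4), c(0, 12, 24, 36))
  tr5 <- make_track(1:5, rep(0, 5), c(0, 12, 24, 36, 48),
                    start = "2015-07-01 00:00:00")
  tr <- dplyr::bind_rows(tr4, tr5)
  out <- month_filter(tr, 5)
  expect_equal(unique(out$month), 7L)
  expect_equal(nrow(out), 5)
  expect_equal(nrow(month_filter(tr4[0, ], 5)), 0)
  expect_equal(nrow(month_filter(tr5, 5)), 5)
})

test_that("the aggregated 1-degree UD recovers known mixture weights", {
  set.seed(21)
  n <- 600; w <- 0.7
  from_a <- runif(n) < w
  xy <- cbind(ifelse(from_a, -1500, 1500) + rnorm(n, sd = 100),
              rnorm(n, sd = 100))
  ud <- kernel_ud(xy, h = 200, cell = 10, center = c(-150, 0))
  g <- aggregate_to_global(ud)
  df <- grid_to_df(g)
  mass_a <- sum(df$value[df$lon < -150]) / sum(df$value)
  se <- sqrt(w * (1 - w) / n)
  expect_lt(abs(mass_a - w), 3 * se + 0.01)
})
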