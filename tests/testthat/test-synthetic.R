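test_that("worlds are pure functions of seed and parameters", {
  w1 <- build_world(7)
  w2 <- build_world(7)
  expect_identical(w1$plastic_truth$values, w2$plastic_truth$values)
  expect_identical(w1$land_mask$values, w2$land_mask$values)
  expect_identical(w1$model_masks, w2$model_masks)
  w3 <- build_world(8)
  expect_false(identical(w1$plastic_truth$values, w3$plastic_truth$values))
})

test_that("world invariants hold: partition, positivity, mask structure", {
  w <- build_world(7)
  land <- w$land_mask$values >= 0.5
  truth <- w$plastic_truth$values
  expect_true(all(is.na(truth[land])))
  expect_true(all(truth[!land] > 0))
  n_missing <- Reduce(`+`, w$model_masks)
  expect_true(any(n_missing == 1))   # single-model gap
  expect_true(any(n_missing == 2))   # two-model gap
  expect_true(any(n_missing == 3))   # no model reports
})

test_that("degenerate parameters behave as documented", {
  # zero hotspot amplitude: no spatial trend beyond lognormal noise
  p0 <- world_params(hotspots = list(list(lon = -120, lat = 25, amp = 0,
                                          sigma_km = 1500)),
                     land_fraction = 0)
  w0 <- build_world(3, p0)
  expect_true(all(w0$land_mask$values == 0))
  lt <- log(w0$plastic_truth$values)
  near <- great_circle_km(rep(-120, 64800),
                          rep(25, 64800), -120, 25) < 1500
  near <- matrix(near, 180, 360)  # degenerate: recompute per cell below
  ctr <- grid_centres()
  lonm <- rep(ctr$lon, each = 180); latm <- rep(ctr$lat, times = 360)
  near <- matrix(great_circle_km(lonm, latm, -120, 25) < 1500, 180, 360)
  expect_lt(abs(mean(lt[near]) - mean(lt[!near])),
            4 * sd(lt) / sqrt(sum(near)))
  # invalid parameters are rejected
  expect_error(world_params(hotspots = list()), "hotspots")
  expect_error(world_params(land_fraction = -0.1))
})

test_that("breeding locations respect the foraging range by construction", {
  w <- build_world(5, world_params(land_fraction = 0))
  spec <- population_spec("p", "s", 0, 0, 100, 0, n_individuals = 3,
                          breeding_months = 6, tracked_months = 6,
                          max_foraging_range = 300, device = "GPS",
                          sampling_interval = 6, location_error_sd = 0)
  tr <- simulate_population_tracks(w, spec, 2)
  d <- great_circle_km(tr$lon, tr$lat, 0, 0)
  expect_true(all(d <= 300 + 1e-6))
})

test_that("non-breeding months are farther from the colony than breeding", {
  w <- build_world(5, world_params(land_fraction = 0))
  wint <- point_at(0, 0, 90, 8000)
  spec <- population_spec("p", "s", 0, 0, wint["lon"], wint["lat"],
                          n_individuals = 4, breeding_months = 4:9,
                          tracked_months = 1:12, max_foraging_range = 400,
                          device = "GLS", location_error_sd = 200)
  tr <- simulate_population_tracks(w, spec, 2)
  d <- great_circle_km(tr$lon, tr$lat, 0, 0)
  m <- as.integer(format(tr$timestamp, "%m", tz = "UTC"))
  br <- m %in% 4:9
  expect_gt(mean(tapply(d[!br], m[!br], mean)),
            mean(tapply(d[br], m[br], mean)))
})

test_that("tracks are seeded deterministically; zero individuals give none", {
  w <- build_world(5, world_params(land_fraction = 0))
  spec <- population_spec("p", "s", 0, 0, 50, 10, n_individuals = 2,
                          tracked_months = c(3, 7))
  expect_identical(simulate_population_tracks(w, spec, 11),
                   simulate_population_tracks(w, spec, 11))
  spec0 <- population_spec("p", "s", 0, 0, 50, 10, n_individuals = 0)
  expect_equal(nrow(simulate_population_tracks(w, spec0, 11)), 0)
})

test_that("a colony on land with no ocean neighbour is rejected", {
  w <- build_world(5)   # default continents
  spec <- population_spec("p", "s", -60.5, 0.5, 50, 10)  # mid-continent
  expect_error(simulate_population_tracks(w, spec, 1), "ocean")
})

test_that("model layers are noisy copies of the truth with masks applied", {
  w <- build_world(9, world_params(noise_sdlog = 0))
  ls <- derive_model_layers(w, 1)
  joint <- !Reduce(`|`, w$model_masks) & !is.na(w$plastic_truth$values)
  # zero noise: layers equal the truth where observed
  for (k in 1:3) {
    obs <- !w$model_masks[[k]] & !is.na(w$plastic_truth$values)
    expect_equal(ls[[k]]$values[obs], w$plastic_truth$values[obs])
    expect_true(all(is.na(ls[[k]]$values[w$model_masks[[k]]])))
  }
  gm <- combine_models(ls)
  expect_equal(gm$values[joint], w$plastic_truth$values[joint],
               tolerance = 1e-12)
})

test_that("per-cell geometric mean across seeds converges to the truth", {
  w <- build_world(9)   # noise_sdlog 0.5
  truth <- w$plastic_truth$values
  cells <- which(!is.na(truth) & !Reduce(`|`, w$model_masks))[1:5]
  n_seeds <- 200
  logs <- matrix(0, n_seeds, length(cells))
  for (s in seq_len(n_seeds)) {
    ls <- derive_model_layers(w, 1000 + s)
    gm <- exp((log(ls[[1]]$values[cells]) + log(ls[[2]]$values[cells]) +
                 log(ls[[3]]$values[cells])) / 3)
    logs[s, ] <- log(gm)
  }
  # noise has median 1, so E[log layer] = log truth; the mean over seeds
  # of log gm estimates log truth with se = sdlog / sqrt(3 n)
  se <- w$params$noise_sdlog / sqrt(3 * n_seeds)
  for (j in seq_along(cells)) {
    expect_lt(abs(mean(logs[, j]) - log(truth[cells[j]])), 3 * se)
  }
})

test_that("the demo world exercises every preprocessing rule", {
  demo <- get_demo()
  tr <- demo$tracks
  # GLS fixes inside equinox windows
  gls <- tr[tr$device == "GLS", ]
  expect_gt(nrow(gls) - nrow(strip_equinox(gls)), 0)
  # GPS fixes within the colony buffer
  gps <- tr[tr$population_id == "alba_gps", ]
  colony <- demo$colonies[demo$colonies$population_id == "alba_gps", ]
  d <- great_circle_km(gps$lon, gps$lat, colony$lon, colony$lat)
  expect_gt(sum(d < 5), 0)
  # injected speed outliers exceed 90 km/h
  ind <- gps[gps$individual_id == "alba_gps_ind01", ]
  ind <- ind[order(ind$timestamp), ]
  sp <- great_circle_km(ind$lon[-1], ind$lat[-1],
                        ind$lon[-nrow(ind)], ind$lat[-nrow(ind)]) /
    as.numeric(diff(ind$timestamp), units = "hours")
  expect_gt(sum(sp > 90), 0)
  # a population-month with fewer than five locations
  m <- format(tr$timestamp, "%m")
  counts <- table(paste(tr$population_id, m))
  expect_true(any(counts < 5))
})

test_that("an end-to-end hotspot population outscores a cold-water one", {
  # two populations identical except for where they winter
  w <- build_world(5, world_params(land_fraction = 0))
  hot <- w$params$hotspots[[1]]
  mk <- function(id, wlon, wlat) {
    population_spec(id, "s", 0.5, 0.5, wlon, wlat, n_individuals = 6,
                    breeding_months = 5:8, tracked_months = 1:12,
                    max_foraging_range = 400, device = "GLS",
                    location_error_sd = 185)
  }
  tr_hot <- simulate_population_tracks(w, mk("hot", hot$lon, hot$lat), 3)
  tr_cold <- simulate_population_tracks(w, mk("cold", 40, -60), 3)
  ls <- derive_model_layers(w, 4)
  plastic <- normalize_unit_sum(impute_band(combine_models(ls)))
  score_of <- function(tr) {
    uds <- monthly_uds(tr, land = w$land_mask)
    monthly <- vapply(uds$global, function(g)
      exposure_score(exposure_map(normalize_unit_sum(g), plastic)), 0)
    mean(monthly)
  }
  expect_gt(score_of(tr_hot), score_of(tr_cold))
})
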