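#' Parameters for a synthetic world
#'
#' Defines the toy planet used to exercise the pipeline without
#' restricted tracking data: rectangular continents, a patchy lognormal
#' ocean plastic field with Gaussian gyre-like hotspots (multiplicative,
#' i.e. added in log space), per-model missing-data masks, and a small set
#' of rectangular maritime jurisdictions.
#'
#' @param land_fraction scale factor in `[0, 1]` applied to the extent of
#'   the toy continents about their centres; 0 removes all land.
#' @param land_rects list of `c(lon_min, lon_max, lat_min, lat_max)`
#'   continent rectangles.
#' @param plastic_meanlog,plastic_sdlog log-scale mean and sd of the
#'   background plastic field (pieces per km^2).
#' @param hotspots list of hotspots, each
#'   `list(lon =, lat =, amp =, sigma_km =)`; `amp` is the log-scale peak
#'   elevation (amp 0 leaves the field homogeneous up to lognormal
#'   noise), `sigma_km` the Gaussian e-folding scale.
#' @param model_missing_frac random missing fraction per model layer.
#' @param noise_sdlog sd of the per-model multiplicative lognormal noise
#'   (median 1) used by [derive_model_layers()].
#' @return a list of class `world_params`.
#' @export
world_params <- function(land_fraction = 1,
                         land_rects = list(c(-70, -50, -35, 40),
                                           c(20, 45, -10, 55)),
                         plastic_meanlog = log(200),
                         plastic_sdlog = 0.8,
                         hotspots = list(list(lon = -120, lat = 25,
                                              amp = log(60),
                                              sigma_km = 1500)),
                         model_missing_frac = 0.02,
                         noise_sdlog = 0.5) {
  stopifnot(land_fraction >= 0, land_fraction <= 1,
            plastic_sdlog >= 0, length(hotspots) >= 1,
            model_missing_frac >= 0, model_missing_frac < 1,
            noise_sdlog >= 0)
  for (hs in hotspots) {
    stopifnot(all(c("lon", "lat", "amp", "sigma_km") %in% names(hs)),
              hs$sigma_km > 0, hs$amp >= 0)
  }
  structure(list(land_fraction = land_fraction, land_rects = land_rects,
                 plastic_meanlog = plastic_meanlog,
                 plastic_sdlog = plastic_sdlog, hotspots = hotspots,
                 model_missing_frac = model_missing_frac,
                 noise_sdlog = noise_sdlog),
            class = "world_params")
}

#' Build a seeded synthetic world
#'
#' Deterministic in `(seed, params)`: land mask, strictly positive
#' plastic-density truth on ocean cells, three per-model missing masks
#' (polar coverage gaps of different extents plus random dropout,
#' guaranteeing cells missing in exactly one, exactly two and all three
#' models), and a toy jurisdiction layer with two single-sovereign EEZs,
#' a theoretical EEZ and a two-sovereign joint regime.
#'
#' @param seed integer RNG seed.
#' @param params a [world_params()].
#' @return an object of class `synthetic_world`.
#' @export
build_world <- function(seed, params = world_params()) {
  stopifnot(inherits(params, "world_params"))
  withr::with_seed(as.integer(seed), {
    land <- land_mask_from_rects(params$land_rects, params$land_fraction)
    ctr <- grid_centres()
    lonm <- matrix(rep(ctr$lon, each = 180), 180, 360)
    latm <- matrix(rep(ctr$lat, times = 360), 180, 360)
    logf <- params$plastic_meanlog +
      stats::rnorm(180 * 360, sd = params$plastic_sdlog)
    logf <- matrix(logf, 180, 360)
    for (hs in params$hotspots) {
      d <- great_circle_km(as.vector(lonm), as.vector(latm), hs$lon, hs$lat)
      logf <- logf + hs$amp * matrix(exp(-d^2 / (2 * hs$sigma_km^2)),
                                     180, 360)
    }
    truth <- exp(logf)
    truth[land$values >= 0.5] <- NA_real_
    masks <- model_masks(latm, params$model_missing_frac)
    world <- structure(
      list(seed = as.integer(seed), params = params,
           land_mask = land,
           plastic_truth = global_grid(truth),
           model_masks = masks,
           jurisdictions = toy_jurisdictions(),
           colonies = NULL),
      class = "synthetic_world")
    world
  })
}

land_mask_from_rects <- function(rects, fraction) {
  ctr <- grid_centres()
  m <- matrix(0, 180, 360)
  if (fraction > 0) {
    for (r in rects) {
      clon <- (r[1] + r[2]) / 2; clat <- (r[3] + r[4]) / 2
      half_lon <- fraction * (r[2] - r[1]) / 2
      half_lat <- fraction * (r[4] - r[3]) / 2
      in_lon <- ctr$lon >= clon - half_lon & ctr$lon <= clon + half_lon
      in_lat <- ctr$lat >= clat - half_lat & ctr$lat <= clat + half_lat
      m[in_lat, in_lon] <- 1
    }
  }
  global_grid(m)
}

# Three missing masks (TRUE = missing). Polar bands of different extents
# guarantee regions missing in exactly one (70-75 deg), exactly two
# (75-85 deg) and all three (above 85 deg) models.
model_masks <- function(latm, frac) {
  base <- list(abs(latm) > 75, abs(latm) > 70, abs(latm) > 85)
  lapply(base, function(b) {
    b | matrix(stats::runif(length(latm)) < frac, nrow = nrow(latm))
  })
}

toy_jurisdictions <- function() {
  rectp <- function(lon0, lon1, lat0, lat1) {
    cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
          lat = c(lat0, lat0, lat1, lat1, lat0))
  }
  jurisdiction_layer(
    names = c("Alba EEZ", "Bruma EEZ", "Cerulea theoretical EEZ",
              "Bruma-Cerulea joint regime"),
    sovereigns = list("Alba", "Bruma", "Cerulea", c("Bruma", "Cerulea")),
    categories = c("EEZ", "EEZ", "theoretical-EEZ", "joint-regime"),
    polygons = list(rectp(-50, -40, 10, 40),
                    rectp(-50, -40, -10, 10),
                    rectp(-130, -115, 20, 35),
                    rectp(-115, -108, 18, 32)))
}

#' Population specification for the track simulator
#'
#' Describes one synthetic breeding population: where it breeds and
#' winters, how many individuals carry which device on what schedule, and
#' its metadata (size, country, threat category).
#'
#' @param population_id,species_id identifiers.
#' @param colony_lon,colony_lat colony coordinates (degrees); the colony
#'   cell must be ocean or have an ocean neighbour.
#' @param wintering_lon,wintering_lat centroid of the non-breeding range.
#' @param n_individuals number of tracked individuals.
#' @param breeding_months integer months (1-12) of the breeding season.
#' @param tracked_months months with device data (defaults to all 12; a
#'   breeding-only deployment passes `breeding_months`).
#' @param max_foraging_range maximum distance (km) from the colony during
#'   breeding trips, before location error.
#' @param nonbreeding_spread sd (km) of the stationary scatter around the
#'   wintering centroid.
#' @param device `GPS`, `PTT` or `GLS`.
#' @param sampling_interval hours between fixes.
#' @param location_error_sd isotropic positional error sd in km (about
#'   200 for GLS, near zero for GPS).
#' @param population_size breeding pairs (may be `NA`).
#' @param breeding_country,iucn_category metadata.
#' @return a list of class `population_spec`.
#' @export
population_spec <- function(population_id, species_id,
                            colony_lon, colony_lat,
                            wintering_lon, wintering_lat,
                            n_individuals = 10,
                            breeding_months = 4:9,
                            tracked_months = 1:12,
                            max_foraging_range = 500,
                            nonbreeding_spread = 400,
                            device = c("GLS", "GPS", "PTT"),
                            sampling_interval = 12,
                            location_error_sd = 200,
                            population_size = NA_real_,
                            breeding_country = NA_character_,
                            iucn_category = "LC") {
  device <- match.arg(device)
  check_lonlat(colony_lon, colony_lat)
  check_lonlat(wintering_lon, wintering_lat)
  stopifnot(n_individuals >= 0,
            all(breeding_months %in% 1:12),
            all(tracked_months %in% 1:12),
            max_foraging_range >= 0, nonbreeding_spread >= 0,
            sampling_interval > 0, location_error_sd >= 0,
            iucn_category %in% c("LC", "NT", "VU", "EN", "CR"))
  structure(as.list(environment()), class = "population_spec")
}

dest_km <- function(lon, lat, bearing, dist_km) {
  out <- geosphere::destPoint(cbind(lon, lat), bearing, dist_km * 1000,
                              a = 6371000, f = 0)
  colnames(out) <- c("lon", "lat")
  out
}

#' Simulate tracks for one population
#'
#' Central-place movement during breeding months: each individual makes
#' repeated out-and-back foraging trips from the colony (a random-bearing
#' trajectory whose colony distance rises and falls sinusoidally over the
#' trip, with the bearing drifting as a random walk), never exceeding
#' `max_foraging_range` before location error; short colony-attendance
#' bouts separate trips. Non-breeding months: stationary first-order
#' autoregressive scatter around the wintering centroid. Fixes are taken
#' every `sampling_interval` hours through each tracked month of one
#' calendar year (2015), then perturbed by isotropic Gaussian location
#' error; GLS deployments therefore naturally include equinox-window
#' locations, so the equinox filter is exercised.
#'
#' @param world a `synthetic_world`.
#' @param spec a [population_spec()].
#' @param seed integer seed (independent of the world seed).
#' @return a track tibble (columns as in [standardise_track()], plus
#'   `species_id`).
#' @export
simulate_population_tracks <- function(world, spec, seed) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(spec, "population_spec"))
  check_colony_near_ocean(world, spec)
  if (spec$n_individuals == 0) return(empty_track())
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(spec$n_individuals), function(i) {
      simulate_individual(spec, i)
    })
    dplyr::bind_rows(rows)
  })
}

empty_track <- function() {
  tibble::tibble(individual_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 lon = numeric(), lat = numeric(), device = character(),
                 population_id = character(), species_id = character())
}

check_colony_near_ocean <- function(world, spec) {
  idx <- grid_cell_index(spec$colony_lon, spec$colony_lat)
  rows <- pmax(1, pmin(180, idx$row + (-1:1)))
  cols <- ((idx$col + (-1:1) - 1) %% 360) + 1
  cells <- expand.grid(r = rows, c = cols)
  vals <- world$land_mask$values[cbind(cells$r, cells$c)]
  if (all(vals >= 0.5)) {
    stop("colony is on land with no ocean neighbour in this world")
  }
  invisible(TRUE)
}

simulate_individual <- function(spec, i) {
  year <- 2015
  pieces <- lapply(sort(unique(spec$tracked_months)), function(m) {
    t0 <- as.POSIXct(sprintf("%d-%02d-01", year, m), tz = "UTC")
    t1 <- if (m < 12) as.POSIXct(sprintf("%d-%02d-01", year, m + 1),
                                 tz = "UTC") else
      as.POSIXct(sprintf("%d-01-01", year + 1), tz = "UTC")
    n <- floor(as.numeric(difftime(t1, t0, units = "hours")) /
                 spec$sampling_interval)
    times <- t0 + (seq_len(n) - 1) * spec$sampling_interval * 3600
    pos <- if (m %in% spec$breeding_months) {
      breeding_positions(spec, n)
    } else {
      nonbreeding_positions(spec, n)
    }
    tibble::tibble(timestamp = times, lon = pos[, "lon"], lat = pos[, "lat"])
  })
  tr <- dplyr::bind_rows(pieces)
  if (spec$location_error_sd > 0) {
    dx <- stats::rnorm(nrow(tr), sd = spec$location_error_sd)
    dy <- stats::rnorm(nrow(tr), sd = spec$location_error_sd)
    p <- dest_km(tr$lon, tr$lat, atan2(dx, dy) * 180 / pi,
                 sqrt(dx^2 + dy^2))
    tr$lon <- p[, "lon"]; tr$lat <- p[, "lat"]
  }
  tr$lat <- pmin(90, pmax(-90, tr$lat))
  tr$lon <- wrap_lon(tr$lon)
  tibble::tibble(individual_id = sprintf("%s_ind%02d", spec$population_id, i),
                 timestamp = tr$timestamp, lon = tr$lon, lat = tr$lat,
                 device = spec$device, population_id = spec$population_id,
                 species_id = spec$species_id)
}

# Out-and-back trips: colony distance follows a sine over each trip,
# bearing drifts as a random walk; 1-3 fixes of colony attendance
# between trips.
breeding_positions <- function(spec, n) {
  lon <- numeric(0); lat <- numeric(0)
  while (length(lon) < n) {
    rest <- sample(1:3, 1)
    lon <- c(lon, rep(spec$colony_lon, rest))
    lat <- c(lat, rep(spec$colony_lat, rest))
    len <- sample(4:14, 1)
    frac <- stats::runif(1, 0.3, 1)
    bearing <- stats::runif(1, 0, 360) +
      cumsum(stats::rnorm(len, sd = 12))
    d <- frac * spec$max_foraging_range * sin(pi * seq_len(len) / (len + 1))
    p <- dest_km(spec$colony_lon, spec$colony_lat, bearing, d)
    lon <- c(lon, p[, "lon"]); lat <- c(lat, p[, "lat"])
  }
  cbind(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}

nonbreeding_positions <- function(spec, n) {
  phi <- 0.85
  innov <- spec$nonbreeding_spread * sqrt(1 - phi^2)
  ox <- stats::filter(stats::rnorm(n, sd = innov), phi, "recursive",
                      init = stats::rnorm(1, sd = spec$nonbreeding_spread))
  oy <- stats::filter(stats::rnorm(n, sd = innov), phi, "recursive",
                      init = stats::rnorm(1, sd = spec$nonbreeding_spread))
  dest_km(spec$wintering_lon, spec$wintering_lat,
          atan2(ox, oy) * 180 / pi, sqrt(ox^2 + oy^2))
}

#' Derive the three plastic model layers from a world
#'
#' Each layer is the plastic truth multiplied by independent cellwise
#' lognormal noise with median one (log-sd `params$noise_sdlog`), with
#' that model's missing mask applied — emulating three transport models
#' that agree up to log-scale scatter and differ in spatial coverage.
#'
#' @param world a `synthetic_world`.
#' @param seed integer seed.
#' @return a list of three [global_grid()] layers.
#' @export
derive_model_layers <- function(world, seed) {
  stopifnot(inherits(world, "synthetic_world"))
  truth <- world$plastic_truth$values
  withr::with_seed(as.integer(seed), {
    lapply(world$model_masks, function(mask) {
      noise <- exp(matrix(stats::rnorm(length(truth),
                                       sd = world$params$noise_sdlog),
                          nrow = nrow(truth)))
      v <- truth * noise
      v[mask] <- NA_real_
      global_grid(v)
    })
  })
}

#' The demo world: two species, three populations
#'
#' The packaged end-to-end scenario. Species S1 (country Alba) has a
#' year-round GLS population wintering in low-plastic southern waters and
#' a breeding-season-only GPS population (which therefore gets a 0.5
#' coverage weight); species S2 (country Bruma) winters inside the
#' plastic hotspot. The generated data exercise every preprocessing rule:
#' GLS fixes inside equinox windows, GPS fixes at the colony, injected
#' teleport spikes that trip the speed filter, and one stray month with
#' fewer than five locations. The published schedules deliberately label
#' one post-departure month as breeding so the reconciliation override
#' fires.
#'
#' @param seed integer seed driving the world, the tracks and the model
#'   layers.
#' @return a list with `world`, `tracks`, `colonies`, `schedules`,
#'   `model_layers` and the `specs` used.
#' @export
demo_world <- function(seed = 42) {
  seed <- as.integer(seed)
  world <- build_world(seed)
  specs <- list(
    population_spec("alba_north", "S1", -49.5, 20.5, -15, -42,
                    n_individuals = 18, breeding_months = 4:9,
                    tracked_months = 1:12, max_foraging_range = 400,
                    nonbreeding_spread = 500, device = "GLS",
                    sampling_interval = 12, location_error_sd = 185,
                    population_size = 20000, breeding_country = "Alba",
                    iucn_category = "LC"),
    population_spec("alba_gps", "S1", -49.5, 32.5, -20, -35,
                    n_individuals = 12, breeding_months = 5:8,
                    tracked_months = 5:8, max_foraging_range = 300,
                    nonbreeding_spread = 400, device = "GPS",
                    sampling_interval = 2, location_error_sd = 0.05,
                    population_size = 6000, breeding_country = "Alba",
                    iucn_category = "LC"),
    population_spec("bruma_south", "S2", -49.5, 5.5, -120, 25,
                    n_individuals = 16,
                    breeding_months = c(11, 12, 1, 2),
                    tracked_months = 1:12, max_foraging_range = 450,
                    nonbreeding_spread = 600, device = "GLS",
                    sampling_interval = 12, location_error_sd = 185,
                    population_size = 9000, breeding_country = "Bruma",
                    iucn_category = "VU"))
  tracks <- dplyr::bind_rows(lapply(seq_along(specs), function(k) {
    simulate_population_tracks(world, specs[[k]], seed + k)
  }))
  tracks <- withr::with_seed(seed + 100, inject_artefacts(tracks, specs))
  colonies <- tibble::tibble(
    population_id = vapply(specs, `[[`, "", "population_id"),
    species_id = vapply(specs, `[[`, "", "species_id"),
    colony_lon = vapply(specs, `[[`, 0, "colony_lon"),
    colony_lat = vapply(specs, `[[`, 0, "colony_lat"),
    breeding_country = vapply(specs, `[[`, "", "breeding_country"),
    population_size = vapply(specs, `[[`, 0, "population_size"),
    iucn_category = vapply(specs, `[[`, "", "iucn_category"),
    equinox_prefiltered = FALSE)
  colonies$lon <- colonies$colony_lon
  colonies$lat <- colonies$colony_lat
  schedules <- demo_schedules(specs)
  world$colonies <- colonies
  list(world = world, tracks = tracks, colonies = colonies,
       schedules = schedules,
       model_layers = derive_model_layers(world, seed + 200),
       specs = specs)
}

# Teleport spikes for the GPS population (speed filter fodder) and one
# stray under-sampled month (month filter fodder).
inject_artefacts <- function(tracks, specs) {
  gps <- which(tracks$population_id == "alba_gps")
  if (length(gps)) {
    spike <- sample(gps, min(25, length(gps)))
    p <- dest_km(tracks$lon[spike], tracks$lat[spike],
                 stats::runif(length(spike), 0, 360), 600)
    tracks$lon[spike] <- p[, "lon"]
    tracks$lat[spike] <- p[, "lat"]
  }
  stray <- tibble::tibble(
    individual_id = "alba_gps_stray",
    timestamp = as.POSIXct(c("2015-11-10 00:00:00", "2015-11-10 12:00:00",
                             "2015-11-11 00:00:00"), tz = "UTC"),
    lon = -45.5, lat = 31.5, device = "GPS",
    population_id = "alba_gps", species_id = "S1")
  dplyr::bind_rows(tracks, stray)
}

# Published schedules: the specs' breeding months, plus one deliberate
# mismatch for alba_north (October published as breeding although tracked
# birds have departed), so reconciliation is exercised.
demo_schedules <- function(specs) {
  rows <- lapply(specs, function(s) {
    lab <- ifelse(1:12 %in% s$breeding_months, "breeding", "non-breeding")
    if (s$population_id == "alba_north") lab[10] <- "breeding"
    tibble::tibble(population_id = s$population_id, month = 1:12,
                   label = lab)
  })
  dplyr::bind_rows(rows)
}

#' Write a synthetic scenario to disk
#'
#' Serialises a [demo_world()]-style scenario as the plain-text inputs
#' the pipeline reads: standardised tracking CSV, colony metadata CSV,
#' published schedule CSV, three plastic model CSVs, a land-mask CSV and
#' a jurisdictions GeoJSON.
#'
#' @param demo list from [demo_world()].
#' @param dir output directory (created if needed).
#' @return a named list of file paths, ready to splice into
#'   [run_config()].
#' @export
write_world <- function(demo, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tracks = file.path(dir, "tracks.csv"),
    colonies = file.path(dir, "colonies.csv"),
    schedules = file.path(dir, "schedules.csv"),
    plastic = file.path(dir, paste0("plastic_model_", 1:3, ".csv")),
    land = file.path(dir, "land.csv"),
    jurisdictions = file.path(dir, "jurisdictions.geojson"))
  write_tracks(demo$tracks, paths$tracks)
  readr::write_csv(demo$colonies[, c("population_id", "species_id",
                                     "colony_lon", "colony_lat",
                                     "breeding_country", "population_size",
                                     "iucn_category",
                                     "equinox_prefiltered")],
                   paths$colonies)
  readr::write_csv(demo$schedules, paths$schedules)
  for (k in 1:3) {
    df <- grid_to_df(demo$model_layers[[k]])
    names(df)[3] <- "density"
    readr::write_csv(df, paths$plastic[k])
  }
  write_grid_csv(demo$world$land_mask, paths$land)
  write_jurisdictions_geojson(demo$world$jurisdictions,
                              paths$jurisdictions)
  paths
}
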