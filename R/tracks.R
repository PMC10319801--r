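#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, the workhorse behind
#' the speed filter, the colony-buffer trim and all distance-to-colony
#' statistics. Vectorised over both endpoints.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; longitudes in
#'   `[-180, 180)` (other conventions are wrapped), latitudes in
#'   `[-90, 90]`.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  geosphere::distHaversine(cbind(wrap_lon(lon1), lat1),
                           cbind(wrap_lon(lon2), lat2),
                           r = 6371)
}

#' Preprocessing configuration for tracking data
#'
#' Bundles the quality-control thresholds applied to raw locations:
#' the speed filter for GPS/PTT, per-device colony-buffer radii, the GLS
#' equinox exclusion windows, the common resampling interval, and the
#' minimum number of pooled locations a population-month needs to be kept.
#'
#' @param speed_max maximum plausible travel speed, km/h; locations
#'   implying a faster move from the previously retained point are dropped
#'   (strictly greater than).
#' @param colony_buffer named numeric vector of per-device buffer radii in
#'   km; locations closer than this to the colony are dropped. GLS
#'   positions are never trimmed (their error dwarfs any sensible buffer).
#' @param resample_interval target interval in hours for linear
#'   resampling of GPS and PTT tracks (GLS data already arrive at about
#'   two positions per day and pass through untouched).
#' @param equinox_windows list with `march = c(before, after)` and
#'   `september = c(before, after)` window extents in days around the
#'   20 March and 22 September equinoxes.
#' @param min_locations_per_month population-months pooled across
#'   individuals and years with fewer locations than this are discarded.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(speed_max = 90,
                              colony_buffer = c(GPS = 5, PTT = 15, GLS = 0),
                              resample_interval = 12,
                              equinox_windows = list(march = c(21, 7),
                                                     september = c(7, 21)),
                              min_locations_per_month = 5) {
  stopifnot(speed_max >= 0, all(colony_buffer >= 0),
            resample_interval > 0,
            all(unlist(equinox_windows) >= 0),
            min_locations_per_month >= 0)
  structure(list(speed_max = speed_max,
                 colony_buffer = colony_buffer,
                 resample_interval = resample_interval,
                 equinox_windows = equinox_windows,
                 min_locations_per_month = min_locations_per_month),
            class = "preprocess_config")
}

track_cols <- c("individual_id", "timestamp", "lon", "lat", "device",
                "population_id")

check_track <- function(track) {
  miss <- setdiff(track_cols, names(track))
  if (length(miss)) stop("track table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(track)) check_lonlat(track$lon, track$lat)
  invisible(TRUE)
}

#' Standardise a raw track table
#'
#' Sorts by individual and time, drops rows with duplicated
#' (individual, timestamp) pairs keeping the first occurrence, and wraps
#' longitudes to `[-180, 180)`. After this step each individual's
#' timestamps are strictly increasing.
#'
#' @param track a track tibble with columns `individual_id`, `timestamp`
#'   (POSIXct UTC), `lon`, `lat`, `device` (GPS/PTT/GLS), `population_id`.
#' @return the standardised tibble.
#' @export
standardise_track <- function(track) {
  check_track(track)
  track <- dplyr::arrange(track, .data$individual_id, .data$timestamp)
  track <- dplyr::distinct(track, .data$individual_id, .data$timestamp,
                           .keep_all = TRUE)
  track$lon <- wrap_lon(track$lon)
  track
}

#' Drop locations implying unrealistic travel speeds
#'
#' Forward pass per individual: a location whose implied speed from the
#' previously *retained* location strictly exceeds `speed_max` is dropped,
#' and the next speed is computed from the last retained point. Each
#' individual's first location seeds the pass. Only GPS and PTT locations
#' are tested; GLS positions pass through untouched (their error makes
#' point-to-point speeds meaningless).
#'
#' @param track a standardised track tibble (chronological per individual).
#' @param speed_max threshold in km/h (default 90).
#' @return the filtered tibble.
#' @export
filter_speed <- function(track, speed_max = 90) {
  check_track(track)
  if (!nrow(track)) return(track)
  keep <- rep(TRUE, nrow(track))
  for (id in unique(track$individual_id)) {
    ii <- which(track$individual_id == id)
    if (!(track$device[ii[1]] %in% c("GPS", "PTT"))) next
    last <- ii[1]
    for (k in ii[-1]) {
      dt_h <- as.numeric(difftime(track$timestamp[k], track$timestamp[last],
                                  units = "hours"))
      d_km <- great_circle_km(track$lon[last], track$lat[last],
                              track$lon[k], track$lat[k])
      if (dt_h > 0 && d_km / dt_h > speed_max) {
        keep[k] <- FALSE
      } else {
        last <- k
      }
    }
  }
  track[keep, , drop = FALSE]
}

equinox_window_bounds <- function(years, windows) {
  mk <- function(dates, before, after) {
    e <- as.POSIXct(dates, tz = "UTC")
    list(from = e - before * 86400, to = e + after * 86400)
  }
  list(
    march = mk(sprintf("%d-03-20", years),
               windows$march[1], windows$march[2]),
    september = mk(sprintf("%d-09-22", years),
                   windows$september[1], windows$september[2]))
}

#' Remove GLS locations around the equinoxes
#'
#' Light-based geolocation cannot resolve latitude near the equinoxes, so
#' GLS locations inside the windows (default: 21 d before to 7 d after the
#' March equinox; 7 d before to 21 d after the September equinox, bounds
#' inclusive, equinoxes fixed at 20 March / 22 September 00:00 UTC) are
#' dropped. Datasets whose latitudes were already corrected upstream (e.g.
#' with sea-surface temperature matching) set `prefiltered = TRUE` and pass
#' through unchanged, as do all GPS and PTT locations.
#'
#' @param track a standardised track tibble.
#' @param windows equinox windows, as in [preprocess_config()].
#' @param prefiltered logical; `TRUE` if equinox latitudes were already
#'   corrected so no stripping is needed.
#' @return the filtered tibble.
#' @export
strip_equinox <- function(track,
                          windows = list(march = c(21, 7),
                                         september = c(7, 21)),
                          prefiltered = FALSE) {
  check_track(track)
  if (prefiltered || !nrow(track)) return(track)
  is_gls <- track$device == "GLS"
  if (!any(is_gls)) return(track)
  yr <- as.integer(format(track$timestamp, "%Y", tz = "UTC"))
  drop <- rep(FALSE, nrow(track))
  for (y in unique(yr[is_gls])) {
    b <- equinox_window_bounds(y, windows)
    in_win <- (track$timestamp >= b$march$from & track$timestamp <= b$march$to) |
      (track$timestamp >= b$september$from & track$timestamp <= b$september$to)
    drop <- drop | (is_gls & yr == y & in_win)
  }
  track[!drop, , drop = FALSE]
}

#' Drop locations within the colony buffer
#'
#' Removes locations closer to the breeding colony than the per-device
#' buffer radius (defaults: GPS 5 km, PTT 15 km, GLS 0 km i.e. untouched).
#' The comparison is strict: a location exactly at the buffer distance is
#' kept. Colony attendance records would otherwise dominate the
#' at-sea utilisation distribution.
#'
#' @param track a standardised track tibble.
#' @param colony a one-row data frame (or list) with `lon` and `lat` of
#'   the colony.
#' @param buffers named vector of buffer radii in km by device.
#' @return the filtered tibble.
#' @export
trim_colony_buffer <- function(track, colony,
                               buffers = c(GPS = 5, PTT = 15, GLS = 0)) {
  check_track(track)
  if (!nrow(track)) return(track)
  check_lonlat(colony$lon, colony$lat)
  r <- unname(buffers[track$device])
  r[is.na(r)] <- 0
  d <- great_circle_km(track$lon, track$lat, colony$lon, colony$lat)
  track[!(d < r), , drop = FALSE]
}

#' Linearly resample GPS and PTT tracks to a common interval
#'
#' Interpolates coordinates linearly in time and resamples each GPS/PTT
#' individual at `interval`-hour steps from its first to its last retained
#' location (never extrapolating). This standardises sampling effort to
#' the native GLS frequency of about two positions per day; GLS tracks
#' pass through unresampled. Longitudes are unwrapped before interpolation
#' so antimeridian crossings interpolate along the short way round, then
#' rewrapped to `[-180, 180)`. Gaps of any length inside one deployment
#' are spanned; individuals with a single retained location are dropped
#' with a warning.
#'
#' @param track a standardised, filtered track tibble.
#' @param interval resampling interval in hours (default 12).
#' @return the resampled tibble.
#' @export
resample_track <- function(track, interval = 12) {
  check_track(track)
  if (!nrow(track)) return(track)
  pieces <- lapply(split(track, track$individual_id), function(tr) {
    if (tr$device[1] == "GLS") return(tr)
    if (nrow(tr) < 2) {
      warning("dropping single-location track for individual ",
              tr$individual_id[1], call. = FALSE)
      return(tr[0, , drop = FALSE])
    }
    t0 <- tr$timestamp[1]
    hrs <- as.numeric(difftime(tr$timestamp, t0, units = "hours"))
    out_h <- seq(0, hrs[length(hrs)], by = interval)
    lon_u <- unwrap_lon(tr$lon)
    tibble::tibble(
      individual_id = tr$individual_id[1],
      timestamp = t0 + out_h * 3600,
      lon = wrap_lon(stats::approx(hrs, lon_u, xout = out_h)$y),
      lat = stats::approx(hrs, tr$lat, xout = out_h)$y,
      device = tr$device[1],
      population_id = tr$population_id[1])
  })
  out <- dplyr::bind_rows(pieces)
  extra <- setdiff(names(track), names(out))
  if (length(extra) == 0) out else out
}

# Unwrap a longitude sequence so consecutive differences are in (-180, 180];
# makes linear interpolation antimeridian-safe.
unwrap_lon <- function(lon) {
  if (length(lon) < 2) return(lon)
  d <- diff(lon)
  d <- d - 360 * round(d / 360)
  cumsum(c(lon[1], d))
}

#' Full track preprocessing pipeline
#'
#' Applies the canonical cleaning order to a multi-individual track table:
#' standardise, strip GLS equinox windows, filter speeds, trim the colony
#' buffer, then resample GPS/PTT to the common interval. The pipeline is
#' idempotent: running it on its own output changes nothing.
#'
#' @param track a raw track tibble (see [standardise_track()] for columns).
#' @param colony colony record with `lon`, `lat` and optionally
#'   `equinox_prefiltered`.
#' @param config a [preprocess_config()].
#' @return the cleaned, resampled track tibble.
#' @export
preprocess_tracks <- function(track, colony, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  prefiltered <- isTRUE(colony$equinox_prefiltered)
  track |>
    standardise_track() |>
    strip_equinox(config$equinox_windows, prefiltered) |>
    filter_speed(config$speed_max) |>
    trim_colony_buffer(colony, config$colony_buffer) |>
    resample_track(config$resample_interval)
}

#' Read / write tracking tables
#'
#' CSV schema mirrors standardised seabird tracking-database exports:
#' `dataset_id, individual_id, species, population, colony_lat, colony_lon,
#' device, date_time` (ISO-8601 UTC)`, latitude, longitude`.
#'
#' @param path file path.
#' @return `read_tracks` returns a track tibble in the internal column
#'   layout; `write_tracks` returns `path` invisibly.
#' @export
read_tracks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    individual_id = as.character(df$individual_id),
    timestamp = as.POSIXct(df$date_time, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                          "%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S")),
    lon = as.numeric(df$longitude),
    lat = as.numeric(df$latitude),
    device = as.character(df$device),
    population_id = as.character(df$population),
    species_id = as.character(df$species))
}

#' @rdname read_tracks
#' @param track a track tibble.
#' @param meta optional list/row with `dataset_id`, `species`,
#'   `colony_lat`, `colony_lon` to fill the export columns.
#' @export
write_tracks <- function(track, path, meta = list()) {
  check_track(track)
  out <- tibble::tibble(
    dataset_id = meta$dataset_id %||% "synthetic",
    individual_id = track$individual_id,
    species = track$species_id %||% meta$species %||% NA_character_,
    population = track$population_id,
    colony_lat = meta$colony_lat %||% NA_real_,
    colony_lon = meta$colony_lon %||% NA_real_,
    device = track$device,
    date_time = format(track$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    latitude = track$lat,
    longitude = track$lon)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read colony / population metadata
#'
#' Expects columns `population_id, species_id, colony_lon, colony_lat,
#' breeding_country, population_size, iucn_category, equinox_prefiltered`.
#'
#' @param path file path.
#' @return a tibble, one row per population, with `lon`/`lat` aliases for
#'   the colony coordinates.
#' @export
read_colonies <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("population_id", "colony_lon", "colony_lat") %in% names(df)))
  ok <- c("LC", "NT", "VU", "EN", "CR")
  if ("iucn_category" %in% names(df) &&
      !all(is.na(df$iucn_category) | df$iucn_category %in% ok)) {
    stop("unknown IUCN category in colony file")
  }
  check_lonlat(df$colony_lon, df$colony_lat)
  df$lon <- df$colony_lon
  df$lat <- df$colony_lat
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
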