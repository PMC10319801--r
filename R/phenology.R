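#' Monthly distance-to-colony statistics
#'
#' Pools all retained locations of a population across individuals and
#' years by calendar month and computes, per month, the number of
#' locations and the mean and minimum great-circle distance to the colony.
#' Months without locations are reported as untracked.
#'
#' @param points a preprocessed track tibble for one population.
#' @param colony colony record with `lon` and `lat`.
#' @return a 12-row tibble with `month`, `n`, `mean_km`, `min_km`,
#'   `tracked`.
#' @export
monthly_colony_stats <- function(points, colony) {
  base <- tibble::tibble(month = 1:12, n = 0L,
                         mean_km = NA_real_, min_km = NA_real_)
  if (nrow(points)) {
    check_track(points)
    d <- great_circle_km(points$lon, points$lat, colony$lon, colony$lat)
    m <- as.integer(format(points$timestamp, "%m", tz = "UTC"))
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(month = m, d = d), .data$month),
      n = dplyr::n(), mean_km = mean(.data$d), min_km = min(.data$d),
      .groups = "drop")
    base <- dplyr::rows_update(base, agg, by = "month")
  }
  base$tracked <- base$n > 0L
  base
}

#' Classify tracked months as breeding or non-breeding
#'
#' Distance-to-colony rule: a tracked month is non-breeding if its mean
#' colony distance exceeds the population grand mean (the unweighted mean
#' of the tracked monthly means) or if no pooled location came within
#' `attendance_radius` of the colony (minimum distance at or above the
#' radius, default 200 km, the typical GLS positional error). Otherwise it
#' is breeding; ties on the grand mean count as breeding. Untracked months
#' stay `"untracked"`.
#'
#' @param stats output of [monthly_colony_stats()].
#' @param attendance_radius colony-attendance radius in km.
#' @return `stats` with added `label` column
#'   (`breeding`/`non-breeding`/`untracked`).
#' @export
classify_months <- function(stats, attendance_radius = 200) {
  stopifnot(any(stats$tracked))
  grand <- mean(stats$mean_km[stats$tracked])
  lab <- rep("untracked", nrow(stats))
  tr <- stats$tracked
  nonbr <- tr & (stats$mean_km > grand | stats$min_km >= attendance_radius)
  lab[tr] <- ifelse(nonbr[tr], "non-breeding", "breeding")
  stats$label <- lab
  stats
}

#' Smooth month labels into single seasons
#'
#' A tracked month labelled differently from both of its tracked cyclic
#' neighbours (December and January are adjacent; untracked months are
#' skipped when finding neighbours) is re-classified to the neighbours'
#' label, in calendar order, repeating until stable. Because the annual
#' cycle should contain a single breeding and a single non-breeding
#' season, any remaining fragmentation is then resolved by flipping whole
#' runs, shortest first (earliest start on ties), until at most one
#' contiguous cyclic run of each label remains.
#'
#' @param labels character vector of 12 month labels
#'   (`breeding`/`non-breeding`/`untracked`).
#' @return the smoothed label vector.
#' @export
smooth_labels <- function(labels) {
  stopifnot(length(labels) == 12)
  tracked <- which(labels != "untracked")
  if (length(tracked) < 3) return(labels)
  lab <- labels[tracked]
  k <- length(lab)
  repeat {
    changed <- FALSE
    # in-place calendar-order pass: each flip removes two label
    # boundaries, so the iteration cannot oscillate
    for (i in seq_len(k)) {
      prev <- lab[if (i == 1) k else i - 1]
      nxt <- lab[if (i == k) 1 else i + 1]
      if (prev == nxt && lab[i] != prev) {
        lab[i] <- prev
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # collapse residual multi-run patterns (e.g. two separate "breeding"
  # stints) by flipping the shortest run; each flip merges its two
  # neighbouring runs, so this terminates with one run per label
  repeat {
    runs <- cyclic_runs(lab)
    if (nrow(runs) <= 2) break
    shortest <- which.min(runs$length)
    idx <- ((runs$start[shortest] - 1 + seq_len(runs$length[shortest]) - 1)
            %% k) + 1
    lab[idx] <- setdiff(c("breeding", "non-breeding"), runs$label[shortest])
  }
  labels[tracked] <- lab
  labels
}

# Maximal cyclic runs of equal labels: start index, length, label.
cyclic_runs <- function(lab) {
  k <- length(lab)
  if (length(unique(lab)) == 1) {
    return(data.frame(start = 1L, length = k, label = lab[1]))
  }
  # rotate so position 1 starts a run
  first <- which(lab != lab[c(k, seq_len(k - 1))])[1]
  rot <- c(seq(first, k), seq_len(first - 1))
  r <- rle(lab[rot])
  starts_rot <- cumsum(c(1, utils::head(r$lengths, -1)))
  data.frame(start = ((rot[starts_rot] - 1) %% k) + 1,
             length = r$lengths, label = r$values)
}

n_cyclic_runs <- function(labels, value) {
  lab <- labels[labels != "untracked"]
  k <- length(lab)
  if (k == 0) return(0L)
  is_v <- lab == value
  if (all(is_v)) return(1L)
  starts <- sum(is_v & !is_v[c(k, seq_len(k - 1))])
  as.integer(starts)
}

#' Reconcile inferred labels with a published breeding schedule
#'
#' Published month labels take precedence, with one override: a month
#' published as breeding in which the tracked birds demonstrably did not
#' attend the colony (pooled minimum distance at or above
#' `attendance_radius`) takes the distance-rule label instead. Months with
#' no published value take the inferred label.
#'
#' @param published character vector of 12 labels
#'   (`breeding`/`non-breeding`/`NA`).
#' @param inferred character vector of 12 labels from [classify_months()]
#'   + [smooth_labels()].
#' @param min_km per-month pooled minimum colony distance (length 12).
#' @param attendance_radius attendance radius in km.
#' @return a tibble with `month`, `label`, `label_source`
#'   (`published`/`distance_rule`/`reconciled`).
#' @export
reconcile_with_published <- function(published, inferred, min_km,
                                     attendance_radius = 200) {
  stopifnot(length(published) == 12, length(inferred) == 12,
            length(min_km) == 12)
  label <- published
  source <- rep("published", 12)
  absent <- !is.na(min_km) & min_km >= attendance_radius
  override <- !is.na(published) & published == "breeding" & absent
  label[override] <- inferred[override]
  source[override] <- "reconciled"
  use_inf <- is.na(published)
  label[use_inf] <- inferred[use_inf]
  source[use_inf] <- "distance_rule"
  source[label == "untracked"] <- "distance_rule"
  tibble::tibble(month = 1:12, label = label, label_source = source)
}

#' Infer a population's monthly phenology from tracking data
#'
#' Convenience wrapper: monthly colony statistics, distance-rule
#' classification, cyclic smoothing, and (optionally) reconciliation with
#' a published schedule.
#'
#' @param points preprocessed track tibble for one population.
#' @param colony colony record with `lon`, `lat`.
#' @param published optional character vector of 12 published labels
#'   (`NA` where unknown).
#' @param attendance_radius attendance radius in km.
#' @return a tibble with per-month distance stats, `label` and
#'   `label_source`.
#' @export
infer_phenology <- function(points, colony, published = NULL,
                            attendance_radius = 200) {
  stats <- monthly_colony_stats(points, colony)
  stats <- classify_months(stats, attendance_radius)
  stats$label <- smooth_labels(stats$label)
  if (is.null(published)) {
    stats$label_source <- ifelse(stats$tracked, "distance_rule",
                                 "distance_rule")
    return(stats)
  }
  rec <- reconcile_with_published(published, stats$label, stats$min_km,
                                  attendance_radius)
  stats$label <- rec$label
  stats$label_source <- rec$label_source
  stats
}

#' Read published breeding schedules
#'
#' CSV with columns `population_id` (or `species_id`), `month`, `label`;
#' duplicate conflicting entries for one population-month are an error.
#'
#' @param path file path.
#' @return a tibble `population_id`, `month`, `label`.
#' @export
read_schedules <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  key <- if ("population_id" %in% names(df)) "population_id" else "species_id"
  dup <- dplyr::summarise(
    dplyr::group_by(df, .data[[key]], .data$month),
    k = dplyr::n_distinct(.data$label), .groups = "drop")
  if (any(dup$k > 1)) stop("conflicting duplicate published schedule entries")
  dplyr::distinct(df)
}

#' Published schedule for one population as a 12-vector
#'
#' @param schedules tibble from [read_schedules()].
#' @param population_id population to extract.
#' @return character vector of 12 labels with `NA` for missing months, or
#'   `NULL` if the population has no published schedule.
#' @export
schedule_vector <- function(schedules, population_id) {
  key <- if ("population_id" %in% names(schedules)) "population_id" else
    "species_id"
  rows <- schedules[schedules[[key]] == population_id, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  out <- rep(NA_character_, 12)
  out[rows$month] <- rows$label
  out
}

#' Season-score sensitivity to the phenology source
#'
#' Recomputes each population's seasonal exposure scores twice — once
#' under the final (published, reconciled) labels and once under pure
#' distance-rule labels — and pairs them up. The rank agreement between
#' the two columns measures how robust seasonal scores are to the choice
#' of breeding-schedule source.
#'
#' @param results a [run_pipeline()] result list.
#' @return a tibble `population_id`, `season`, `published`, `inferred`.
#' @export
phenology_sensitivity <- function(results) {
  monthly <- results$scores$monthly
  rows <- lapply(names(results$phenology), function(p) {
    ph <- results$phenology[[p]]
    inferred <- smooth_labels(classify_months(ph)$label)
    msub <- monthly[monthly$population_id == p, ]
    a <- season_score(msub, ph$label)
    b <- season_score(msub, inferred)
    out <- dplyr::inner_join(a[, c("season", "score")],
                             b[, c("season", "score")],
                             by = "season", suffix = c("_pub", "_inf"))
    tibble::tibble(population_id = p, season = out$season,
                   published = out$score_pub, inferred = out$score_inf)
  })
  dplyr::bind_rows(rows)
}
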