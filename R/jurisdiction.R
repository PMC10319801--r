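#' Jurisdiction layer
#'
#' A set of maritime-jurisdiction polygons: Exclusive Economic Zones,
#' theoretical EEZs (median-line boundaries where none are declared) and
#' joint regimes (areas administered by more than one sovereign). The
#' complement of all polygons is the high seas.
#'
#' @param names character vector of polygon names.
#' @param sovereigns list of character vectors, one per polygon (joint
#'   regimes list two or more sovereigns).
#' @param categories character vector: `EEZ`, `theoretical-EEZ` or
#'   `joint-regime`.
#' @param polygons list of two-column lon/lat matrices (rings; closure is
#'   optional, self-intersection is not checked beyond mgcv's needs).
#' @return an object of class `jurisdiction_layer`.
#' @export
jurisdiction_layer <- function(names, sovereigns, categories, polygons) {
  stopifnot(length(names) == length(polygons),
            length(sovereigns) == length(polygons),
            length(categories) == length(polygons),
            all(categories %in% c("EEZ", "theoretical-EEZ", "joint-regime")),
            all(lengths(sovereigns) >= 1))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) stop("invalid jurisdiction polygon")
    p
  })
  structure(list(name = names, sovereigns = sovereigns,
                 category = categories, polygons = polygons),
            class = "jurisdiction_layer")
}

#' Assign every global-grid cell to a jurisdiction
#'
#' Centre-point rule: a 1-degree cell belongs to the first polygon (in
#' layer order) containing its centre, and to the high seas if no polygon
#' does. Boundary ties therefore resolve to the earlier polygon in the
#' layer. This is the resolution-limited approximation appropriate at a
#' 1-degree grid; no area-weighted splitting is attempted.
#'
#' @param layer a [jurisdiction_layer()].
#' @return an integer 180 x 360 matrix of polygon indices, `0L` meaning
#'   high seas.
#' @export
assign_cells <- function(layer) {
  stopifnot(inherits(layer, "jurisdiction_layer"))
  ctr <- grid_centres()
  pts <- cbind(rep(ctr$lon, each = 180), rep(ctr$lat, times = 360))
  assign <- matrix(0L, 180, 360)
  for (j in rev(seq_along(layer$polygons))) {
    inside <- mgcv::in.out(layer$polygons[[j]], pts)
    assign[matrix(inside, nrow = 180)] <- j
  }
  assign
}

#' Partition an exposure map across jurisdictions
#'
#' Credits each cell's exposure value to the jurisdiction holding the
#' cell; joint-regime cells are split evenly among the involved
#' sovereigns. Shares sum exactly to the map total.
#'
#' @param map an exposure [global_grid()].
#' @param assignment cell assignment from [assign_cells()].
#' @param layer the [jurisdiction_layer()] used for the assignment.
#' @return a tibble `jurisdiction`, `sovereign`, `category`, `score`
#'   (1e6-scaled share) and `fraction` of the total.
#' @export
partition_score <- function(map, assignment, layer) {
  stopifnot(inherits(map, "global_grid"),
            all(dim(assignment) == c(180, 360)))
  v <- map$values
  v[is.na(v)] <- 0
  totals <- vapply(seq_along(layer$polygons),
                   function(j) sum(v[assignment == j]), 0)
  hs <- sum(v[assignment == 0L])
  rows <- list(tibble::tibble(jurisdiction = "High seas",
                              sovereign = "High seas",
                              category = "high-seas", value = hs))
  for (j in seq_along(layer$polygons)) {
    sov <- layer$sovereigns[[j]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      jurisdiction = layer$name[j], sovereign = sov,
      category = layer$category[j], value = totals[j] / length(sov))
  }
  out <- dplyr::bind_rows(rows)
  tot <- sum(v)
  out$score <- 1e6 * out$value
  out$fraction <- if (tot > 0) out$value / tot else 0
  out$value <- NULL
  out
}

#' Link breeding countries to the jurisdictions of their exposure
#'
#' For each population, sums the share of its exposure falling inside
#' jurisdictions of its own breeding country versus elsewhere, and flags
#' populations whose own-country share is not the largest single share —
#' the situations where exposure risk accrues mostly outside the breeding
#' state's jurisdiction.
#'
#' @param shares_by_pop named list of per-population share tibbles from
#'   [partition_score()].
#' @param colonies colony metadata tibble with `population_id` and
#'   `breeding_country`.
#' @return a tibble `population_id`, `breeding_country`, `own_eez_share`,
#'   `high_seas_share`, `other_share`, `own_is_max`.
#' @export
breeding_country_linkage <- function(shares_by_pop, colonies) {
  rows <- lapply(names(shares_by_pop), function(pid) {
    sh <- shares_by_pop[[pid]]
    country <- colonies$breeding_country[colonies$population_id == pid][1]
    own <- sum(sh$fraction[sh$sovereign == country])
    hs <- sum(sh$fraction[sh$sovereign == "High seas"])
    by_sov <- tapply(sh$fraction, sh$sovereign, sum)
    tibble::tibble(population_id = pid,
                   breeding_country = country,
                   own_eez_share = own,
                   high_seas_share = hs,
                   other_share = 1 - own - hs,
                   own_is_max = own >= max(by_sov))
  })
  dplyr::bind_rows(rows)
}

#' Read / write jurisdiction layers as GeoJSON
#'
#' FeatureCollection of Polygon features with properties `name`,
#' `sovereigns` (semicolon-delimited) and `category`.
#'
#' @param path file path.
#' @return `read_jurisdictions_geojson` returns a
#'   [jurisdiction_layer()]; the writer returns `path` invisibly.
#' @export
read_jurisdictions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  })
  jurisdiction_layer(
    names = vapply(feats, function(f) f$properties$name, ""),
    sovereigns = lapply(feats, function(f)
      strsplit(f$properties$sovereigns, ";")[[1]]),
    categories = vapply(feats, function(f) f$properties$category, ""),
    polygons = polys)
}

#' @rdname read_jurisdictions_geojson
#' @param layer a [jurisdiction_layer()].
#' @export
write_jurisdictions_geojson <- function(layer, path) {
  feats <- lapply(seq_along(layer$polygons), function(j) {
    p <- layer$polygons[[j]]
    if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
    list(type = "Feature",
         properties = list(name = layer$name[j],
                           sovereigns = paste(layer$sovereigns[[j]],
                                              collapse = ";"),
                           category = layer$category[j]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(i) as.list(p[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
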