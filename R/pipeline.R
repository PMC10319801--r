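#' Assemble a run configuration
#'
#' Collects the file paths and parameters for an end-to-end run. All
#' randomness in a run flows from the single `seed`.
#'
#' @param tracks,colonies,schedules,land,jurisdictions input file paths
#'   (`schedules`, `land`, `jurisdictions` may be `NULL` to skip the
#'   corresponding stage detail).
#' @param plastic character vector of three plastic model CSV paths.
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param preprocess a [preprocess_config()].
#' @param h,cell,level,n_min kernel bandwidth (km), fine cell (km),
#'   isopleth level, minimum locations per population-month.
#' @param attendance_radius phenology colony-attendance radius (km).
#' @param verbose print stage progress.
#' @return a list of class `run_config`.
#' @export
run_config <- function(tracks, colonies, plastic, outdir,
                       schedules = NULL, land = NULL, jurisdictions = NULL,
                       seed = 1, preprocess = preprocess_config(),
                       h = 200, cell = 10, level = 0.95, n_min = 5,
                       attendance_radius = 200, verbose = FALSE) {
  structure(list(tracks = tracks, colonies = colonies, plastic = plastic,
                 schedules = schedules, land = land,
                 jurisdictions = jurisdictions, outdir = outdir,
                 seed = as.integer(seed), preprocess = preprocess,
                 h = h, cell = cell, level = level, n_min = n_min,
                 attendance_radius = attendance_radius,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  y$preprocess <- NULL
  do.call(run_config, c(y, list(preprocess = pp)))
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full exposure-risk pipeline
#'
#' Executes, in order: track reading and preprocessing; phenology
#' classification; monthly kernel utilisation distributions aggregated to
#' the global grid; plastic-layer fusion; monthly, seasonal, population,
#' species and all-species exposure scores; IUCN category shares and
#' species richness; and jurisdictional attribution. Writes result tables
#' and a JSON run manifest (config echo, input checksums, versions,
#' seed) to `config$outdir`.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return the full results list, invisibly; also written to disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  for (f in c(config$tracks, config$colonies, config$plastic,
              config$schedules, config$land, config$jurisdictions)) {
    if (!file.exists(f)) stop(sprintf("[stage:inputs] missing file: %s", f),
                              call. = FALSE)
  }

  inputs <- stage("inputs", v, {
    list(tracks = read_tracks(config$tracks),
         colonies = read_colonies(config$colonies),
         schedules = if (!is.null(config$schedules))
           read_schedules(config$schedules),
         land = if (!is.null(config$land)) read_grid_csv(config$land),
         jurisdictions = if (!is.null(config$jurisdictions))
           read_jurisdictions_geojson(config$jurisdictions))
  })
  # land CSV stores only non-missing cells; absent cells are ocean
  if (!is.null(inputs$land)) {
    m <- inputs$land$values
    m[is.na(m)] <- 0
    inputs$land <- global_grid(m)
  }

  clean <- stage("preprocess", v, {
    pops <- split(inputs$tracks, inputs$tracks$population_id)
    dplyr::bind_rows(lapply(pops, function(tr) {
      colony <- inputs$colonies[inputs$colonies$population_id ==
                                  tr$population_id[1], ]
      if (!nrow(colony)) stop("no colony metadata for population ",
                              tr$population_id[1])
      out <- preprocess_tracks(tr[, track_cols], colony, config$preprocess)
      out$species_id <- tr$species_id[1]
      out
    }))
  })
  clean <- stage("month_filter", v,
                 month_filter(clean, config$preprocess$min_locations_per_month))

  phen <- stage("phenology", v, {
    pops <- split(clean, clean$population_id)
    lapply(pops, function(tr) {
      colony <- inputs$colonies[inputs$colonies$population_id ==
                                  tr$population_id[1], ]
      pub <- if (!is.null(inputs$schedules))
        schedule_vector(inputs$schedules, tr$population_id[1])
      infer_phenology(tr, colony, pub, config$attendance_radius)
    })
  })

  uds <- stage("ud", v,
               monthly_uds(clean, land = inputs$land, h = config$h,
                           cell = config$cell, level = config$level,
                           n_min = config$n_min))

  plastic <- stage("plastic", v, build_plastic_layer(config$plastic))

  scores <- stage("exposure", v,
                  score_tables(uds, phen, plastic$normalised,
                               inputs$colonies))

  juris <- if (!is.null(inputs$jurisdictions)) {
    stage("jurisdiction", v, {
      assignment <- assign_cells(inputs$jurisdictions)
      all_sp <- partition_score(scores$all_species$map, assignment,
                                inputs$jurisdictions)
      by_pop <- lapply(scores$population_maps, function(m)
        partition_score(m, assignment, inputs$jurisdictions))
      linkage <- breeding_country_linkage(by_pop, inputs$colonies)
      list(assignment = assignment, all_species = all_sp,
           by_population = by_pop, linkage = linkage)
    })
  }

  results <- list(config = config, phenology = phen, uds = uds,
                  plastic = plastic, scores = scores,
                  jurisdiction = juris)
  stage("write", v, write_results(results, config))
  invisible(results)
}

# Monthly, season, population and species scores plus combined maps.
score_tables <- function(uds, phen, plastic_norm, colonies) {
  monthly <- dplyr::bind_rows(lapply(seq_len(nrow(uds)), function(i) {
    g <- normalize_unit_sum(uds$global[[i]])
    map <- exposure_map(g, plastic_norm)
    tibble::tibble(population_id = uds$population_id[i],
                   month = uds$month[i], n = uds$n[i],
                   score = exposure_score(map),
                   missing_plastic_mass =
                     attr(map, "missing_plastic_mass"),
                   map = list(map))
  }))

  pops <- unique(monthly$population_id)
  seasons <- dplyr::bind_rows(lapply(pops, function(p) {
    lab <- phen[[p]]$label
    out <- season_score(monthly[monthly$population_id == p, ], lab)
    out$population_id <- p
    out
  }))

  pop_tab <- dplyr::bind_rows(lapply(pops, function(p) {
    m <- monthly[monthly$population_id == p, ]
    lab <- phen[[p]]$label
    tracked_lab <- lab[m$month]
    tibble::tibble(
      population_id = p,
      species_id = colonies$species_id[colonies$population_id == p][1],
      n_months = nrow(m),
      score = population_score(m$score),
      coverage = if (any(tracked_lab == "non-breeding")) 1 else 0.5,
      population_size =
        colonies$population_size[colonies$population_id == p][1])
  }))

  population_maps <- lapply(stats::setNames(pops, pops), function(p) {
    maps <- monthly$map[monthly$population_id == p]
    global_grid(Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps))
  })
  population_grids <- lapply(stats::setNames(pops, pops), function(p) {
    population_grid(uds$global[uds$population_id == p])
  })

  sp_ids <- unique(pop_tab$species_id)
  species_tab <- dplyr::bind_rows(lapply(sp_ids, function(s) {
    rows <- pop_tab[pop_tab$species_id == s, ]
    cat_s <- colonies$iucn_category[colonies$species_id == s][1]
    tibble::tibble(
      species_id = s, n_populations = nrow(rows),
      score = species_score(rows$score, rows$population_size,
                            rows$coverage),
      coverage = if (all(rows$coverage == 0.5)) 0.5 else 1,
      iucn_category = cat_s)
  }))
  species_grids <- lapply(stats::setNames(sp_ids, sp_ids), function(s) {
    rows <- pop_tab[pop_tab$species_id == s, ]
    species_grid(population_grids[rows$population_id],
                 rows$population_size)
  })

  all_sp <- all_species_map(species_grids, species_tab$coverage,
                            plastic_norm)
  shares <- category_share(species_tab$score, species_tab$iucn_category)

  list(monthly = monthly[, setdiff(names(monthly), "map")],
       monthly_maps = monthly$map,
       seasons = seasons, populations = pop_tab, species = species_tab,
       population_maps = population_maps,
       population_grids = population_grids,
       species_grids = species_grids,
       all_species = all_sp,
       category_shares = shares,
       richness = richness_map(species_grids))
}

write_results <- function(results, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  s <- results$scores
  readr::write_csv(s$monthly, out("monthly_scores.csv"))
  readr::write_csv(s$seasons, out("season_scores.csv"))
  readr::write_csv(s$populations, out("population_scores.csv"))
  readr::write_csv(s$species, out("species_scores.csv"))
  readr::write_csv(s$category_shares, out("category_shares.csv"))
  phen_tab <- dplyr::bind_rows(lapply(names(results$phenology), function(p) {
    ph <- results$phenology[[p]]
    ph$population_id <- p
    ph
  }))
  readr::write_csv(phen_tab, out("phenology.csv"))
  write_grid_csv(s$all_species$map, out("all_species_exposure.csv"))
  write_grid_csv(s$richness, out("species_richness.csv"))
  if (!is.null(results$jurisdiction)) {
    readr::write_csv(results$jurisdiction$all_species,
                     out("jurisdiction_shares.csv"))
    readr::write_csv(results$jurisdiction$linkage,
                     out("breeding_country_linkage.csv"))
  }
  write_manifest(results, config, out("manifest.json"))
  invisible(config$outdir)
}

write_manifest <- function(results, config, path) {
  inputs <- c(tracks = config$tracks, colonies = config$colonies,
              stats::setNames(config$plastic,
                              paste0("plastic", seq_along(config$plastic))),
              schedules = config$schedules, land = config$land,
              jurisdictions = config$jurisdictions)
  manifest <- list(
    package = "plasticrisk",
    version = as.character(utils::packageVersion("plasticrisk")),
    seed = config$seed,
    parameters = list(h = config$h, cell = config$cell,
                      level = config$level, n_min = config$n_min,
                      attendance_radius = config$attendance_radius,
                      preprocess = unclass(config$preprocess)),
    input_md5 = as.list(tools::md5sum(inputs)),
    n_populations = nrow(results$scores$populations),
    n_species = nrow(results$scores$species))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Render ranked tables and maps from pipeline results
#'
#' Produces the species ranking table, the jurisdiction table and
#' square-root-scaled map renderings of the all-species exposure map and
#' species richness. For display only, map values are capped at the 90th
#' percentile of positive values (extreme hotspot cells otherwise swamp
#' the colour scale); tabulated scores are never capped.
#'
#' @param results list returned by [run_pipeline()].
#' @param outdir directory for report files.
#' @return named list of written file paths, invisibly.
#' @export
make_report <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- results$scores
  ranking <- dplyr::arrange(s$species, dplyr::desc(.data$score))
  ranking$score <- format_score(ranking$score)
  paths <- list(ranking = file.path(outdir, "species_ranking.csv"),
                jurisdiction = file.path(outdir, "jurisdiction_table.csv"),
                exposure_map = file.path(outdir, "all_species_exposure.pdf"),
                richness_map = file.path(outdir, "species_richness.pdf"))
  readr::write_csv(ranking, paths$ranking)
  if (!is.null(results$jurisdiction)) {
    jt <- dplyr::arrange(results$jurisdiction$all_species,
                         dplyr::desc(.data$fraction))
    readr::write_csv(jt, paths$jurisdiction)
  } else {
    readr::write_csv(tibble::tibble(jurisdiction = character(),
                                    sovereign = character(),
                                    fraction = numeric()),
                     paths$jurisdiction)
  }
  plot_grid_map(s$all_species$map, "Relative plastic exposure risk",
                paths$exposure_map, cap = TRUE)
  plot_grid_map(s$richness, "Species richness (95% UD presence)",
                paths$richness_map, cap = FALSE)
  invisible(paths)
}

plot_grid_map <- function(grid, title, path, cap = FALSE) {
  df <- grid_to_df(grid)
  df <- df[df$value > 0, , drop = FALSE]
  if (cap && nrow(df)) {
    df$value <- pmin(df$value, stats::quantile(df$value, 0.9))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                        fill = sqrt(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "sqrt value") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-90, 90),
                         expand = FALSE) +
    ggplot2::labs(title = title, x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 10, height = 5, device = "pdf")
  invisible(path)
}
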