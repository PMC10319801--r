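#' Cellwise exposure-risk map
#'
#' The overlap statistic at the heart of the pipeline: the per-cell
#' product of a normalised bird utilisation grid and the normalised
#' plastic-density grid. Bird mass over cells with no plastic estimate
#' contributes zero; the fraction of bird mass lost that way is recorded
#' in the `missing_plastic_mass` attribute so coverage can be judged.
#'
#' @param petrel normalised [global_grid()] of bird density.
#' @param plastic normalised [global_grid()] of plastic density.
#' @return a [global_grid()] exposure map (unnormalised product values).
#' @export
exposure_map <- function(petrel, plastic) {
  stopifnot(inherits(petrel, "global_grid"), inherits(plastic, "global_grid"))
  if (!petrel$normalised || !plastic$normalised) {
    stop("exposure_map requires normalised input grids")
  }
  p <- petrel$values
  q <- plastic$values
  miss <- is.na(q) & !is.na(p) & p > 0
  prod <- ifelse(is.na(p), 0, p) * ifelse(is.na(q), 0, q)
  out <- global_grid(prod)
  attr(out, "missing_plastic_mass") <- sum(p[miss], na.rm = TRUE)
  out
}

#' Exposure-risk score of a map
#'
#' One million times the sum of the exposure map's cell values — a
#' dimensionless relative score scaled to avoid long strings of decimal
#' places. Bounded by 0 and 1e6; the maximum is attained only when both
#' distributions sit entirely in the same single cell.
#'
#' @param map an exposure [global_grid()] from [exposure_map()].
#' @return a single number.
#' @export
exposure_score <- function(map) {
  stopifnot(inherits(map, "global_grid"))
  1e6 * sum(map$values, na.rm = TRUE)
}

#' Reference score under uniform plastic
#'
#' The score any bird distribution would attain if plastic were spread
#' evenly over all cells with a plastic estimate: every non-missing cell
#' is set to the layer mean, the layer renormalised, and the product
#' summed. For a bird distribution wholly supported on non-missing cells
#' this collapses to 1e6 / N with N the number of non-missing plastic
#' cells, independent of the bird distribution. Scores above this
#' reference indicate above-average plastic in the areas used.
#'
#' @param plastic a plastic [global_grid()] (any positive scaling).
#' @return the reference score, 1e6 / N.
#' @export
uniform_plastic_reference <- function(plastic) {
  stopifnot(inherits(plastic, "global_grid"))
  n <- sum(!is.na(plastic$values))
  if (n == 0) stop("plastic layer has no non-missing cells")
  1e6 / n
}

#' Seasonal mean scores
#'
#' The breeding (or non-breeding) season score is the arithmetic mean of
#' the monthly scores labelled with that season. Seasons with no tracked
#' months are absent from the result, not zero.
#'
#' @param monthly tibble with columns `month`, `score`.
#' @param labels character vector of 12 month labels
#'   (`breeding`/`non-breeding`/`untracked`).
#' @return a tibble `season`, `score`, `n_months`.
#' @export
season_score <- function(monthly, labels) {
  stopifnot(all(c("month", "score") %in% names(monthly)),
            length(labels) == 12)
  monthly$season <- labels[monthly$month]
  keep <- monthly$season %in% c("breeding", "non-breeding")
  dplyr::summarise(dplyr::group_by(monthly[keep, ], .data$season),
                   score = mean(.data$score), n_months = dplyr::n(),
                   .groups = "drop")
}

#' Population score
#'
#' The mean of all tracked monthly scores (not season-balanced), allowing
#' comparison between populations with different numbers of tracked
#' months.
#'
#' @param monthly_scores numeric vector of monthly scores.
#' @return a single number.
#' @export
population_score <- function(monthly_scores) {
  stopifnot(length(monthly_scores) >= 1)
  mean(monthly_scores)
}

#' Species score with population-size weighting and coverage factor
#'
#' The mean of population scores weighted by approximate population size
#' (breeding pairs); a population tracked only during the breeding season
#' contributes with a coverage factor of 0.5 to avoid biasing the species
#' score towards breeding-area exposure. Populations with unknown size
#' fall back to equal weights (with a warning).
#'
#' @param scores numeric vector of population scores.
#' @param sizes numeric vector of population sizes (breeding pairs; `NA`
#'   triggers the equal-weight fallback for all populations).
#' @param coverage numeric vector of coverage factors (1 for populations
#'   tracked in both seasons, 0.5 for breeding-only).
#' @return a single number.
#' @export
species_score <- function(scores, sizes = NULL,
                          coverage = rep(1, length(scores))) {
  stopifnot(length(scores) >= 1, length(coverage) == length(scores),
            all(coverage %in% c(0.5, 1)))
  if (is.null(sizes) || any(is.na(sizes))) {
    if (!is.null(sizes) && any(is.na(sizes))) {
      warning("missing population size; falling back to equal weights",
              call. = FALSE)
    }
    sizes <- rep(1, length(scores))
  }
  stopifnot(all(sizes > 0))
  sum(sizes * coverage * scores) / sum(sizes)
}

#' Population and species utilisation grids
#'
#' A population's grid is the unweighted mean of its normalised monthly
#' grids (so the map is consistent with the score being the month-mean);
#' a species' grid is the population-size-weighted mean of its population
#' grids, renormalised.
#'
#' @param grids list of unnormalised monthly [global_grid()]s.
#' @return a normalised [global_grid()].
#' @export
population_grid <- function(grids) {
  stopifnot(length(grids) >= 1)
  mats <- lapply(grids, function(g) normalize_unit_sum(g)$values)
  global_grid(Reduce(`+`, mats) / length(mats), normalised = TRUE)
}

#' @rdname population_grid
#' @param pop_grids list of normalised population [global_grid()]s.
#' @param sizes population sizes used as weights (equal if `NULL`).
#' @export
species_grid <- function(pop_grids, sizes = NULL) {
  stopifnot(length(pop_grids) >= 1)
  if (is.null(sizes) || any(is.na(sizes))) sizes <- rep(1, length(pop_grids))
  w <- sizes / sum(sizes)
  mats <- Map(function(g, wi) g$values * wi, pop_grids, w)
  normalize_unit_sum(global_grid(Reduce(`+`, mats)))
}

#' All-species exposure map and score
#'
#' Sums normalised species grids with weight 1 for species tracked in
#' both seasons and 0.5 for breeding-only species, renormalises the
#' combined distribution to unit sum, and multiplies cellwise by the
#' normalised plastic grid.
#'
#' @param species_grids list of normalised species [global_grid()]s.
#' @param coverage per-species coverage weights (1 or 0.5).
#' @param plastic normalised plastic [global_grid()].
#' @return a list with `grid` (combined normalised bird distribution),
#'   `map` (exposure map) and `score`.
#' @export
all_species_map <- function(species_grids, coverage, plastic) {
  stopifnot(length(species_grids) >= 1,
            length(coverage) == length(species_grids),
            all(coverage %in% c(0.5, 1)))
  mats <- Map(function(g, w) {
    stopifnot(inherits(g, "global_grid"))
    g$values * w
  }, species_grids, coverage)
  combined <- normalize_unit_sum(global_grid(Reduce(`+`, mats)))
  map <- exposure_map(combined, plastic)
  list(grid = combined, map = map, score = exposure_score(map))
}

#' Share of total exposure score per IUCN threat category
#'
#' @param scores numeric vector of species scores.
#' @param categories character vector of IUCN categories
#'   (LC/NT/VU/EN/CR) per species.
#' @return a tibble `category`, `total`, `share`; shares sum to one.
#' @export
category_share <- function(scores, categories) {
  ok <- c("LC", "NT", "VU", "EN", "CR")
  if (!all(categories %in% ok)) stop("unknown IUCN category")
  stopifnot(length(scores) == length(categories), sum(scores) > 0)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(category = categories, score = scores),
                    .data$category),
    total = sum(.data$score), .groups = "drop")
  out$share <- out$total / sum(out$total)
  out
}

#' Species-richness map
#'
#' Per-cell count of species whose (95% isopleth) utilisation grid has
#' positive mass there.
#'
#' @param species_grids list of species [global_grid()]s.
#' @return a [global_grid()] of integer counts.
#' @export
richness_map <- function(species_grids) {
  acc <- matrix(0L, 180, 360)
  for (g in species_grids) {
    stopifnot(inherits(g, "global_grid"))
    acc <- acc + (!is.na(g$values) & g$values > 0)
  }
  global_grid(acc + 0)
}

#' Round a score for reporting
#'
#' Scores at or above one are reported at one decimal place; smaller
#' scores at four significant figures. Full precision is kept internally.
#'
#' @param x numeric scores.
#' @return rounded scores.
#' @export
format_score <- function(x) {
  ifelse(abs(x) >= 1, round(x, 1), signif(x, 4))
}
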