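norm_sparse <- function(lon, lat, value) {
  normalize_unit_sum(sparse_grid(lon, lat, value))
}

test_that("exposure map is the cellwise product of normalised grids", {
  petrel <- norm_sparse(c(0.5, 1.5), c(0.5, 0.5), c(0.2, 0.8))
  plastic <- norm_sparse(c(0.5, 1.5), c(0.5, 0.5), c(0.75, 0.25))
  map <- exposure_map(petrel, plastic)
  expect_equal(sort(map$values[map$values > 0]), c(0.15, 0.2))
  expect_equal(exposure_score(map), 350000)
  # unnormalised inputs are refused
  expect_error(exposure_map(sparse_grid(0.5, 0.5, 1), plastic),
               "normalised")
  # disjoint supports give a zero map
  p2 <- norm_sparse(100.5, 0.5, 1)
  expect_equal(exposure_score(exposure_map(p2, plastic)), 0)
})

test_that("bird mass over plastic-missing cells contributes zero and is flagged", {
  petrel <- norm_sparse(c(0.5, 1.5), c(0.5, 0.5), c(0.4, 0.6))
  plastic_vals <- sparse_grid(0.5, 0.5, 1, fill = NA_real_)
  plastic <- normalize_unit_sum(plastic_vals)
  map <- exposure_map(petrel, plastic)
  expect_equal(exposure_score(map), 1e6 * 0.4)
  expect_equal(attr(map, "missing_plastic_mass"), 0.6)
})

test_that("score bounds and the single-cell maximum", {
  one <- norm_sparse(10.5, 10.5, 1)
  expect_equal(exposure_score(exposure_map(one, one)), 1e6)
  set.seed(4)
  for (k in 1:20) {
    p <- norm_sparse(runif(5, -170, 170), runif(5, -80, 80), runif(5))
    q <- norm_sparse(runif(5, -170, 170), runif(5, -80, 80), runif(5))
    s <- exposure_score(exposure_map(p, q))
    expect_gte(s, 0); expect_lte(s, 1e6)
  }
  # both uniform over the full grid
  u <- normalize_unit_sum(global_grid(1))
  expect_equal(exposure_score(exposure_map(u, u)), 1e6 / 64800,
               tolerance = 1e-9)
})

test_that("uniform-plastic reference equals 1e6 over the cell count", {
  g <- global_grid(NA_real_)
  g$values[1:100, 1:10] <- 5.5   # 1000 cells
  expect_equal(uniform_plastic_reference(global_grid(g$values)), 1000)
  # independent of the bird distribution: flattening the layer and
  # scoring any UD on it gives the same number
  flat <- g$values
  flat[!is.na(flat)] <- mean(flat, na.rm = TRUE)
  flatn <- normalize_unit_sum(global_grid(flat))
  ud1 <- normalize_unit_sum(sparse_grid(c(-179.5, -170.5), c(-89.5, -85.5),
                                        c(1, 3)))
  ud2 <- normalize_unit_sum(sparse_grid(-175.5, -88.5, 7))
  expect_equal(exposure_score(exposure_map(ud1, flatn)), 1000)
  expect_equal(exposure_score(exposure_map(ud2, flatn)), 1000)
})

test_that("season, population and species scores follow the stated means", {
  monthly <- tibble::tibble(month = c(1, 2, 6, 7, 8), score = c(5, 15, 10,
                                                                20, 30))
  labels <- rep("untracked", 12)
  labels[c(1, 2)] <- "non-breeding"
  labels[6:8] <- "breeding"
  ss <- season_score(monthly, labels)
  expect_equal(ss$score[ss$season == "breeding"], 20)
  expect_equal(ss$score[ss$season == "non-breeding"], 10)
  # a season with no months is absent, not zero
  expect_equal(nrow(season_score(monthly[3:5, ], labels)), 1)
  expect_equal(population_score(c(0, 100)), 50)
  expect_equal(population_score(42), 42)
  # population-size weighting and the breeding-only halving
  expect_equal(species_score(c(10, 20), c(1000, 3000)), 17.5)
  expect_equal(species_score(40, 5000, coverage = 0.5), 20)
  expect_warning(s <- species_score(c(10, 20), c(NA, 3000)), "equal")
  expect_equal(s, 15)
})

test_that("all-species combination weights, renormalises and multiplies", {
  plastic <- normalize_unit_sum(global_grid(1))
  a <- norm_sparse(10.5, 10.5, 1)
  b <- norm_sparse(50.5, -20.5, 1)
  # one species: identical to its own exposure map
  one <- all_species_map(list(a), 1, plastic)
  expect_equal(one$map$values, exposure_map(a, plastic)$values)
  # identical grids: renormalisation absorbs the weights
  same <- all_species_map(list(a, a), c(1, 0.5), plastic)
  expect_equal(same$grid$values, a$values)
  # disjoint single cells under weights 1 and 0.5 split mass 2/3 vs 1/3
  two <- all_species_map(list(a, b), c(1, 0.5), plastic)
  df <- grid_to_df(two$grid)
  df <- df[df$value > 0, ]
  expect_equal(sort(df$value), c(1 / 3, 2 / 3))
})

test_that("category shares partition the total score", {
  cs <- category_share(c(100, 100), c("CR", "LC"))
  expect_equal(cs$share, c(0.5, 0.5))
  expect_equal(sum(category_share(runif(10, 1, 9),
                                  sample(c("LC", "NT", "VU", "EN", "CR"),
                                         10, TRUE))$share), 1)
  expect_equal(category_share(7, "EN")$share, 1)
  expect_error(category_share(1, "XX"), "unknown")
})

test_that("richness counts species with positive mass per cell", {
  a <- sparse_grid(c(0.5, 1.5), c(0.5, 0.5), 1)
  b <- sparse_grid(c(1.5, 2.5), c(0.5, 0.5), 1)
  r <- richness_map(list(a, b))
  expect_equal(cellv <- r$values[grid_cell_index(1.5, 0.5)$row,
                                 grid_cell_index(1.5, 0.5)$col], 2)
  expect_equal(max(r$values), 2)
  expect_equal(sum(r$values), 4)
  expect_equal(sum(richness_map(list())$values), 0)
})

test_that("scores are invariant to positive rescaling of raw inputs", {
  set.seed(9)
  raw_ud <- sparse_grid(runif(6, -170, 170), runif(6, -80, 80),
                        runif(6, 1, 5))
  raw_pl <- sparse_grid(runif(8, -170, 170), runif(8, -80, 80),
                        runif(8, 1, 5))
  s1 <- exposure_score(exposure_map(normalize_unit_sum(raw_ud),
                                    normalize_unit_sum(raw_pl)))
  s2 <- exposure_score(exposure_map(
    normalize_unit_sum(global_grid(raw_ud$values * 123.4)),
    normalize_unit_sum(global_grid(raw_pl$values * 0.007))))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("concentrating bird mass on the plastic argmax maximises the score", {
  set.seed(10)
  lon <- runif(6, -170, 170); lat <- runif(6, -80, 80)
  q <- runif(6, 0.1, 1)
  plastic <- normalize_unit_sum(sparse_grid(lon, lat, q))
  best <- which.max(q)
  s_delta <- exposure_score(exposure_map(
    norm_sparse(lon[best], lat[best], 1), plastic))
  for (k in 1:50) {
    w <- stats::rexp(6); w <- w / sum(w)
    s <- exposure_score(exposure_map(norm_sparse(lon, lat, w), plastic))
    expect_lte(s, s_delta + 1e-9)
  }
})

test_that("population maps are consistent with month-mean scores", {
  res <- get_demo_run()
  s <- res$scores
  for (p in names(s$population_maps)) {
    msc <- s$monthly$score[s$monthly$population_id == p]
    psc <- s$populations$score[s$populations$population_id == p]
    expect_equal(1e6 * grid_sum(s$population_maps[[p]]), mean(msc),
                 tolerance = 1e-9)
    expect_equal(psc, mean(msc), tolerance = 1e-9)
  }
})
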