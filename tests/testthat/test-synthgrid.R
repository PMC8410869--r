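test_that("grid construction and cell membership follow the frozen conventions", {
  spec <- grid_spec(cell_size = 10)
  cells <- grid_cells(spec)
  expect_equal(nrow(cells), 36 * 18)
  expect_equal(min(cells$lon), -175)
  expect_equal(max(cells$lat), 85)
  # half-open membership and longitude wrap
  expect_equal(cell_of(spec, -180, -90), 1L)
  expect_equal(cell_of(spec, 180, 0), cell_of(spec, -180, 0))
  expect_equal(cell_of(spec, -179.9, 10), cell_of(spec, -180, 10))
  expect_true(is.na(cell_of(spec, 0, 90))) # north edge excluded
  expect_error(grid_spec(cell_size = 7), "multiple")
})

test_that("the synthetic environment has the designed structure", {
  spec <- grid_spec(cell_size = 10)
  env <- generate_environment(spec, seed = 1)
  expect_equal(nrow(env), 36 * 18 * 12)
  # SST at the equator exceeds SST at the poles in every month
  eq <- env[abs(env$lat) < 10, ]
  po <- env[abs(env$lat) > 80, ]
  for (m in 1:12) {
    expect_gt(min(eq$sst[eq$month == m]), max(po$sst[po$month == m]))
  }
  # nutrients anti-correlated with temperature
  expect_lt(cor(env$sst, env$no3), -0.6)
  expect_lt(cor(env$sst, env$sioh4), -0.6)
  expect_gt(cor(env$no3, env$chl), 0.3)
})

test_that("environment generation is deterministic and seasonality is tunable", {
  spec <- grid_spec(cell_size = 30)
  expect_identical(generate_environment(spec, seed = 5),
                   generate_environment(spec, seed = 5))
  flat <- derive_predictors(generate_environment(spec, seed = 5, seasonal_amp = 0))
  expect_true(all(flat$dsst == 0))
  withseason <- derive_predictors(generate_environment(spec, seed = 5))
  expect_true(all(withseason$dsst >= 0) && any(withseason$dsst > 0))
})

test_that("virtual species have in-range niches and a tunable size-temperature link", {
  sp <- generate_species(tw_stack, 200, predictors = "sst", seed = 7,
                         size_temp_rho = -0.8)
  expect_equal(nrow(sp), 200)
  centres <- purrr::map_dbl(sp$niche, ~ .x$centre[.x$predictor == "sst"])
  expect_true(all(centres >= min(tw_stack$sst) & centres <= max(tw_stack$sst)))
  expect_true(all(purrr::map_dbl(sp$niche, ~ min(.x$breadth)) > 0))
  expect_lt(cor(sp$trait_size, centres, method = "spearman"), 0)
  expect_error(generate_species(tw_stack, 5, predictors = character(0)))
})

test_that("an unbounded niche saturates at the species' maximal suitability", {
  sp <- generate_species(tw_stack, 1, predictors = "sst", seed = 1)
  sp$niche[[1]]$breadth <- 1e9
  s <- true_suitability(sp, tw_stack)
  expect_true(all(abs(s$suitability - sp$max_suitability[1]) < 1e-6))
})

test_that("occurrence sampling follows the effort x suitability law", {
  # one broad-niche species, uniform effort: per-cell counts should match
  # the summed suitability under a chi-squared goodness-of-fit test
  sp <- generate_species(tw_stack, 1, predictors = "sst", seed = 3,
                         breadth_frac = c(0.5, 0.6))
  occ <- sample_occurrences(sp, tw_stack, 1e5, contamination = 0, seed = 9)
  spec <- get_grid(tw_stack)
  cellm <- cell_of(spec, occ$decimal_longitude, occ$decimal_latitude)
  counts <- table(factor(cellm, levels = grid_cells(spec)$cell))
  expected <- true_suitability(sp, tw_stack) |>
    dplyr::group_by(cell) |>
    dplyr::summarise(w = sum(suitability))
  p <- suppressWarnings(chisq.test(as.vector(counts), p = expected$w / sum(expected$w)))$p.value
  expect_gt(p, 0.01)
})

test_that("hemisphere-concentrated effort concentrates the records", {
  spec <- get_grid(tw_stack)
  eff <- sampling_effort(spec)
  eff$effort[grid_cells(spec)$lat[eff$cell] < 0] <- 0
  occ <- sample_occurrences(tw_species, tw_stack, 2000, effort = eff,
                            contamination = 0, seed = 4)
  expect_gte(mean(occ$decimal_latitude > -10), 0.9)
  eff$effort <- 0
  expect_error(sample_occurrences(tw_species, tw_stack, 10, effort = eff))
})

test_that("contamination is off by default-zero and the filter chain removes nothing", {
  occ <- sample_occurrences(tw_species, tw_stack, 500, contamination = 0, seed = 2)
  res <- filter_occurrences(occ)
  expect_equal(sum(res$report$removed), 0)
  expect_equal(res$n_retained, 500)
})

test_that("future anomalies cover the ESM axis and support null forcing", {
  an <- generate_future_anomalies(tw_stack, esm_configs(5), seed = 1)
  expect_equal(dplyr::n_distinct(an$esm_id), 5)
  # uniform +3 C: no amplification
  an3 <- generate_future_anomalies(
    tw_stack, esm_configs(1, warming = 3, amplification = 0)
  )
  d <- an3[an3$predictor == "sst", ]
  expect_true(all(d$delta == 3))
  # zero warming gives exactly zero deltas for every field
  an0 <- generate_future_anomalies(tw_stack, esm_configs(1, warming = 0))
  expect_true(all(an0$delta == 0))
})
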