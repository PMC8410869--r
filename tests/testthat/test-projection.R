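test_that("zero anomalies reproduce the observed climatology bit for bit", {
  an0 <- generate_future_anomalies(tw_env, esm_configs(1, warming = 0))
  fut <- apply_delta(tw_env, anomalies = an0, esm = "ESM1")
  obs <- derive_predictors(tw_env)
  expect_identical(fut$sst, obs$sst)
  expect_equal(as.data.frame(fut[, names(obs)]), as.data.frame(obs))
})

test_that("a uniform +3 degree anomaly shifts SST by exactly 3 everywhere", {
  an3 <- generate_future_anomalies(tw_env, esm_configs(1, warming = 3,
                                                       amplification = 0))
  fut <- apply_delta(tw_env, anomalies = an3, esm = "ESM1")
  expect_equal(fut$sst - tw_env$sst, rep(3, nrow(tw_env)))
})

test_that("the annual-range delta follows its own baseline/future rule", {
  # observed range 8, ESM baseline range 10, ESM future range 12 -> future 10
  spec <- grid_spec(cell_size = 90)
  mk <- function(amp, mean_sst) {
    d <- tidyr::crossing(grid_cells(spec), month = 1:12) |>
      dplyr::mutate(
        sst = mean_sst + amp / 2 * cos(2 * pi * (month - 8) / 12),
        mld = 50, par = 40, no3 = 5, po4 = 0.3, sioh4 = 5, chl = 0.5
      )
    plankdiv:::as_clim_stack(d, spec)
  }
  obs <- mk(8, 20)
  base <- mk(10, 19)
  fut <- mk(12, 22)
  out <- apply_delta(obs, esm_baseline = base, esm_future = fut)
  expect_equal(unique(out$dsst), 10)
  # monthly fields still follow obs + (future - baseline)
  expect_equal(out$sst, obs$sst + (fut$sst - base$sst))
  expect_error(apply_delta(obs, esm_baseline = base[1:10, ], esm_future = fut),
               "mismatch")
})

test_that("projected suitability respects bounds and the member layout", {
  tsets <- list(spA = tw_train)
  cfgs <- sdm_configs(ann = list(sizes = 2, decays = 0.01),
                      rf = list(num_trees = 100))
  des <- run_sdm_design(tsets, predictor_sets("phyto")["p1"], cfgs,
                        n_splits = 2, seed = 3)
  cube <- project_hsi(des, tw_stack)
  expect_true(all(cube$hsi >= 0 & cube$hsi <= 1))
  expect_equal(dplyr::n_distinct(cube$algorithm), 4)
  expect_equal(nrow(cube), 4 * nrow(tw_stack))
  # an off-grid niche projects to near-zero suitability
  off <- generate_species(tw_stack, 1, predictors = "sst", seed = 2)
  off$niche[[1]]$centre <- 80
  off$niche[[1]]$breadth <- 1
  s <- true_suitability(off, tw_stack)
  expect_lt(max(s$suitability), 1e-6)
})

test_that("richness stacking is additive and bounded", {
  cube <- tidyr::crossing(
    species_id = sprintf("s%d", 1:3), algorithm = "glm", set = "p1",
    esm = "obs", cell = 1:4, month = 1:2
  ) |> dplyr::mutate(hsi = 0.5)
  sr <- stack_richness(cube)
  expect_equal(unique(sr$sr), 1.5)
  expect_true(all(sr$sr >= 0 & sr$sr <= 3))
  # union of disjoint groups: SR adds
  sr_a <- stack_richness(cube, species = c("s1"))
  sr_bc <- stack_richness(cube, species = c("s2", "s3"))
  expect_equal(sr$sr, sr_a$sr + sr_bc$sr)
  expect_error(stack_richness(cube, species = character(0)), "empty group")
})

test_that("ensemble change handles identity, sign agreement and masking", {
  members <- tidyr::crossing(algorithm = c("glm", "gam"), set = c("p1", "p2"),
                             cell = 1:3)
  pres <- members |> dplyr::mutate(esm = "obs", sr = 10)
  fut <- members |> dplyr::mutate(esm = "ESM1", sr = 10)
  ch0 <- ensemble_change(pres, fut)
  expect_equal(unique(ch0$pct_mean), 0)
  expect_equal(unique(ch0$pct_iqr), 0)
  expect_false(any(ch0$stipple)) # no non-zero member -> agreement undefined
  # all members positive -> full agreement, stipple on
  futp <- members |> dplyr::mutate(esm = "ESM1", sr = 12)
  chp <- ensemble_change(pres, futp)
  expect_equal(unique(chp$agreement), 1)
  expect_true(all(chp$stipple))
  # 3 of 4 members positive -> agreement 0.75, stipple off at the 0.9 rule
  futm <- futp
  futm$sr[futm$algorithm == "gam" & futm$set == "p2"] <- 8
  chm <- ensemble_change(pres, futm)
  expect_equal(unique(chm$agreement), 0.75)
  expect_false(any(chm$stipple))
  # cells below the present-SR mask are undefined
  pres2 <- pres |> dplyr::mutate(sr = ifelse(cell == 2, 0.1, sr))
  chmask <- ensemble_change(pres2, futp)
  expect_true(is.na(chmask$pct_mean[chmask$cell == 2]))
})

test_that("variance attribution sums to about one over the factorial axes", {
  set.seed(5)
  members <- tidyr::crossing(algorithm = c("glm", "gam", "rf", "ann"),
                             set = c("p1", "p2"), cell = 1)
  pres <- members |> dplyr::mutate(esm = "obs", sr = 10)
  fut <- tidyr::crossing(members, esm = c("E1", "E2")) |>
    dplyr::mutate(sr = 10 + 2 * (algorithm == "rf") + rnorm(dplyr::n(), 0, 0.1))
  ch <- ensemble_change(pres, fut)
  expect_gt(ch$var_algorithm, ch$var_esm)
  expect_lte(ch$var_algorithm + ch$var_set + ch$var_esm, 1 + 1e-9)
})

test_that("MESS branch formulas match the brute-force oracle and sign rule", {
  set.seed(8)
  ref <- tibble::tibble(a = rnorm(40), b = runif(40))
  proj <- tibble::tibble(cell = 1:200, month = 1L,
                         a = rnorm(200, 0, 2), b = runif(200, -0.5, 1.5))
  m <- compute_mess(ref, proj, c("a", "b"))
  for (i in seq_len(50)) {
    sims <- c(oracle_mess_one(proj$a[i], ref$a), oracle_mess_one(proj$b[i], ref$b))
    expect_equal(m$mess[i], min(sims), tolerance = 1e-12)
    expect_equal(m$driver[i], c("a", "b")[which.min(sims)])
    out_of_range <- proj$a[i] < min(ref$a) || proj$a[i] > max(ref$a) ||
      proj$b[i] < min(ref$b) || proj$b[i] > max(ref$b)
    expect_equal(m$mess[i] < 0, out_of_range)
  }
})

test_that("MESS hits its landmark values at the median, minimum and beyond", {
  ref <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  proj <- tibble::tibble(cell = 1:4, month = 1L, x = c(5.5, 1, 0, 10))
  m <- compute_mess(ref, proj, "x")
  expect_equal(m$mess[1], 100) # f = 50 at the median -> 2 * 50
  expect_equal(m$mess[2], 0)   # at the reference minimum
  expect_lt(m$mess[3], 0)      # below the minimum: non-analog
  expect_equal(m$mess[4], 20)  # at the max of 10 values, f = 90 -> 2 * (100 - 90)
  # degenerate reference: 0 at the value, large negative elsewhere
  refc <- tibble::tibble(x = rep(2, 5))
  mc <- compute_mess(refc, proj, "x")
  expect_equal(mc$mess, c(-1e4, -1e4, -1e4, -1e4))
})
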