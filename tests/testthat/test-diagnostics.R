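k_b <- 8.617333e-5

test_that("the MTE fit recovers a noiseless Boltzmann slope exactly", {
  set.seed(2)
  sst <- runif(400, -2, 32)
  d <- tibble::tibble(sst = sst,
                      sr = exp(20 - 0.65 / (k_b * (sst + 273.15))))
  fit <- mte_fit(d, window = c(5, 30))
  expect_equal(fit$slope_ev, 0.65, tolerance = 1e-6)
  expect_equal(fit$slope_sign, -1)
  expect_equal(fit$r2_linear, 1, tolerance = 1e-9)
  # constant richness: zero slope
  d0 <- tibble::tibble(sst = sst, sr = 42)
  expect_equal(mte_fit(d0, window = c(5, 30))$slope_ev, 0, tolerance = 1e-12)
  expect_error(mte_fit(d, window = c(60, 70)), "too few")
  g <- generics::glance(fit)
  expect_equal(g$slope_ev, fit$slope_ev)
  expect_equal(nrow(generics::tidy(fit)), 2)
})

test_that("the haversine distance agrees with a law-of-cosines oracle", {
  set.seed(6)
  for (i in 1:20) {
    lon <- runif(2, -180, 180); lat <- runif(2, -85, 85)
    hav <- geosphere::distHaversine(c(lon[1], lat[1]), c(lon[2], lat[2]),
                                    r = 6371000) / 1000
    sloc <- oracle_sloc_km(lon[1], lat[1], lon[2], lat[2])
    expect_lt(abs(hav - sloc), 0.1)
  }
})

test_that("a one-degree poleward centroid shift gives the textbook velocity", {
  spec <- grid_spec(cell_size = 1, lat_min = 30, lat_max = 50,
                    lon_min = 0, lon_max = 20)
  cells <- grid_cells(spec)
  mk <- function(lat0) tibble::tibble(
    species_id = "s1", cell = cells$cell,
    hsi = as.numeric(cells$lat == lat0 & cells$lon == 10.5)
  )
  rs <- range_shift(mk(40.5), mk(41.5), spec)
  expect_equal(rs$distance_km, 111.195, tolerance = 1e-3)
  expect_equal(rs$velocity_km_per_decade, 111.195 / 6.9, tolerance = 1e-3)
  expect_true(rs$poleward)
  # identical fields: zero velocity, not poleward
  rs0 <- range_shift(mk(40.5), mk(40.5), spec)
  expect_equal(rs0$velocity_km_per_decade, 0)
  expect_false(rs0$poleward)
  # all-zero suitability flags the species as undefined
  z <- mk(40.5); z$hsi <- 0
  rsz <- range_shift(z, mk(40.5), spec)
  expect_true(is.na(rsz$distance_km))
})

test_that("bipolar ranges use the dominant hemisphere instead of cancelling", {
  spec <- grid_spec(cell_size = 10)
  cells <- grid_cells(spec)
  w <- ifelse(cells$lat > 0, 1, 0.4) * as.numeric(abs(cells$lat) %in% c(45))
  p <- tibble::tibble(species_id = "s", cell = cells$cell, hsi = w)
  f <- p # unchanged
  rs <- range_shift(p, f, spec)
  expect_equal(rs$lat_present, 45, tolerance = 1e-9)
})

test_that("severity clustering recovers well-separated structure in change space", {
  set.seed(10)
  n <- 150
  blob <- function(mu, n) {
    tibble::tibble(
      d_sr_phyto = rnorm(n, mu[1], 0.3), d_sr_zoo = rnorm(n, mu[2], 0.3),
      st_phyto = rnorm(n, mu[3], 0.3), st_zoo = rnorm(n, mu[4], 0.3),
      jac = rnorm(n, mu[5], 0.3)
    )
  }
  change <- dplyr::bind_rows(blob(c(0, 0, 0, 0, 0), n),
                             blob(c(4, 4, 4, 4, 4), n)) |>
    dplyr::mutate(cell = dplyr::row_number())
  truth <- rep(1:2, each = n)
  fields <- c("d_sr_phyto", "d_sr_zoo", "st_phyto", "st_zoo", "jac")
  res <- severity_cluster(change, fields, k_range = 2:6, seed = 3)
  expect_equal(res$k, 2)
  expect_equal(res$profiles$k[which.max(res$profiles$calinski_harabasz)], 2)
  ari <- mclust::adjustedRandIndex(res$regions$region, truth)
  expect_gt(ari, 0.9)
  expect_gte(sum(res$variance_share[seq_len(res$n_pcs)]), 0.95)
})

test_that("severity is zero at the PC origin, sign-flip and order invariant", {
  set.seed(11)
  n <- 120
  change <- tibble::tibble(
    cell = 1:n, a = rnorm(n), b = rnorm(n), c = rnorm(n)
  )
  res <- severity_cluster(change, c("a", "b", "c"), k_range = 2:3, seed = 1)
  # severity = |weighted score sum|: non-negative, zero iff the weighted sum is
  expect_true(all(res$regions$severity >= 0))
  scores <- as.matrix(res$regions[, grep("^PC", names(res$regions))])
  w <- res$variance_share[seq_len(res$n_pcs)]
  expect_equal(res$regions$severity, abs(as.vector(scores %*% w)))
  # permuting cells permutes severity identically
  perm <- sample(n)
  res2 <- severity_cluster(change[perm, ], c("a", "b", "c"),
                           k_range = 2:3, seed = 1)
  m <- match(res$regions$cell, res2$regions$cell)
  expect_equal(res$regions$severity, res2$regions$severity[m])
  # constant fields are dropped; all-constant input is refused
  expect_warning(
    severity_cluster(dplyr::mutate(change, k = 1), c("a", "b", "k"),
                     k_range = 2:3),
    "constant"
  )
  expect_error(
    suppressWarnings(severity_cluster(dplyr::mutate(change, k = 1, l = 2),
                                      c("k", "l"), k_range = 2:3)),
    "refused"
  )
})

test_that("the weighted median honours its conventions", {
  # equal weights reduce to the ordinary median
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1))
    expect_equal(weighted_median(x, rep(1, length(x))), median(x))
  }
  # two species, equal suitability: midpoint convention
  expect_equal(weighted_median(c(1, 3), c(0.5, 0.5)), 2)
  # single species: its own trait
  expect_equal(weighted_median(7, 0.3), 7)
  expect_true(is.na(weighted_median(c(1, 2), c(0, 0))))
})

test_that("trait preparation applies the genus fallback and S/V exclusion", {
  traits <- tibble::tibble(
    species_id = c("s1", "s2", "s3", "s4"),
    genus = c("G1", "G1", "G1", "G2"),
    trait_value = c(10, 20, 99, 5),
    n_measurements = c(10, 8, 2, 20),
    sv_ratio = c(1, 2, 3, 12)
  )
  out <- prepare_traits(traits)
  expect_equal(out$trait_value[out$species_id == "s3"], mean(c(10, 20, 99)))
  expect_equal(out$source[out$species_id == "s3"], "genus")
  expect_false("s4" %in% out$species_id) # S/V > 10 outlier dropped
})

test_that("community trait structure responds to warm-small replacement", {
  pres <- tibble::tibble(
    species_id = c("small", "large"), cell = 1,
    hsi = c(0.2, 0.8)
  )
  fut <- tibble::tibble(
    species_id = c("small", "large"), cell = 1,
    hsi = c(0.8, 0.2)
  )
  traits <- tibble::tibble(species_id = c("small", "large"),
                           trait_value = c(10, 1000))
  w <- weighted_trait_structure(pres, traits, fut)
  expect_lt(w$trait_median_future, w$trait_median)
  expect_lt(w$pct_change, 0)
  # zero total weight masks the cell
  z <- weighted_trait_structure(dplyr::mutate(pres, hsi = 0), traits)
  expect_true(is.na(z$trait_median))
})

test_that("service overlap tests behave under null, shifted and hand fixtures", {
  set.seed(13)
  regions <- tibble::tibble(cell = 1:300, region = rep(1:3, each = 100))
  # identical distribution across regions: omnibus p large, no pairwise table
  svc_null <- tibble::tibble(cell = 1:300, flat = rnorm(300))
  r_null <- service_overlap_tests(regions, svc_null)
  expect_gt(r_null$kruskal$p_value, 0.01)
  expect_equal(nrow(r_null$pairwise), 0)
  # one region shifted by 10 sigma: tiny p, all its pairs significant
  svc <- tibble::tibble(cell = 1:300,
                        shifted = rnorm(300) + 10 * (regions$region == 2))
  r <- service_overlap_tests(regions, svc)
  expect_lt(r$kruskal$p_value, 1e-6)
  pw <- r$pairwise
  with2 <- pw[pw$region_a == "2" | pw$region_b == "2", ]
  expect_true(all(with2$p_adjusted < 0.01))
  expect_equal(nrow(pw), 3 * 2 / 2) # k(k-1)/2 pairwise tests
  # Bonferroni never lowers a p-value below the raw pairwise p
  raw <- pairwise.wilcox.test(svc$shifted, factor(regions$region),
                              p.adjust.method = "none", exact = FALSE)$p.value
  adj <- pairwise.wilcox.test(svc$shifted, factor(regions$region),
                              p.adjust.method = "bonferroni", exact = FALSE)$p.value
  expect_true(all(adj >= raw - 1e-12, na.rm = TRUE))
  # hand-computed Kruskal-Wallis statistic on a small two-region table
  d <- tibble::tibble(cell = 1:6, region = c(1, 1, 1, 2, 2, 2))
  svc2 <- tibble::tibble(cell = 1:6, v = c(1, 3, 5, 2, 4, 6))
  r2 <- service_overlap_tests(d, svc2, alpha = 0.01)
  rk <- rank(svc2$v)
  n <- 6
  h <- 12 / (n * (n + 1)) * (sum(rk[1:3])^2 / 3 + sum(rk[4:6])^2 / 3) - 3 * (n + 1)
  expect_equal(r2$kruskal$statistic, h, tolerance = 1e-12)
  # constant variable is skipped with a note
  svc3 <- tibble::tibble(cell = 1:300, k = 1)
  r3 <- service_overlap_tests(regions, svc3)
  expect_match(r3$kruskal$note, "skipped")
})
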