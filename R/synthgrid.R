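#' Generate a synthetic monthly environmental climatology
#'
#' Builds twelve monthly gridded fields for the primary surface-ocean
#' variables used throughout the pipeline: sea surface temperature (`sst`,
#' degrees C), mixed-layer depth (`mld`, m), photosynthetically active
#' radiation (`par`, umol m-2 s-1), macronutrients (`no3`, `po4`, `sioh4`,
#' uM), chlorophyll a (`chl`, mg m-3), dissolved oxygen at depth (`do2`,
#' ml l-1), surface wind (`wind`, m s-1), sea surface salinity (`sss`) and
#' geostrophic velocity anomaly components (`uo`, `vo`, m s-1) from which
#' eddy kinetic energy is later derived.
#'
#' The construction emulates the gross structure of observational
#' climatologies: SST decreases monotonically with absolute latitude in
#' every month, carries a sinusoidal seasonal cycle whose amplitude grows
#' poleward and is phase-shifted by six months between hemispheres, and
#' nutrients, chlorophyll and oxygen are (anti-)correlated with SST.
#' Cell-level noise for SST is constant across months so that a zero
#' `seasonal_amp` yields an SST field with exactly zero annual range.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param sst_tropical,sst_polar Annual-mean SST at the equator and the
#'   poles (degrees C).
#' @param seasonal_amp Peak seasonal SST amplitude at the poles (degrees C);
#'   scales linearly with latitude.
#' @param noise_sd Standard deviation of the cell-level SST noise.
#'
#' @return A `clim_stack` tibble with one row per (cell, month) and one
#'   column per field, carrying the grid as an attribute.
#' @examples
#' env <- generate_environment(grid_spec(cell_size = 30), seed = 1)
#' @export
generate_environment <- function(spec, seed,
                                 sst_tropical = 29, sst_polar = -1,
                                 seasonal_amp = 4, noise_sd = 0.5) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.numeric(seed) || length(seed) != 1) abort("`seed` must be a single integer.")
  set.seed(as.integer(seed))

  cells <- grid_cells(spec)
  n_cell <- nrow(cells)
  # cell-level (month-constant) perturbations, drawn once in fixed order
  eps_sst  <- rnorm(n_cell, 0, noise_sd)
  eps_nut  <- rnorm(n_cell, 0, 1)
  eps_si   <- rnorm(n_cell, 0, 1)
  eps_mld  <- rnorm(n_cell, 0, 1)
  eps_par  <- rnorm(n_cell, 0, 1)
  eps_chl  <- rnorm(n_cell, 0, 0.3)
  eps_do2  <- rnorm(n_cell, 0, 0.3)
  eps_sss  <- rnorm(n_cell, 0, 0.3)
  eps_wind <- rnorm(n_cell, 0, 0.5)

  grid <- tidyr::crossing(cells, month = spec$months) |> arrange(.data$cell, .data$month)
  lat <- grid$lat
  lon <- grid$lon
  m <- grid$month
  latr <- lat * pi / 180
  # NH summer peaks in August; the SH phase flips through the signed lat term,
  # and a smooth zonal factor modulates the amplitude so the annual range is
  # not a pure function of latitude
  amp_mod <- 1 + 0.4 * sin(lon * pi / 60)
  season <- cos(2 * pi * (m - 8) / 12) * (lat / 90)
  idx <- grid$cell

  sst <- sst_polar + (sst_tropical - sst_polar) * cos(latr) +
    seasonal_amp * amp_mod * season + eps_sst[idx]
  winter <- 0.5 + 0.5 * cos(2 * pi * (m - ifelse(lat >= 0, 2, 8)) / 12)
  # eastern-boundary-style upwelling bands decouple nutrients from SST
  upw <- pmax(0, sin((lon - 80) * pi / 180)) * cos(latr)^2
  upw2 <- pmax(0, sin((lon + 60) * pi / 180)) * cos(latr)^2
  mld <- pmax(10, 25 + 110 * abs(lat / 90) * winter + 15 * upw + 12 * eps_mld[idx])
  par <- pmax(1, 62 - 42 * abs(lat / 90) + 18 * season + 6 * eps_par[idx])
  no3 <- pmax(0.05, 14 - 0.5 * sst + 10 * upw + 3 * winter + 2.2 * eps_nut[idx])
  po4 <- pmax(0.01, no3 / 16 + 0.06 * eps_chl[idx])
  sioh4 <- pmax(0.05, 16 - 0.5 * sst + 8 * upw2 + 2 * winter + 2.2 * eps_si[idx])
  chl <- exp(-1.8 + 0.09 * no3 + 0.8 * eps_chl[idx])
  # oxygen declines with temperature but also under the upwelling bands
  # (oxygen-minimum-zone analogue), so it is not a pure SST proxy
  do2 <- pmax(1, 7.8 - 0.10 * sst - 2.5 * upw + 0.8 * eps_do2[idx])
  wind <- pmax(0.5, 4.5 + 3.5 * abs(sin(2 * latr)) + eps_wind[idx])
  sss <- 34 + 1.6 * cos(2 * latr) + eps_sss[idx]
  vel_sd <- 0.25 * (1 - 0.7 * abs(lat / 90))
  uo <- rnorm(nrow(grid), 0, vel_sd)
  vo <- rnorm(nrow(grid), 0, vel_sd)

  out <- grid |>
    mutate(
      sst = sst, mld = mld, par = par, no3 = no3, po4 = po4,
      sioh4 = sioh4, chl = chl, do2 = do2, wind = wind, sss = sss,
      uo = uo, vo = vo
    )
  as_clim_stack(out, spec)
}

#' Generate virtual species with unimodal environmental niches
#'
#' Each species' habitat suitability is a product of Gaussian terms, one
#' per niche predictor, scaled by `max_suitability`: a smooth, bounded
#' response surface with a known optimum that downstream recovery tests
#' can check against. Niche centres are drawn inside the observed range of
#' each predictor (central quantiles), and a body/cell size trait can be
#' generated with a configurable rank correlation to the thermal niche
#' centre (negative values encode "warm means small").
#'
#' @param env A `clim_stack` (derive first if niches use derived
#'   predictors) providing the observed environmental ranges.
#' @param n_species Number of species to create.
#' @param predictors Character vector of niche predictors (columns of
#'   `env`).
#' @param seed Integer seed.
#' @param centre_quantiles Quantiles of the observed predictor distribution
#'   between which niche centres are drawn.
#' @param breadth_frac Range (fraction of the observed predictor range)
#'   from which niche breadths are drawn.
#' @param max_suitability Range of the species' maximal suitability.
#' @param size_temp_rho Gaussian-copula correlation between log trait size
#'   and the `sst` niche centre (ignored when `sst` is not a niche axis).
#' @param prop_zoo Proportion of species labelled zooplankton.
#'
#' @return A tibble with one row per species: `species_id`,
#'   `trophic_group`, `target_group`, `max_suitability`, `trait_size` and
#'   a `niche` list-column of (predictor, centre, breadth) tibbles.
#' @export
generate_species <- function(env, n_species,
                             predictors = "sst",
                             seed = 1,
                             centre_quantiles = c(0.05, 0.95),
                             breadth_frac = c(0.08, 0.2),
                             max_suitability = c(0.7, 1),
                             size_temp_rho = -0.5,
                             prop_zoo = 0.5) {
  if (n_species < 1) abort("`n_species` must be at least 1.")
  if (length(predictors) < 1) abort("At least one niche predictor is required.")
  missing <- setdiff(predictors, names(env))
  if (length(missing) > 0) {
    abort(paste0("Niche predictors not found in `env`: ", paste(missing, collapse = ", ")))
  }
  set.seed(as.integer(seed))

  ranges <- purrr::map(predictors, function(p) {
    v <- env[[p]]
    q <- quantile(v, centre_quantiles, na.rm = TRUE, names = FALSE)
    list(lo = q[1], hi = q[2], span = diff(range(v, na.rm = TRUE)))
  })
  names(ranges) <- predictors

  z_sst <- rnorm(n_species)
  niches <- purrr::map(seq_len(n_species), function(i) {
    tibble(
      predictor = predictors,
      centre = purrr::map_dbl(predictors, function(p) {
        r <- ranges[[p]]
        if (p == "sst") {
          # keep sst centres copula-linked to the size trait
          r$lo + (r$hi - r$lo) * pnorm(z_sst[i])
        } else {
          runif(1, r$lo, r$hi)
        }
      }),
      breadth = purrr::map_dbl(predictors, function(p) {
        ranges[[p]]$span * runif(1, breadth_frac[1], breadth_frac[2])
      })
    )
  })

  rho <- if ("sst" %in% predictors) size_temp_rho else 0
  z_size <- rho * z_sst + sqrt(max(0, 1 - rho^2)) * rnorm(n_species)
  trait_size <- qlnorm(pnorm(z_size), meanlog = log(50), sdlog = 1)

  trophic <- ifelse(runif(n_species) < prop_zoo, "zoo", "phyto")
  tibble(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    trophic_group = trophic,
    target_group = trophic,
    max_suitability = runif(n_species, max_suitability[1], max_suitability[2]),
    trait_size = trait_size,
    niche = niches
  )
}

#' Evaluate virtual-species habitat suitability on a climatology
#'
#' @param species A species table from [generate_species()].
#' @param env A `clim_stack` containing the niche predictors.
#' @return A tibble (species_id, cell, month, suitability).
#' @export
true_suitability <- function(species, env) {
  purrr::map_dfr(seq_len(nrow(species)), function(i) {
    nic <- species$niche[[i]]
    s <- rep(species$max_suitability[i], nrow(env))
    for (j in seq_len(nrow(nic))) {
      v <- env[[nic$predictor[j]]]
      s <- s * exp(-0.5 * ((v - nic$centre[j]) / nic$breadth[j])^2)
    }
    tibble(
      species_id = species$species_id[i],
      cell = env$cell, month = env$month, suitability = s
    )
  })
}

#' Build a gridded monthly sampling-effort field
#'
#' Effort is a mixture of a uniform component and an optional Gaussian
#' "bump" mimicking the historical oversampling of particular basins
#' (by default a North-Atlantic-like sector).
#'
#' @param spec A [grid_spec()].
#' @param bias `"uniform"` or `"bump"`.
#' @param bump_lon,bump_lat,bump_sd Bump centre and width (degrees).
#' @param bump_weight Mixture weight of the bump component in `[0, 1]`.
#' @return A tibble (cell, month, effort), effort summing to 1.
#' @export
sampling_effort <- function(spec, bias = c("uniform", "bump"),
                            bump_lon = -30, bump_lat = 45, bump_sd = 25,
                            bump_weight = 0.7) {
  bias <- match.arg(bias)
  g <- tidyr::crossing(grid_cells(spec), month = spec$months)
  e <- rep(1, nrow(g))
  if (bias == "bump") {
    d2 <- ((g$lon - bump_lon) / bump_sd)^2 + ((g$lat - bump_lat) / bump_sd)^2
    e <- (1 - bump_weight) * e / sum(e) + bump_weight * exp(-0.5 * d2) / sum(exp(-0.5 * d2))
  }
  g |>
    mutate(effort = e / sum(e)) |>
    select("cell", "month", "effort")
}

#' Sample biased occurrence records from virtual species
#'
#' Records are drawn with probability proportional to
#' `effort x suitability`, then dressed up as raw occurrence rows with the
#' standard column set (coordinates jittered within the cell, sampling
#' date, depths, salinity, bathymetry, source). A configurable fraction of
#' records is contaminated with exactly one quality-control violation
#' (missing coordinate, incomplete date, pre-1800 year, missing depth,
#' genus-level name, sediment-core source, brackish salinity, shallow
#' bathymetry, or a net tow deeper than 500 m) so the filter chain has
#' known prey.
#'
#' @param species Species table from [generate_species()].
#' @param env A `clim_stack` with the niche predictors.
#' @param n_records Number of records to draw.
#' @param effort Optional effort field from [sampling_effort()]; uniform
#'   when `NULL`. Must be non-negative and not all zero.
#' @param contamination Fraction of records given one QC violation.
#' @param seed Integer seed.
#' @param year_range Sampling years drawn uniformly from this range.
#'
#' @return An occurrence tibble with columns `species_id`,
#'   `decimal_longitude`, `decimal_latitude`, `year`, `month`, `day`,
#'   `depth_m`, `max_net_depth_m`, `salinity_at_point`, `bathymetry_m`,
#'   `source`.
#' @export
sample_occurrences <- function(species, env, n_records,
                               effort = NULL, contamination = 0.05,
                               seed = 1, year_range = c(1950, 2015)) {
  spec <- get_grid(env)
  if (is.null(effort)) effort <- sampling_effort(spec)
  if (any(effort$effort < 0)) abort("`effort` must be non-negative.")
  if (all(effort$effort == 0)) abort("`effort` must not be all zero.")
  set.seed(as.integer(seed))

  suit <- true_suitability(species, env) |>
    left_join(effort, by = c("cell", "month")) |>
    mutate(w = .data$suitability * coalesce(.data$effort, 0))
  if (sum(suit$w) <= 0) abort("All sampling weights are zero; check effort and niches.")

  take <- sample.int(nrow(suit), n_records, replace = TRUE, prob = suit$w)
  drawn <- suit[take, c("species_id", "cell", "month")]
  cells <- grid_cells(spec)
  drawn <- left_join(drawn, cells, by = "cell")
  half <- spec$cell_size / 2

  depth <- runif(n_records, 0, 150)
  occ <- tibble(
    species_id = drawn$species_id,
    decimal_longitude = drawn$lon + runif(n_records, -half, half),
    decimal_latitude = pmin(
      spec$lat_max - 1e-6,
      pmax(spec$lat_min, drawn$lat + runif(n_records, -half, half))
    ),
    year = sample(seq(year_range[1], year_range[2]), n_records, replace = TRUE),
    month = drawn$month,
    day = sample.int(28, n_records, replace = TRUE),
    depth_m = depth,
    max_net_depth_m = pmin(500, depth + runif(n_records, 0, 150)),
    salinity_at_point = runif(n_records, 33, 37),
    bathymetry_m = runif(n_records, 1000, 6000),
    source = "synthetic-survey"
  )

  n_bad <- round(contamination * n_records)
  if (n_bad > 0) {
    bad <- sample.int(n_records, n_bad)
    kinds <- sample(c(
      "coord", "date", "year", "depth", "taxon", "fossil",
      "salinity", "shallow", "deep_net"
    ), n_bad, replace = TRUE)
    for (i in seq_along(bad)) {
      r <- bad[i]
      occ[r, ] <- switch(kinds[i],
        coord = { occ$decimal_longitude[r] <- NA_real_; occ[r, ] },
        date = { occ$day[r] <- NA_integer_; occ[r, ] },
        year = { occ$year[r] <- 1750L; occ[r, ] },
        depth = { occ$depth_m[r] <- NA_real_; occ$max_net_depth_m[r] <- NA_real_; occ[r, ] },
        taxon = { occ$species_id[r] <- paste(occ$species_id[r], "sp."); occ[r, ] },
        fossil = { occ$source[r] <- "sediment core archive"; occ[r, ] },
        salinity = { occ$salinity_at_point[r] <- runif(1, 5, 19.9); occ[r, ] },
        shallow = { occ$bathymetry_m[r] <- runif(1, 10, 199); occ[r, ] },
        deep_net = { occ$max_net_depth_m[r] <- runif(1, 501, 2000); occ[r, ] }
      )
    }
  }
  attr(occ, "n_contaminated") <- n_bad
  occ
}

#' Default pseudo earth-system-model configurations
#'
#' Five pseudo-ESMs spanning a spread of climate sensitivities, emulating
#' the situation where some forcing models are markedly more sensitive
#' than others.
#'
#' @param n Number of pseudo-ESMs.
#' @param warming Global-mean SST warming per ESM (degrees C); recycled to
#'   length `n`.
#' @param amplification Polar amplification factor (0 = spatially uniform
#'   warming).
#' @return A tibble (esm_id, warming, amplification).
#' @export
esm_configs <- function(n = 5,
                        warming = c(1.5, 2, 2.5, 3, 4),
                        amplification = 0.5) {
  tibble(
    esm_id = sprintf("ESM%d", seq_len(n)),
    warming = rep_len(warming, n),
    amplification = rep_len(amplification, n)
  )
}

#' Generate additive future anomaly fields for pseudo-ESMs
#'
#' For each pseudo-ESM the SST anomaly is `warming * (1 + amplification *
#' (|lat|/90 - 0.5))` (spatially uniform when `amplification = 0`), and
#' the biogeochemical fields respond with fixed sensitivities to the local
#' SST anomaly (stratification-like nutrient decline, chlorophyll and
#' oxygen decline, mixed-layer shoaling). Anomalies are deltas on the
#' linear scale of each field; a zero `warming` gives identically zero
#' anomalies for every field.
#'
#' @param env A `clim_stack` (present-day baseline).
#' @param configs A tibble from [esm_configs()].
#' @param seed Integer seed (reserved; the default pattern is
#'   deterministic).
#' @return A long tibble (esm_id, cell, month, predictor, delta) of class
#'   `anomaly_set`.
#' @export
generate_future_anomalies <- function(env, configs = esm_configs(), seed = 1) {
  if (nrow(configs) < 1) abort("At least one ESM configuration is required.")
  spec <- get_grid(env)
  base <- env |> select("cell", "lon", "lat", "month")
  sens <- c(no3 = -1.2, po4 = -0.075, sioh4 = -1.0, chl = -0.05,
            do2 = -0.12, mld = -3, par = 0, wind = 0, sss = 0, uo = 0, vo = 0)
  out <- purrr::map_dfr(seq_len(nrow(configs)), function(k) {
    w <- configs$warming[k]
    a <- configs$amplification[k]
    d_sst <- w * (1 + a * (abs(base$lat) / 90 - 0.5))
    if (w == 0) d_sst <- rep(0, nrow(base))
    fields <- c(list(sst = d_sst),
                purrr::map(sens, function(s) s * d_sst * (w != 0)))
    purrr::imap_dfr(fields, function(delta, nm) {
      tibble(
        esm_id = configs$esm_id[k],
        cell = base$cell, month = base$month,
        predictor = nm, delta = delta
      )
    })
  })
  out <- set_grid(out, spec)
  class(out) <- unique(c("anomaly_set", class(out)))
  out
}
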