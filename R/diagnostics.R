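#' Metabolic-theory temperature-richness fit
#'
#' Under the metabolic theory of ecology, ln(richness) is linear in
#' inverse thermal energy `1/(kT)` (T in Kelvin, k Boltzmann's constant
#' in eV/K) with slopes near 0.32 eV for autotrophs and 0.65 eV for
#' heterotrophs. The fit regresses `ln(SR)` on `1/(kT)` by OLS over the
#' cells whose SST lies inside the temperature window, reports the slope
#' magnitude in eV (sign stored separately), and also fits a 3rd-degree
#' polynomial over the full thermal range to expose the non-linear parts
#' of the gradient.
#'
#' @param data A tibble with one row per cell.
#' @param sr,sst Column names (tidy-select style strings) of annual-mean
#'   richness and SST (degrees C).
#' @param window `[lo, hi]` SST window (degrees C) for the linear fit.
#' @return An object of class `mte_fit` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' d <- tibble::tibble(sst = runif(100, 0, 30))
#' d$sr <- exp(8 - 0.6 / (8.617333e-5 * (d$sst + 273.15)))
#' mte_fit(d, window = c(10, 30))$slope_ev
#' @export
mte_fit <- function(data, sr = "sr", sst = "sst", window = c(22, 35)) {
  d <- tibble(sr = data[[sr]], sst = data[[sst]])
  d <- filter(d, !is.na(.data$sr), !is.na(.data$sst), .data$sr > 0)
  d <- mutate(d, x = 1 / (.k_boltzmann * (.data$sst + 273.15)),
              lnsr = log(.data$sr))
  in_win <- d$sst >= window[1] & d$sst <= window[2]
  if (sum(in_win) < 2) abort("The temperature window contains too few cells.")
  linear <- lm(lnsr ~ x, data = d[in_win, ])
  slope <- unname(coef(linear)[2])
  # summary.lm warns on noiseless (exact) fits; those are legitimate here
  lin_summary <- suppressWarnings(summary(linear))
  poly3 <- if (nrow(d) >= 4 && length(unique(d$x)) >= 4) {
    lm(lnsr ~ poly(x, 3), data = d)
  } else {
    NULL
  }
  structure(
    list(
      linear = linear, poly3 = poly3,
      slope_ev = abs(slope), slope_sign = sign(slope),
      window = window, n_window = sum(in_win), n_total = nrow(d),
      r2_linear = lin_summary$r.squared,
      r2_poly3 = if (is.null(poly3)) NA_real_
                 else suppressWarnings(summary(poly3))$r.squared,
      data = d
    ),
    class = "mte_fit"
  )
}

#' @export
print.mte_fit <- function(x, ...) {
  cat(sprintf(
    "<mte_fit> |slope| = %.3f eV (sign %+d) over SST in [%g, %g] C (n = %d); linear R2 = %.3f\n",
    x$slope_ev, x$slope_sign, x$window[1], x$window[2], x$n_window, x$r2_linear
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mte_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$linear))$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @export
glance.mte_fit <- function(x, ...) {
  tibble(
    slope_ev = x$slope_ev, slope_sign = x$slope_sign,
    r2_linear = x$r2_linear, r2_poly3 = x$r2_poly3,
    n_window = x$n_window, n_total = x$n_total
  )
}

# Weighted centroid of a suitability field on one hemisphere; longitudes
# are averaged circularly so ranges straddling the date line behave.
hsi_centroid <- function(lon, lat, w) {
  lr <- lon * pi / 180
  lon_c <- atan2(sum(w * sin(lr)), sum(w * cos(lr))) * 180 / pi
  tibble(lon = lon_c, lat = sum(w * lat) / sum(w))
}

#' Species range-shift centroids and velocities
#'
#' The range centroid of each species is the suitability-weighted mean of
#' the cell-centre coordinates, computed on the hemisphere holding the
#' larger share of suitability mass (preventing the centroids of bipolar
#' ranges from cancelling at the equator). The shift between periods is
#' the great-circle (haversine, R = 6371 km) distance between present
#' and future centroids; velocity divides by the elapsed time between
#' the period midpoints (2021.5 to 2090.5, i.e. 6.9 decades). A species
#' is poleward-shifting when its future centroid sits at a higher
#' absolute latitude than its present one.
#'
#' @param present,future Annual HSI tibbles (species_id, cell, hsi) on
#'   the same grid; member columns, if present, should be averaged first.
#' @param spec The [grid_spec()] giving cell-centre coordinates.
#' @param period_midpoints Decimal-year midpoints of the two periods.
#' @return A `range_shift` tibble: per-species centroids, distance (km),
#'   velocity (km/decade) and `poleward` flag (`NA` rows flag all-zero
#'   suitability).
#' @export
range_shift <- function(present, future, spec,
                        period_midpoints = c(2021.5, 2090.5)) {
  cells <- grid_cells(spec)
  decades <- diff(period_midpoints) / 10
  per_species <- function(d) {
    d <- d |>
      group_by(.data$species_id, .data$cell) |>
      summarise(hsi = mean(.data$hsi, na.rm = TRUE), .groups = "drop") |>
      left_join(cells, by = "cell")
    d |>
      group_by(.data$species_id) |>
      summarise(centroid = {
        w <- .data$hsi
        if (sum(w) <= 0) {
          list(tibble(lon = NA_real_, lat = NA_real_))
        } else {
          north <- .data$lat >= 0
          use <- if (sum(w[north]) >= sum(w[!north])) north else !north
          list(hsi_centroid(.data$lon[use], .data$lat[use], w[use]))
        }
      }, .groups = "drop") |>
      tidyr::unnest("centroid")
  }
  p <- per_species(as_tibble(present))
  f <- per_species(as_tibble(future))
  out <- inner_join(p, f, by = "species_id", suffix = c("_present", "_future")) |>
    mutate(
      distance_km = purrr::pmap_dbl(
        list(.data$lon_present, .data$lat_present,
             .data$lon_future, .data$lat_future),
        function(lo1, la1, lo2, la2) {
          if (anyNA(c(lo1, la1, lo2, la2))) return(NA_real_)
          geosphere::distHaversine(c(lo1, la1), c(lo2, la2), r = 6371000) / 1000
        }
      ),
      velocity_km_per_decade = .data$distance_km / decades,
      poleward = abs(.data$lat_future) > abs(.data$lat_present)
    )
  class(out) <- unique(c("range_shift", class(out)))
  out
}

#' Population summaries of range shifts
#'
#' Emits both readings of the headline velocity: over all species and
#' over poleward shifters only, each with median, standard deviation and
#' IQR.
#'
#' @param shifts A [range_shift()] tibble.
#' @return A two-row tibble (`subset` = all / poleward).
#' @export
shift_summary <- function(shifts) {
  ok <- filter(shifts, !is.na(.data$velocity_km_per_decade))
  summarize_subset <- function(d, label) {
    tibble(
      subset = label,
      n = nrow(d),
      median_velocity = median(d$velocity_km_per_decade),
      sd_velocity = sd(d$velocity_km_per_decade),
      iqr_velocity = stats::IQR(d$velocity_km_per_decade),
      pct_poleward = 100 * mean(ok$poleward)
    )
  }
  bind_rows(
    summarize_subset(ok, "all"),
    summarize_subset(filter(ok, .data$poleward), "poleward")
  )
}

# Calinski-Harabasz index (between-variance ratio criterion).
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, ci)^2)
    b <- b + nrow(xi) * sum((ci - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Regionalise climate-impact severity by PCA + k-medoids
#'
#' Standardises the change fields (percentage richness changes and
#' turnover components), reduces them by PCA, clusters the cells with
#' k-medoids (PAM) on the Euclidean distances between the retained PC
#' scores for each candidate `k`, and selects `k` (unless fixed) by the
#' Calinski-Harabasz profile (average silhouette widths are also
#' returned). The severity of a cell is the absolute variance-weighted
#' sum of its retained PC scores; regions are ranked by decreasing
#' median severity (rank 1 = most severe).
#'
#' @param change A tibble with a `cell` column and the change-field
#'   columns.
#' @param fields Character vector of change-field columns to cluster on.
#' @param k_range Candidate numbers of regions.
#' @param k Fixed number of regions (overrides the profile choice).
#' @param n_pcs Number of principal components retained (raised if
#'   needed so the retained PCs explain at least 95% of variance).
#' @param seed Integer seed.
#' @return An object of class `severity_regions`: `regions` (cell,
#'   region, region_rank, severity, PC scores), `profiles` (k,
#'   calinski_harabasz, silhouette), the chosen `k`, and the PCA
#'   variance shares.
#' @export
severity_cluster <- function(change, fields, k_range = 2:10, k = NULL,
                             n_pcs = 4, seed = 1) {
  x <- as_tibble(change)[, c("cell", fields)]
  x <- x[complete.cases(x), ]
  keep <- fields[purrr::map_lgl(fields, ~ sd(x[[.x]]) > 0)]
  dropped <- setdiff(fields, keep)
  if (length(dropped) > 0) {
    warn(paste0("Dropping constant change field(s): ", paste(dropped, collapse = ", ")))
  }
  if (length(keep) < 2) {
    abort("Clustering refused: fewer than two change fields with non-zero variance.")
  }
  pca <- prcomp(x[, keep], center = TRUE, scale. = TRUE)
  share <- pca$sdev^2 / sum(pca$sdev^2)
  npc <- min(max(n_pcs, which(cumsum(share) >= 0.95)[1]), ncol(pca$x))
  scores <- pca$x[, seq_len(npc), drop = FALSE]
  w <- share[seq_len(npc)]
  severity <- abs(as.vector(scores %*% w))

  set.seed(as.integer(seed))
  k_range <- k_range[k_range < nrow(scores)]
  profiles <- purrr::map_dfr(k_range, function(kk) {
    pm <- cluster::pam(scores, kk, pamonce = 5)
    sil <- if (nrow(scores) <= 10000) {
      mean(cluster::silhouette(pm)[, "sil_width"])
    } else {
      NA_real_
    }
    tibble(k = kk, calinski_harabasz = calinski_harabasz(scores, pm$clustering),
           silhouette = sil)
  })
  k_final <- k %||% profiles$k[which.max(profiles$calinski_harabasz)]
  pm <- cluster::pam(scores, k_final, pamonce = 5)

  regions <- bind_cols(
    tibble(cell = x$cell, region = pm$clustering, severity = severity),
    as_tibble(scores)
  )
  ranking <- regions |>
    group_by(.data$region) |>
    summarise(median_severity = median(.data$severity), .groups = "drop") |>
    arrange(desc(.data$median_severity)) |>
    mutate(region_rank = row_number())
  regions <- left_join(regions, ranking, by = "region")

  structure(
    list(regions = regions, profiles = profiles, k = k_final,
         variance_share = share, n_pcs = npc, pca = pca),
    class = "severity_regions"
  )
}

#' @export
print.severity_regions <- function(x, ...) {
  cat(sprintf(
    "<severity_regions> k = %d regions on %d PCs (%.1f%% variance), %d cells\n",
    x$k, x$n_pcs, 100 * sum(x$variance_share[seq_len(x$n_pcs)]), nrow(x$regions)
  ))
  invisible(x)
}

#' Suitability-weighted median of a vector
#'
#' Sorts the values, accumulates the normalised weights and returns the
#' value at which the cumulative weight crosses one half; when it hits
#' exactly one half the midpoint of the bracketing values is returned,
#' so the weighted median reduces to the ordinary median under equal
#' weights.
#'
#' @param x Values.
#' @param w Non-negative weights.
#' @return The weighted median (`NA` when total weight is zero).
#' @export
weighted_median <- function(x, w) {
  ok <- !is.na(x) & !is.na(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0 || sum(w) == 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

weighted_variance <- function(x, w) {
  ok <- !is.na(x) & !is.na(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0 || sum(w) == 0) return(NA_real_)
  mu <- sum(w * x) / sum(w)
  sum(w * (x - mu)^2) / sum(w)
}

#' Prepare a species trait table with genus-level fallback
#'
#' Species with fewer than `min_measurements` measurements inherit their
#' genus mean; species whose surface-to-volume ratio exceeds `sv_max`
#' are treated as artifactual outliers and dropped.
#'
#' @param traits A tibble with `species_id`, `genus`, `trait_value`,
#'   optional `n_measurements` and `sv_ratio`.
#' @param min_measurements Measurement count below which the genus mean
#'   is used.
#' @param sv_max Surface-to-volume exclusion threshold.
#' @return A tibble (species_id, trait_value, source = species/genus).
#' @export
prepare_traits <- function(traits, min_measurements = 5, sv_max = 10) {
  t <- as_tibble(traits)
  if (!"n_measurements" %in% names(t)) t$n_measurements <- Inf
  if ("sv_ratio" %in% names(t)) {
    t <- filter(t, is.na(.data$sv_ratio) | .data$sv_ratio <= sv_max)
  }
  genus_means <- t |>
    group_by(.data$genus) |>
    summarise(genus_mean = mean(.data$trait_value, na.rm = TRUE), .groups = "drop")
  t |>
    left_join(genus_means, by = "genus") |>
    mutate(
      source = if_else(.data$n_measurements >= min_measurements, "species", "genus"),
      trait_value = if_else(.data$source == "species",
                            .data$trait_value, .data$genus_mean)
    ) |>
    filter(!is.na(.data$trait_value)) |>
    select("species_id", "trait_value", "source")
}

#' Suitability-weighted community trait structure
#'
#' Combines per-cell habitat suitability with species trait values (cell
#' volume, body length, ...) to map the HSI-weighted median and variance
#' of the trait across the community, and optionally the percentage
#' change of the future median relative to the present one. Cells with
#' zero total suitability weight are masked.
#'
#' @param present Annual HSI tibble (species_id, cell, hsi), member
#'   columns averaged beforehand or ignored.
#' @param traits A [prepare_traits()] tibble (species_id, trait_value).
#' @param future Optional future annual HSI tibble.
#' @return A tibble per cell: `trait_median`, `trait_variance` (and
#'   `trait_median_future`, `pct_change` when `future` is given).
#' @export
weighted_trait_structure <- function(present, traits, future = NULL) {
  one_period <- function(d) {
    d |>
      as_tibble() |>
      group_by(.data$species_id, .data$cell) |>
      summarise(hsi = mean(.data$hsi, na.rm = TRUE), .groups = "drop") |>
      inner_join(select(traits, "species_id", "trait_value"), by = "species_id") |>
      group_by(.data$cell) |>
      summarise(
        trait_median = weighted_median(.data$trait_value, .data$hsi),
        trait_variance = weighted_variance(.data$trait_value, .data$hsi),
        .groups = "drop"
      )
  }
  out <- one_period(present)
  if (!is.null(future)) {
    fut <- one_period(future) |>
      rename(trait_median_future = "trait_median",
             trait_variance_future = "trait_variance")
    out <- left_join(out, fut, by = "cell") |>
      mutate(pct_change = 100 * (.data$trait_median_future - .data$trait_median) /
               .data$trait_median)
  }
  out
}

#' Test ecosystem-service variables across severity regions
#'
#' For each service variable, a Kruskal-Wallis test across regions at the
#' given significance level, followed (when significant) by pairwise
#' Wilcoxon rank-sum comparisons with Bonferroni adjustment. Constant
#' variables are skipped with a note; regions can be excluded per
#' service (e.g. where a service is simply unreported).
#'
#' @param regions A tibble (cell, region) or a `severity_regions` object.
#' @param services A tibble with `cell` and one column per service
#'   variable.
#' @param alpha Significance level for the omnibus test.
#' @param exclude Optional named list, `service = regions to drop`.
#' @return A list with `kruskal` (service, statistic, df, p_value, note)
#'   and `pairwise` (service, region_a, region_b, p_adjusted).
#' @export
service_overlap_tests <- function(regions, services, alpha = 0.01,
                                  exclude = NULL) {
  if (inherits(regions, "severity_regions")) regions <- regions$regions
  reg <- as_tibble(regions)[, c("cell", "region")]
  vars <- setdiff(names(services), "cell")
  kw <- list(); pw <- list()
  for (v in vars) {
    d <- inner_join(reg, select(as_tibble(services), "cell", all_of(v)), by = "cell")
    names(d)[3] <- "value"
    d <- filter(d, !is.na(.data$value))
    if (!is.null(exclude[[v]])) d <- filter(d, !.data$region %in% exclude[[v]])
    if (n_distinct(d$region) < 2 || sd(d$value) == 0) {
      kw[[v]] <- tibble(service = v, statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_,
                        note = "skipped: constant variable or single region")
      next
    }
    t <- kruskal.test(d$value, factor(d$region))
    kw[[v]] <- tibble(service = v, statistic = unname(t$statistic),
                      df = unname(t$parameter), p_value = t$p.value,
                      note = NA_character_)
    if (t$p.value < alpha) {
      p <- pairwise.wilcox.test(d$value, factor(d$region),
                                p.adjust.method = "bonferroni", exact = FALSE)
      m <- p$p.value
      idx <- which(!is.na(m), arr.ind = TRUE)
      pw[[v]] <- tibble(
        service = v,
        region_a = rownames(m)[idx[, 1]],
        region_b = colnames(m)[idx[, 2]],
        p_adjusted = m[idx]
      )
    }
  }
  list(kruskal = bind_rows(kw), pairwise = bind_rows(pw))
}
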