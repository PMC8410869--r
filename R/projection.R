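#' Build future climatologies by the delta (anomaly) method
#'
#' Future conditions are the observed climatology plus the ESM's
#' projected change, `future = obs + (esm_future - esm_baseline)`,
#' applied per predictor and month on the linear scale of each field.
#' Derived predictors are then recomputed from the shifted primary
#' fields, so log-variants follow the linear-scale deltas. The annual
#' SST range (`dsst`) follows its own rule: its delta is the difference
#' between the ESM's end-of-century and baseline annual ranges, added to
#' the observed annual range. Physically non-negative fields are floored
#' at zero (mixed-layer depth at 1 m) after adding deltas; a
#' zero-anomaly call returns the observed climatology unchanged.
#'
#' @param obs The observed base `clim_stack` (primary fields).
#' @param esm_baseline,esm_future ESM climatology stacks for the baseline
#'   and end-of-century periods (same grid and fields as `obs`), or
#'   `NULL` when `anomalies` is given.
#' @param anomalies Alternatively, a long `anomaly_set`
#'   (cell, month, predictor, delta) relative to `obs`; use `esm` to pick
#'   one ESM out of a multi-ESM set.
#' @param esm Optional `esm_id` filter for `anomalies`.
#' @param ... Passed to [derive_predictors()].
#' @return A future `predictor_stack`.
#' @export
apply_delta <- function(obs, esm_baseline = NULL, esm_future = NULL,
                        anomalies = NULL, esm = NULL, ...) {
  base_fields <- setdiff(names(obs), c("cell", "lon", "lat", "month"))
  key <- c("cell", "month")

  if (!is.null(anomalies)) {
    an <- as_tibble(anomalies)
    if (!is.null(esm)) an <- filter(an, .data$esm_id == !!esm)
    if ("esm_id" %in% names(an) && n_distinct(an$esm_id) > 1) {
      abort("`anomalies` contains several ESMs; pick one with `esm`.")
    }
    delta <- an |>
      select("cell", "month", "predictor", "delta") |>
      tidyr::pivot_wider(names_from = "predictor", values_from = "delta",
                         values_fill = 0)
    dsst_delta <- NULL
  } else {
    if (is.null(esm_baseline) || is.null(esm_future)) {
      abort("Provide either `anomalies` or both `esm_baseline` and `esm_future`.")
    }
    shared <- intersect(base_fields, intersect(names(esm_baseline), names(esm_future)))
    b <- as_tibble(esm_baseline)[, c(key, shared)]
    f <- as_tibble(esm_future)[, c(key, shared)]
    if (nrow(b) != nrow(obs) || nrow(f) != nrow(obs)) {
      abort("Grid mismatch between `obs` and the ESM stacks.")
    }
    delta <- inner_join(f, b, by = key, suffix = c(".f", ".b"))
    for (p in shared) {
      delta[[p]] <- delta[[paste0(p, ".f")]] - delta[[paste0(p, ".b")]]
    }
    delta <- delta[, c(key, shared)]
    annual_range <- function(stack) {
      as_tibble(stack) |>
        group_by(.data$cell) |>
        summarise(range = max(.data$sst) - min(.data$sst), .groups = "drop")
    }
    dsst_delta <- inner_join(annual_range(esm_future), annual_range(esm_baseline),
                             by = "cell", suffix = c(".f", ".b")) |>
      transmute(cell = .data$cell, d_dsst = .data$range.f - .data$range.b)
  }

  fut <- as_tibble(obs) |> left_join(delta, by = key, suffix = c("", ".delta"))
  for (p in base_fields) {
    dp <- paste0(p, ".delta")
    if (dp %in% names(fut)) {
      fut[[p]] <- fut[[p]] + coalesce(fut[[dp]], 0)
      fut[[dp]] <- NULL
    }
  }
  floors <- c(no3 = 0, po4 = 0, sioh4 = 0, chl = 0, par = 0, wind = 0,
              do2 = 0, mld = 1)
  for (p in intersect(names(floors), names(fut))) {
    fut[[p]] <- pmax(fut[[p]], floors[[p]])
  }
  fut <- as_clim_stack(fut[, names(obs)], get_grid(obs))
  out <- derive_predictors(fut, ...)
  if (!is.null(dsst_delta)) {
    obs_range <- as_tibble(obs) |>
      group_by(.data$cell) |>
      summarise(obs_dsst = max(.data$sst) - min(.data$sst), .groups = "drop")
    out <- out |>
      select(-"dsst") |>
      left_join(inner_join(obs_range, dsst_delta, by = "cell"), by = "cell") |>
      mutate(dsst = .data$obs_dsst + .data$d_dsst) |>
      select(-"obs_dsst", -"d_dsst")
    out <- set_grid(out, get_grid(obs))
    class(out) <- unique(c("predictor_stack", "clim_stack", class(out)))
  }
  out
}

#' Project fitted SDMs onto a climatology
#'
#' For every retained species, algorithm and predictor set, predicts
#' habitat suitability on each (cell, month) of the supplied stack,
#' averaging over the design's repeated-split fits. Failed members are
#' skipped and recorded in the `skipped` attribute.
#'
#' @param design An [run_sdm_design()] result.
#' @param stack A `predictor_stack` (present or future conditions).
#' @param species Optional subset of species ids.
#' @param esm_id Label for the forcing behind `stack` (`"obs"` for the
#'   observed climatology).
#' @return An `hsi_cube` tibble (species_id, algorithm, set, esm, cell,
#'   month, hsi).
#' @export
project_hsi <- function(design, stack, species = NULL, esm_id = "obs") {
  stopifnot(inherits(design, "sdm_design"))
  sp_ids <- species %||% names(design$fits)
  skipped <- character()
  newdata <- as_tibble(stack)
  out <- purrr::map_dfr(sp_ids, function(sp) {
    sets <- design$fits[[sp]]
    purrr::imap_dfr(sets, function(algs, set_id) {
      purrr::imap_dfr(algs, function(split_fits, alg) {
        ok <- purrr::keep(split_fits, inherits, "sdm_fit")
        if (length(ok) == 0) {
          skipped <<- c(skipped, paste(sp, set_id, alg, sep = "/"))
          return(tibble())
        }
        preds <- purrr::map(ok, predict, newdata = newdata)
        hsi <- purrr::reduce(preds, `+`) / length(preds)
        tibble(
          species_id = sp, algorithm = alg, set = set_id, esm = esm_id,
          cell = newdata$cell, month = newdata$month, hsi = hsi
        )
      })
    })
  })
  attr(out, "skipped") <- skipped
  if (length(skipped) > 0) {
    inform(sprintf("Skipped %d member(s) with no surviving fits.", length(skipped)))
  }
  class(out) <- unique(c("hsi_cube", class(out)))
  out
}

#' Annual-mean habitat suitability
#'
#' Averages monthly HSI over the months with data (months with missing
#' suitability are dropped from the mean, the winter-gap convention).
#'
#' @param cube An `hsi_cube`.
#' @return A tibble (species_id, algorithm, set, esm, cell, hsi).
#' @export
annual_hsi <- function(cube) {
  cube |>
    as_tibble() |>
    group_by(.data$species_id, .data$algorithm, .data$set, .data$esm, .data$cell) |>
    summarise(hsi = mean(.data$hsi, na.rm = TRUE), .groups = "drop")
}

#' Stack habitat suitability into potential species richness
#'
#' Potential species richness is the sum of habitat suitability over the
#' species of a group: monthly SR per member, then the annual mean over
#' months with data.
#'
#' @param cube An `hsi_cube`.
#' @param species Optional character vector restricting the group.
#' @return An `sr_field` tibble (algorithm, set, esm, cell, sr) of
#'   annual-mean richness per ensemble member.
#' @export
stack_richness <- function(cube, species = NULL) {
  x <- as_tibble(cube)
  if (!is.null(species)) {
    if (length(species) == 0) abort("`species` selects an empty group.")
    x <- filter(x, .data$species_id %in% species)
    if (nrow(x) == 0) abort("`species` selects an empty group.")
  }
  out <- x |>
    group_by(.data$algorithm, .data$set, .data$esm, .data$cell, .data$month) |>
    summarise(sr = sum(.data$hsi, na.rm = TRUE), .groups = "drop") |>
    group_by(.data$algorithm, .data$set, .data$esm, .data$cell) |>
    summarise(sr = mean(.data$sr, na.rm = TRUE), .groups = "drop")
  class(out) <- unique(c("sr_field", class(out)))
  out
}

#' Ensemble-mean species richness per cell
#' @param sr An `sr_field` (member-level annual SR).
#' @return A tibble (cell, sr).
#' @export
sr_ensemble <- function(sr) {
  sr |>
    as_tibble() |>
    group_by(.data$cell) |>
    summarise(sr = mean(.data$sr), .groups = "drop")
}

#' Ensemble change statistics for species richness
#'
#' Joins present members (algorithm x set) to the future members sharing
#' their algorithm and set (one per ESM) and computes, per cell, the
#' member-level percentage change `100 * (SR_future - SR_present) /
#' SR_present`, its ensemble mean, median, interquartile range and
#' standard deviation, the fraction of members agreeing with the majority
#' sign (zero-change members excluded) with a stippling flag at the
#' `agree` level, and the share of across-member variance attributable to
#' the algorithm, predictor-set and ESM factors (main-effect sums of
#' squares). Cells with present SR below `min_sr` are masked.
#'
#' @param present,future `sr_field` tibbles (present `esm = "obs"`).
#' @param min_sr Present-SR mask threshold.
#' @param agree Sign-agreement fraction required for stippling.
#' @return A `change_field` tibble per cell, with the member-level table
#'   attached as attribute `members`.
#' @export
ensemble_change <- function(present, future, min_sr = 0.5, agree = 0.9) {
  members <- inner_join(
    as_tibble(present) |> rename(sr_pres = "sr") |> select(-"esm"),
    as_tibble(future) |> rename(sr_fut = "sr"),
    by = c("algorithm", "set", "cell")
  ) |>
    mutate(pct = if_else(.data$sr_pres >= min_sr,
                         100 * (.data$sr_fut - .data$sr_pres) / .data$sr_pres,
                         NA_real_))

  agreement <- function(x) {
    x <- x[!is.na(x) & x != 0]
    if (length(x) == 0) return(NA_real_)
    max(mean(x > 0), mean(x < 0))
  }
  ss_share <- function(d) {
    x <- d$pct[!is.na(d$pct)]
    if (length(x) < 2 || var(d$pct, na.rm = TRUE) == 0) {
      return(tibble(var_algorithm = NA_real_, var_set = NA_real_, var_esm = NA_real_))
    }
    tot <- sum((d$pct - mean(d$pct, na.rm = TRUE))^2, na.rm = TRUE)
    main <- function(f) {
      m <- tapply(d$pct, d[[f]], mean, na.rm = TRUE)
      nn <- tapply(!is.na(d$pct), d[[f]], sum)
      sum(nn * (m - mean(d$pct, na.rm = TRUE))^2, na.rm = TRUE) / tot
    }
    tibble(var_algorithm = main("algorithm"), var_set = main("set"),
           var_esm = main("esm"))
  }

  out <- members |>
    group_by(.data$cell) |>
    summarise(
      pct_mean = mean(.data$pct, na.rm = TRUE),
      pct_median = median(.data$pct, na.rm = TRUE),
      pct_iqr = stats::IQR(.data$pct, na.rm = TRUE),
      pct_sd = sd(.data$pct, na.rm = TRUE),
      agreement = agreement(.data$pct),
      n_members = sum(!is.na(.data$pct)),
      ss = list(ss_share(dplyr::pick(dplyr::everything()))),
      .groups = "drop"
    ) |>
    tidyr::unnest("ss") |>
    mutate(
      pct_mean = if_else(is.nan(.data$pct_mean), NA_real_, .data$pct_mean),
      stipple = !is.na(.data$agreement) & .data$agreement >= agree
    )
  attr(out, "members") <- members
  class(out) <- unique(c("change_field", class(out)))
  out
}

#' Global summaries of a richness change field
#'
#' Emits both readings of the headline median change: the median over
#' cells of the ensemble-mean change, and the median over all member x
#' cell values.
#'
#' @param change A [ensemble_change()] result.
#' @return A one-row tibble.
#' @export
change_summary <- function(change) {
  members <- attr(change, "members")
  tibble(
    median_of_ensemble_mean = median(change$pct_mean, na.rm = TRUE),
    median_of_members = median(members$pct, na.rm = TRUE),
    mean_of_ensemble_mean = mean(change$pct_mean, na.rm = TRUE)
  )
}

# Similarity of one value to a reference sample, per the MESS branch rules.
mess_similarity <- function(v, ref) {
  rmin <- min(ref); rmax <- max(ref)
  if (rmax == rmin) {
    return(ifelse(v == rmin, 0, -1e4))
  }
  f <- 100 * vapply(v, function(x) mean(ref < x), numeric(1))
  out <- numeric(length(v))
  out[f == 0] <- 100 * (v[f == 0] - rmin) / (rmax - rmin)
  sel <- f > 0 & f <= 50
  out[sel] <- 2 * f[sel]
  sel <- f > 50 & f < 100
  out[sel] <- 2 * (100 - f[sel])
  out[f == 100] <- 100 * (rmax - v[f == 100]) / (rmax - rmin)
  out
}

#' Multivariate environmental similarity surface (MESS)
#'
#' For each projection point and each predictor, computes the similarity
#' of the projected value to the species' reference (training) sample:
#' with `f` the percentage of reference values below the point, the
#' similarity is `100 * (v - min) / (max - min)` when `f = 0`, `2f` when
#' `0 < f <= 50`, `2(100 - f)` when `50 < f < 100`, and
#' `100 * (max - v) / (max - min)` when `f = 100`. The MESS value is the
#' minimum over predictors and is negative exactly when at least one
#' predictor falls outside its reference range; the minimising predictor
#' is reported as the extrapolation driver. A degenerate reference
#' (max = min) scores 0 at the reference value and a large negative
#' sentinel (-1e4) elsewhere.
#'
#' @param reference Tibble of predictor values at the species' training
#'   points.
#' @param projection A `predictor_stack` (or any tibble with `cell`,
#'   `month` and the predictors).
#' @param predictors Character vector of predictors (a predictor set).
#' @return A `mess_field` tibble (cell, month, mess, driver).
#' @export
compute_mess <- function(reference, projection, predictors) {
  reference <- as_tibble(reference)
  missing <- setdiff(predictors, names(reference))
  if (length(missing) > 0 || nrow(reference) == 0) {
    abort("`reference` must contain non-empty values for every predictor.")
  }
  proj <- as_tibble(projection)
  sims <- purrr::map(predictors, function(p) {
    ref <- reference[[p]][!is.na(reference[[p]])]
    if (length(ref) == 0) abort(sprintf("Reference for '%s' is empty.", p))
    mess_similarity(proj[[p]], ref)
  })
  sim_mat <- do.call(cbind, sims)
  colnames(sim_mat) <- predictors
  idx <- apply(sim_mat, 1, which.min)
  tibble(
    cell = proj$cell, month = proj$month,
    mess = sim_mat[cbind(seq_len(nrow(sim_mat)), idx)],
    driver = predictors[idx]
  ) |>
    structure(class = c("mess_field", class(tibble())))
}

#' Annual-mean MESS and driver frequencies
#'
#' @param mess A [compute_mess()] result.
#' @return A list with `annual` (cell, mess_annual, any_negative) and
#'   `drivers` (driver frequencies among negative-MESS points).
#' @export
mess_annual <- function(mess) {
  annual <- mess |>
    group_by(.data$cell) |>
    summarise(
      mess_annual = mean(.data$mess, na.rm = TRUE),
      any_negative = any(.data$mess < 0, na.rm = TRUE),
      .groups = "drop"
    )
  neg <- filter(mess, .data$mess < 0)
  drivers <- if (nrow(neg) == 0) {
    tibble(driver = character(), n = integer(), frequency = numeric())
  } else {
    neg |> count(.data$driver) |> mutate(frequency = .data$n / sum(.data$n))
  }
  list(annual = annual, drivers = drivers)
}
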