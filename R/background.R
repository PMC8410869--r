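#' Stratify target-group sites along the SST and MLD gradients
#'
#' Builds equal-frequency (quantile) bins of SST and MLD over the
#' target-group's monthly grid sites, and per-stratum sampling weights
#' proportional to the number of target-group sites they contain, so that
#' backgrounds drawn from the strata inherit the survey-effort
#' distribution. When a gradient has fewer distinct values than requested
#' bins, the bin count is reduced with a warning.
#'
#' @param target_group A `gridded_presences` tibble of all target-group
#'   presences.
#' @param stack A `predictor_stack` providing `sst` and `mld`.
#' @param n_sst_bins,n_mld_bins Requested bin counts.
#' @return A tibble (sst_bin, mld_bin, n, weight) of class
#'   `stratum_table`, with the bin breaks attached as attributes. Weights
#'   sum to 1 over non-empty strata.
#' @export
stratify_environment <- function(target_group, stack,
                                 n_sst_bins = 10, n_mld_bins = 10) {
  if (nrow(target_group) == 0) abort("The target group is empty.")
  pts <- target_group |>
    as_tibble() |>
    distinct(.data$cell, .data$month) |>
    left_join(select(as_tibble(stack), "cell", "month", "sst", "mld"),
              by = c("cell", "month"))

  make_breaks <- function(x, n, label) {
    nd <- dplyr::n_distinct(x[!is.na(x)])
    if (nd < n) {
      warn(sprintf("Reduced %s bins to %d (too few distinct values).", label,
                   max(1L, nd)))
      n <- max(1L, nd)
    }
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n + 1),
                          na.rm = TRUE, names = FALSE))
    br[1] <- -Inf
    br[length(br)] <- Inf
    br
  }
  sst_breaks <- make_breaks(pts$sst, n_sst_bins, "SST")
  mld_breaks <- make_breaks(pts$mld, n_mld_bins, "MLD")

  tab <- pts |>
    mutate(
      sst_bin = cut(.data$sst, sst_breaks, labels = FALSE),
      mld_bin = cut(.data$mld, mld_breaks, labels = FALSE)
    ) |>
    count(.data$sst_bin, .data$mld_bin, name = "n") |>
    mutate(weight = .data$n / sum(.data$n))
  attr(tab, "sst_breaks") <- sst_breaks
  attr(tab, "mld_breaks") <- mld_breaks
  class(tab) <- unique(c("stratum_table", class(tab)))
  tab
}

# Assign (cell, month) sites to strata using the frozen breaks.
assign_strata <- function(sites, stack, strata) {
  sites |>
    left_join(select(as_tibble(stack), "cell", "month", "sst", "mld"),
              by = c("cell", "month")) |>
    mutate(
      sst_bin = cut(.data$sst, attr(strata, "sst_breaks"), labels = FALSE),
      mld_bin = cut(.data$mld, attr(strata, "mld_breaks"), labels = FALSE)
    )
}

# Largest-remainder apportionment of n draws across strata weights.
largest_remainder <- function(n, weights) {
  if (sum(weights) == 0) return(integer(length(weights)))
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    frac_order <- order(-(raw - base), seq_along(raw))
    base[frac_order[seq_len(short)]] <- base[frac_order[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Draw stratified target-group background (pseudo-absence) data
#'
#' Samples `ratio` times the species' presence count of background sites,
#' without replacement, from the target-group's (cell, month) sites that
#' the focal species does not occupy. The draw is allocated across the
#' SST x MLD strata proportionally to the stratum weights
#' (largest-remainder rounding); stratum shortfalls are reallocated to
#' the remaining strata, and only if the total candidate pool is smaller
#' than the request does sampling fall back to with-replacement, with a
#' warning. Presences get weight 1 and background rows weight
#' `n_presence / n_background`, so the two classes carry equal total
#' weight.
#'
#' @param presences The focal species' `gridded_presences` rows.
#' @param target_group All target-group presences.
#' @param strata A [stratify_environment()] table.
#' @param stack The `predictor_stack` used for stratification and for
#'   matching predictor values.
#' @param ratio Background-to-presence ratio.
#' @param seed Integer seed.
#' @param predictors Optional character vector of predictor columns to
#'   attach; defaults to every derived/primary field in `stack`.
#' @return A `training_set` tibble: species_id, cell, month, response
#'   (1 presence / 0 background), weight and predictor columns.
#' @export
draw_background <- function(presences, target_group, strata, stack,
                            ratio = 10, seed = 1, predictors = NULL) {
  if (nrow(presences) == 0) abort("The focal species has no presences.")
  sp <- unique(presences$species_id)
  if (length(sp) != 1) abort("`presences` must contain a single species.")
  set.seed(as.integer(seed))

  sites <- target_group |>
    as_tibble() |>
    distinct(.data$cell, .data$month)
  own <- presences |> as_tibble() |> distinct(.data$cell, .data$month)
  candidates <- anti_join(sites, own, by = c("cell", "month"))
  if (nrow(candidates) == 0) {
    abort("No candidate background sites: the species occupies every target-group site.")
  }

  n_pres <- nrow(own)
  n_bg <- ratio * n_pres
  cand <- assign_strata(candidates, stack, strata) |>
    inner_join(select(strata, "sst_bin", "mld_bin", "weight"),
               by = c("sst_bin", "mld_bin"))

  replace_needed <- nrow(cand) < n_bg
  if (replace_needed) {
    warn(sprintf(
      "Only %d candidate sites for %d background draws; sampling with replacement.",
      nrow(cand), n_bg
    ))
  }

  # allocate across strata, reapportioning shortfalls
  strat_tab <- cand |>
    group_by(.data$sst_bin, .data$mld_bin) |>
    summarise(avail = n(), weight = first(.data$weight), .groups = "drop")
  alloc <- largest_remainder(n_bg, strat_tab$weight)
  if (!replace_needed) {
    repeat {
      over <- pmax(0, alloc - strat_tab$avail)
      if (sum(over) == 0) break
      alloc <- pmin(alloc, strat_tab$avail)
      room <- strat_tab$avail - alloc
      if (sum(room) == 0) break
      extra <- largest_remainder(sum(over), ifelse(room > 0, strat_tab$weight, 0))
      alloc <- pmin(strat_tab$avail, alloc + pmin(extra, room))
      if (sum(alloc) == n_bg) break
    }
    # any residual (rounding against capacity) goes to the roomiest strata
    while (sum(alloc) < n_bg) {
      room <- strat_tab$avail - alloc
      k <- which.max(room)
      if (room[k] <= 0) break
      alloc[k] <- alloc[k] + 1
    }
  }

  drawn <- purrr::map_dfr(seq_len(nrow(strat_tab)), function(i) {
    pool <- cand |>
      filter(.data$sst_bin == strat_tab$sst_bin[i],
             .data$mld_bin == strat_tab$mld_bin[i])
    k <- alloc[i]
    if (k == 0) return(pool[0, ])
    pool[sample.int(nrow(pool), k, replace = replace_needed), ]
  })

  if (is.null(predictors)) {
    predictors <- setdiff(names(stack), c("cell", "lon", "lat", "month"))
  }
  env <- select(as_tibble(stack), "cell", "month", all_of(predictors))
  out <- bind_rows(
    own |> mutate(response = 1L, weight = 1),
    drawn |>
      select("cell", "month") |>
      mutate(response = 0L, weight = n_pres / nrow(drawn))
  ) |>
    mutate(species_id = sp, .before = 1) |>
    left_join(env, by = c("cell", "month"))
  class(out) <- unique(c("training_set", class(out)))
  out
}

#' Build a model-ready training set for one species
#'
#' Convenience wrapper: extracts the focal species' presences, draws
#' stratified target-group background with [draw_background()] and
#' attaches the predictor values.
#'
#' @param species_id Focal species id.
#' @param presences All gridded presences (the target group).
#' @param stack A `predictor_stack`.
#' @param strata Optional precomputed [stratify_environment()] table.
#' @inheritParams draw_background
#' @return A `training_set` tibble.
#' @export
build_training_set <- function(species_id, presences, stack, strata = NULL,
                               ratio = 10, seed = 1, predictors = NULL) {
  own <- presences |> as_tibble() |> filter(.data$species_id == !!species_id)
  if (nrow(own) == 0) abort(sprintf("No presences for species '%s'.", species_id))
  if (is.null(strata)) strata <- stratify_environment(presences, stack)
  draw_background(own, presences, strata, stack,
                  ratio = ratio, seed = seed, predictors = predictors)
}
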