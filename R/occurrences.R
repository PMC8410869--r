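#' Quality-control rules for occurrence records
#'
#' The record-level filter chain removes, in a frozen order: records with a
#' missing coordinate; an incomplete sampling date; a collection year
#' before `min_year`; no sampling depth; names not resolved to species
#' level; fossil or sediment-derived records (keyword match on the source
#' field); brackish records (salinity below `min_salinity`); shelf records
#' (bathymetry shallower than `min_bathymetry_m`); and net tows deeper
#' than `max_net_depth_m`. The `"phyto"` profile disables the net-depth
#' rule, for datasets already restricted to the mixed layer.
#'
#' @param profile `"zoo"` (default, all rules) or `"phyto"` (net-depth
#'   rule disabled).
#' @param min_year,min_salinity,min_bathymetry_m,max_net_depth_m Rule
#'   thresholds.
#' @param dedup_cell_deg Cell size (degrees) of the duplicate-detection
#'   grid.
#' @param fossil_keywords Regular expressions matched (case-insensitively)
#'   against the `source` column.
#' @return A list of class `qc_rules`.
#' @export
qc_rules <- function(profile = c("zoo", "phyto"),
                     min_year = 1800,
                     min_salinity = 20,
                     min_bathymetry_m = 200,
                     max_net_depth_m = 500,
                     dedup_cell_deg = 0.25,
                     fossil_keywords = c("fossil", "sediment", "core", "drill")) {
  profile <- match.arg(profile)
  if (profile == "phyto") max_net_depth_m <- Inf
  stopifnot(min_salinity > 0, min_bathymetry_m > 0, dedup_cell_deg > 0)
  structure(
    list(
      profile = profile, min_year = min_year, min_salinity = min_salinity,
      min_bathymetry_m = min_bathymetry_m, max_net_depth_m = max_net_depth_m,
      dedup_cell_deg = dedup_cell_deg, fossil_keywords = fossil_keywords
    ),
    class = "qc_rules"
  )
}

occ_required_cols <- c(
  "species_id", "decimal_longitude", "decimal_latitude", "year", "month",
  "day", "depth_m", "max_net_depth_m", "salinity_at_point", "bathymetry_m",
  "source"
)

check_occ_schema <- function(occ) {
  missing <- setdiff(occ_required_cols, names(occ))
  if (length(missing) > 0) {
    abort(paste0("Occurrence table is missing columns: ", paste(missing, collapse = ", ")))
  }
  invisible(occ)
}

# A name is species-level unless it ends in an open identifier such as
# "sp.", "spp." or "cf.", or is missing.
is_species_level <- function(x) {
  !is.na(x) & !grepl("\\b(sp|spp|cf|aff)\\.?$", x, ignore.case = TRUE)
}

#' Filter occurrence records through the QC chain
#'
#' Applies the rules of [qc_rules()] in their frozen order and reports how
#' many records each step removed. The removal counts are order-dependent
#' (a record violating two rules is counted at the first); the per-step
#' report makes that explicit rather than hiding it. An optional synonym
#' table is applied before the species-level check. The sampling depth
#' used by the net-depth rule falls back from `max_net_depth_m` to
#' `depth_m` when the former is missing.
#'
#' @param raw An occurrence tibble with the standard column set.
#' @param rules A [qc_rules()] object.
#' @param synonyms Optional tibble with columns `from`, `to` mapping
#'   synonym names onto accepted names; applied as-is.
#' @return A list of class `occ_filter` with elements `occurrences` (the
#'   retained rows), `report` (tibble of per-step removal counts) and
#'   `n_retained`.
#' @export
filter_occurrences <- function(raw, rules = qc_rules(), synonyms = NULL) {
  check_occ_schema(raw)
  occ <- as_tibble(raw)
  if (!is.null(synonyms)) {
    stopifnot(all(c("from", "to") %in% names(synonyms)))
    idx <- match(occ$species_id, synonyms$from)
    occ$species_id <- ifelse(is.na(idx), occ$species_id, synonyms$to[idx])
  }

  fossil_re <- paste(rules$fossil_keywords, collapse = "|")
  depth_used <- function(d) coalesce(d$max_net_depth_m, d$depth_m)
  steps <- list(
    missing_coordinates = function(d) is.na(d$decimal_longitude) | is.na(d$decimal_latitude),
    incomplete_date = function(d) is.na(d$year) | is.na(d$month) | is.na(d$day),
    year_before_min = function(d) d$year < rules$min_year,
    missing_depth = function(d) is.na(d$depth_m) & is.na(d$max_net_depth_m),
    not_species_level = function(d) !is_species_level(d$species_id),
    fossil_or_sediment = function(d) !is.na(d$source) &
      grepl(fossil_re, d$source, ignore.case = TRUE),
    low_salinity = function(d) !is.na(d$salinity_at_point) &
      d$salinity_at_point < rules$min_salinity,
    shallow_bathymetry = function(d) !is.na(d$bathymetry_m) &
      d$bathymetry_m < rules$min_bathymetry_m,
    deep_net_tow = function(d) !is.na(depth_used(d)) &
      depth_used(d) > rules$max_net_depth_m
  )

  removed <- integer(length(steps))
  names(removed) <- names(steps)
  for (s in names(steps)) {
    bad <- steps[[s]](occ)
    bad[is.na(bad)] <- FALSE
    removed[[s]] <- sum(bad)
    occ <- occ[!bad, , drop = FALSE]
  }

  structure(
    list(
      occurrences = occ,
      report = tibble(step = names(removed), removed = unname(removed)),
      n_retained = nrow(occ)
    ),
    class = "occ_filter"
  )
}

#' @export
print.occ_filter <- function(x, ...) {
  cat("<occ_filter>", sum(x$report$removed), "removed,", x$n_retained, "retained\n")
  print(x$report)
  invisible(x)
}

#' Remove duplicate occurrence records
#'
#' A record is a duplicate when it shares species name, sampling depth,
#' sampling date and the same `cell_deg` x `cell_deg` grid cell with an
#' earlier record; the first-seen record is kept. Idempotent and never
#' row-increasing.
#'
#' @param occ A QC-filtered occurrence tibble.
#' @param cell_deg Duplicate-detection cell size in degrees.
#' @return The deduplicated tibble.
#' @export
deduplicate_occurrences <- function(occ, cell_deg = 0.25) {
  check_occ_schema(occ)
  keys <- occ |>
    mutate(
      .ilon = floor(.data$decimal_longitude / cell_deg),
      .ilat = floor(.data$decimal_latitude / cell_deg),
      .depth = coalesce(.data$max_net_depth_m, .data$depth_m)
    )
  keep <- !duplicated(keys[, c("species_id", ".depth", "year", "month", "day", ".ilon", ".ilat")])
  occ[keep, , drop = FALSE]
}

#' Bin occurrence records onto the monthly analysis grid
#'
#' A species is present in a (cell, month) when it was recorded there at
#' least once; the count of distinct (cell, month) pairs is the species'
#' presence count used throughout the pipeline. Longitudes are wrapped
#' into the grid span; records outside the latitude bounds are dropped
#' with a warning.
#'
#' @param occ A filtered, deduplicated occurrence tibble.
#' @param spec A [grid_spec()].
#' @return A `gridded_presences` tibble (species_id, cell, month, lon,
#'   lat), one row per presence.
#' @export
bin_to_grid <- function(occ, spec) {
  check_occ_schema(occ)
  cell <- cell_of(spec, occ$decimal_longitude, occ$decimal_latitude)
  n_oob <- sum(is.na(cell))
  if (n_oob > 0) {
    warn(sprintf("Dropped %d record(s) outside the grid bounds.", n_oob))
  }
  pres <- tibble(
    species_id = occ$species_id, cell = cell, month = as.integer(occ$month)
  ) |>
    filter(!is.na(.data$cell), !is.na(.data$month)) |>
    distinct() |>
    left_join(grid_cells(spec), by = "cell") |>
    arrange(.data$species_id, .data$cell, .data$month)
  pres <- set_grid(pres, spec)
  class(pres) <- unique(c("gridded_presences", class(pres)))
  pres
}

#' Count monthly grid presences per species
#'
#' @param presences A `gridded_presences` tibble.
#' @return A tibble (species_id, n_presence).
#' @export
presence_counts <- function(presences) {
  presences |>
    as_tibble() |>
    count(.data$species_id, name = "n_presence")
}
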