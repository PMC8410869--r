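# Shared small-world fixtures, built once per test run.

# 10-degree global grid: 36 x 18 cells, 12 months.
tw_spec <- grid_spec(cell_size = 10)
tw_env <- generate_environment(tw_spec, seed = 11)
tw_stack <- derive_predictors(tw_env)

# A handful of SST-niche species with moderate sampling, QC-clean.
tw_species <- generate_species(tw_stack, 6, predictors = "sst", seed = 21)
tw_occ <- sample_occurrences(tw_species, tw_stack, 2500,
                             contamination = 0, seed = 31)
tw_pres <- bin_to_grid(deduplicate_occurrences(tw_occ), tw_spec)
tw_counts <- presence_counts(tw_pres)
tw_strata <- stratify_environment(tw_pres, tw_stack)

# Training set for the first species (background draws may need
# replacement on this small world; that is expected and warned about).
tw_train <- suppressWarnings(
  build_training_set(tw_counts$species_id[1], tw_pres, tw_stack, tw_strata,
                     seed = 41)
)

# Independent oracles ------------------------------------------------------

# Brute-force TSS: loop over thresholds and count the confusion matrix.
oracle_tss <- function(obs, pred, thresholds = seq(0.01, 0.99, by = 0.01)) {
  best <- -Inf
  for (th in thresholds) {
    tp <- sum(pred >= th & obs == 1)
    fn <- sum(pred < th & obs == 1)
    tn <- sum(pred < th & obs == 0)
    fp <- sum(pred >= th & obs == 0)
    best <- max(best, tp / (tp + fn) + tn / (tn + fp) - 1)
  }
  best
}

# Brute-force AUC: proportion of correctly ordered presence/absence pairs.
oracle_auc <- function(obs, pred) {
  pos <- pred[obs == 1]
  neg <- pred[obs == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force multinomial G2 for a 2x2 table via observed/expected cells.
oracle_g2 <- function(k11, k12, k21, k22) {
  k <- c(k11, k12, k21, k22)
  n <- sum(k)
  e <- c((k11 + k12) * (k11 + k21), (k11 + k12) * (k12 + k22),
         (k21 + k22) * (k11 + k21), (k21 + k22) * (k12 + k22)) / n
  if (any(e == 0)) return(0)
  2 * sum(ifelse(k > 0, k * log(k / e), 0))
}

# Brute-force per-predictor MESS similarity on one value.
oracle_mess_one <- function(v, ref) {
  rmin <- min(ref); rmax <- max(ref)
  f <- 100 * sum(ref < v) / length(ref)
  if (f == 0) 100 * (v - rmin) / (rmax - rmin)
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (rmax - v) / (rmax - rmin)
}

# Spherical law of cosines distance in km (R = 6371 km).
oracle_sloc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  6371 * acos(pmin(1, pmax(-1,
    sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  )))
}

# Hand-built raw occurrence rows with sensible defaults.
make_occ <- function(n = 1, ...) {
  base <- tibble::tibble(
    species_id = "Calanus finmarchicus",
    decimal_longitude = 10, decimal_latitude = 45,
    year = 1985L, month = 6L, day = 12L,
    depth_m = 50, max_net_depth_m = 100,
    salinity_at_point = 35, bathymetry_m = 3000,
    source = "survey"
  )
  out <- base[rep(1, n), ]
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}
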