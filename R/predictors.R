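#' Derive secondary environmental predictors
#'
#' Adds to a climatology the derived fields used for niche modelling:
#' * `nstar` (uM): nitrate excess over the Redfield expectation,
#'   `NO3 - 16 * PO4`;
#' * `sistar` (uM): silicate excess over nitrate, `Si(OH)4 - NO3`,
#'   positive where diatoms can deplete nitrate before silicate;
#' * `dsst` (degrees C): annual SST range, per-cell maximum minus minimum
#'   over the twelve months, replicated to every month;
#' * `mlpar` (umol m-2 s-1): mean PAR over the mixed layer under
#'   exponential light attenuation,
#'   `par * (1 - exp(-k * mld)) / (k * mld)`;
#' * `eke` (m2 s-2): eddy kinetic energy `0.5 * (uo^2 + vo^2)` from the
#'   velocity anomaly components (only when `uo`/`vo` are present);
#' * log-transformed skewed fields `logno3`, `logpo4`, `logsioh4`,
#'   `logchl` and `logeke`, natural log by default with a small-value
#'   floor applied before logging.
#'
#' @param base A `clim_stack` with at least `sst`, `mld`, `par`, `no3`,
#'   `po4`, `sioh4` and `chl`.
#' @param k_par Light attenuation coefficient (m-1) for `mlpar`.
#' @param log_base `"natural"` or `"10"`.
#' @param log_floor Floor applied to arguments before logging.
#' @return The input tibble with derived columns appended, classed
#'   `predictor_stack`.
#' @examples
#' env <- generate_environment(grid_spec(cell_size = 30), seed = 1)
#' stack <- derive_predictors(env)
#' @export
derive_predictors <- function(base, k_par = 0.1,
                              log_base = c("natural", "10"),
                              log_floor = 1e-6) {
  log_base <- match.arg(log_base)
  required <- c("sst", "mld", "par", "no3", "po4", "sioh4", "chl")
  missing <- setdiff(required, names(base))
  if (length(missing) > 0) {
    abort(paste0("Missing primary field(s): ", paste(missing, collapse = ", ")))
  }
  lg <- if (log_base == "natural") log else log10
  out <- base |>
    group_by(.data$cell) |>
    mutate(dsst = max(.data$sst) - min(.data$sst)) |>
    ungroup() |>
    mutate(
      nstar = .data$no3 - 16 * .data$po4,
      sistar = .data$sioh4 - .data$no3,
      mlpar = .data$par * (1 - exp(-k_par * .data$mld)) / (k_par * .data$mld),
      logno3 = lg(pmax(.data$no3, log_floor)),
      logpo4 = lg(pmax(.data$po4, log_floor)),
      logsioh4 = lg(pmax(.data$sioh4, log_floor)),
      logchl = lg(pmax(.data$chl, log_floor))
    )
  if (all(c("uo", "vo") %in% names(base))) {
    out <- out |>
      mutate(
        eke = 0.5 * (.data$uo^2 + .data$vo^2),
        logeke = lg(pmax(.data$eke, log_floor))
      )
  }
  out <- set_grid(out, get_grid(base))
  class(out) <- unique(c("predictor_stack", "clim_stack", class(out)))
  out
}

#' The frozen final predictor sets
#'
#' Four sets per trophic group, the ensemble's predictor-pool axis. The
#' phytoplankton sets combine temperature (`sst`, `dsst`), chlorophyll,
#' nutrient-status (`nstar`, `sistar`, `logno3`, `logsioh4`) and light
#' (`par`); the zooplankton sets swap light for oxygen at depth (`do2`).
#'
#' @param group `"phyto"`, `"zoo"` or `"all"` (named list of all eight).
#' @return A named list of character vectors (`p1`..`p4`, prefixed by
#'   group when `group = "all"`).
#' @export
predictor_sets <- function(group = c("all", "phyto", "zoo")) {
  group <- match.arg(group)
  phyto <- list(
    p1 = c("sst", "dsst", "logchl", "nstar", "par", "logno3"),
    p2 = c("sst", "dsst", "logchl", "nstar", "par", "logsioh4"),
    p3 = c("sst", "dsst", "logchl", "nstar", "par", "logno3", "sistar"),
    p4 = c("sst", "dsst", "logchl", "par", "logno3")
  )
  zoo <- list(
    p1 = c("sst", "dsst", "do2", "logchl", "logno3"),
    p2 = c("sst", "dsst", "do2", "logchl", "logsioh4"),
    p3 = c("sst", "dsst", "do2", "logchl", "logsioh4", "nstar"),
    p4 = c("sst", "dsst", "do2", "logchl", "logno3", "sistar")
  )
  switch(group,
    phyto = phyto,
    zoo = zoo,
    all = c(setNames(phyto, paste0("phyto_", names(phyto))),
            setNames(zoo, paste0("zoo_", names(zoo))))
  )
}

# Distance-to-normality metric used for the collinearity tie-break.
normality_distance <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4 || sd(x) == 0) return(Inf)
  abs(e1071::skewness(x)) + abs(e1071::kurtosis(x))
}

#' Screen predictors for collinearity at the presence points
#'
#' Computes pairwise Spearman rank correlations on the predictor values
#' matched to presences. For every pair with `|rho|` above the threshold
#' (processed in decreasing `|rho|`), the member whose distribution is
#' further from normal (larger `|skewness| + |excess kurtosis|`) is
#' dropped. Constant predictors have undefined correlations; they are
#' flagged and retained with a warning.
#'
#' @param values A tibble of predictor values at presence points (one
#'   column per candidate predictor).
#' @param threshold Absolute Spearman correlation above which one of the
#'   pair is dropped.
#' @return A list with `retained` (character vector), `dropped` (tibble of
#'   dropped predictor, partner and rho) and `rho` (full correlation
#'   matrix).
#' @export
screen_collinearity <- function(values, threshold = 0.70) {
  values <- as_tibble(values)
  preds <- names(values)
  if (nrow(values) < 3) abort("At least 3 matched points are required.")
  constant <- preds[purrr::map_lgl(values, ~ sd(.x, na.rm = TRUE) == 0 || all(is.na(.x)))]
  if (length(constant) > 0) {
    warn(paste0(
      "Constant predictor(s) with undefined correlations retained: ",
      paste(constant, collapse = ", ")
    ))
  }
  rho <- suppressWarnings(cor(values, method = "spearman", use = "pairwise.complete.obs"))

  active <- setdiff(preds, constant)
  dropped <- tibble(predictor = character(), partner = character(), rho = numeric())
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  ord <- order(-abs(rho[pairs]))
  for (idx in ord) {
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    a <- preds[i]; b <- preds[j]
    r <- rho[i, j]
    if (is.na(r) || abs(r) <= threshold) next
    if (!(a %in% active) || !(b %in% active)) next
    da <- normality_distance(values[[a]])
    db <- normality_distance(values[[b]])
    # drop the member further from normality; ties keep the first-listed
    loser <- if (db > da) b else if (da > db) a else b
    active <- setdiff(active, loser)
    dropped <- bind_rows(dropped, tibble(
      predictor = loser, partner = setdiff(c(a, b), loser), rho = r
    ))
  }
  list(retained = c(active, constant)[order(match(c(active, constant), preds))],
       dropped = dropped, rho = rho)
}

#' Rank predictor importance from GLM and random-forest fits
#'
#' For each species and predictor set, fits a weighted binomial GLM
#' (linear + quadratic terms; importance is the largest absolute
#' t-statistic over a predictor's terms) and a probability random forest
#' (importance is the Gini impurity decrease), ranks predictors within
#' each fit (1 = most important), normalises ranks by the maximum rank,
#' and reports the fit's explained variance (adjusted deviance-based R2
#' for the GLM, OOB R2 for the forest).
#'
#' @param training_sets Named list (by species) of training tibbles with a
#'   `response`, `weight` and predictor columns (see
#'   [build_training_set()]).
#' @param sets Named list of predictor sets.
#' @param num_trees,min_node Random-forest settings.
#' @param seed Integer seed.
#' @return A list with `ranks` (tibble: species_id, set, algorithm,
#'   predictor, rank, norm_rank, r2) and `median_ranks` (median normalised
#'   rank per algorithm x predictor).
#' @export
rank_predictors <- function(training_sets, sets = predictor_sets("phyto"),
                            num_trees = 250, min_node = 10, seed = 1) {
  ranks <- purrr::imap_dfr(training_sets, function(train, sp) {
    purrr::imap_dfr(sets, function(preds, set_id) {
      preds <- intersect(preds, names(train))
      d <- train[, c("response", "weight", preds)]
      d <- d[complete.cases(d), ]
      # GLM |t| importance
      form <- as.formula(paste(
        "response ~",
        paste(sprintf("%s + I(%s^2)", preds, preds), collapse = " + ")
      ))
      fit <- suppressWarnings(glm(form, family = binomial(), data = d, weights = d$weight))
      tt <- summary(fit)$coefficients
      imp_glm <- purrr::map_dbl(preds, function(p) {
        rows <- rownames(tt)[rownames(tt) %in% c(p, sprintf("I(%s^2)", p))]
        if (length(rows) == 0) 0 else max(abs(tt[rows, 3]), na.rm = TRUE)
      })
      n <- nrow(d); p_n <- length(coef(fit)) - 1
      d2 <- 1 - fit$deviance / fit$null.deviance
      r2_glm <- 1 - (1 - d2) * (n - 1) / max(1, n - p_n - 1)
      # RF Gini importance
      rf <- ranger::ranger(
        y = factor(d$response), x = d[, preds, drop = FALSE],
        num.trees = num_trees, min.node.size = min_node,
        mtry = max(1, floor(length(preds) / 3)),
        importance = "impurity", case.weights = d$weight,
        seed = seed, num.threads = 1
      )
      imp_rf <- rf$variable.importance[preds]
      to_ranks <- function(imp, algorithm, r2) {
        rk <- rank(-imp, ties.method = "average")
        tibble(
          species_id = sp, set = set_id, algorithm = algorithm,
          predictor = preds, importance = unname(imp),
          rank = unname(rk), norm_rank = unname(rk / max(rk)), r2 = r2
        )
      }
      bind_rows(
        to_ranks(imp_glm, "glm", r2_glm),
        to_ranks(imp_rf, "rf", rf$r.squared %||% NA_real_)
      )
    })
  })
  median_ranks <- ranks |>
    group_by(.data$algorithm, .data$predictor) |>
    summarise(median_norm_rank = median(.data$norm_rank), .groups = "drop") |>
    arrange(.data$algorithm, .data$median_norm_rank)
  list(ranks = ranks, median_ranks = median_ranks)
}
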