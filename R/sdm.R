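#' Configure one species distribution model family
#'
#' The four families span the usual complexity ladder of correlative
#' niche models, each deliberately constrained to smooth, low-feature
#' response curves:
#' * `glm`: binomial logit with linear + quadratic terms and AIC-based
#'   bidirectional stepwise term selection;
#' * `gam`: binomial logit with penalised regression splines of basis
#'   dimension 5, no interactions;
#' * `rf`: probability random forest, 750 trees, terminal node size 10,
#'   `floor(p / 3)` candidate variables per split;
#' * `ann`: single-hidden-layer network whose size and weight decay are
#'   chosen by 5-fold cross-validation (held-out log-loss), at most 200
#'   iterations.
#'
#' @param algorithm One of `"glm"`, `"gam"`, `"rf"`, `"ann"`.
#' @param ... Overrides of the algorithm's settings (`step`, `k`,
#'   `num_trees`, `min_node`, `sizes`, `decays`, `folds`, `maxit`).
#' @return A list of class `sdm_config`.
#' @export
sdm_config <- function(algorithm = c("glm", "gam", "rf", "ann"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    glm = list(step = TRUE),
    gam = list(k = 5),
    rf = list(num_trees = 750, min_node = 10),
    ann = list(sizes = c(2, 4, 6, 8), decays = c(1e-1, 1e-2, 1e-3),
               folds = 5, maxit = 200)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown settings for ", algorithm, ": ", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(c(list(algorithm = algorithm), defaults), class = "sdm_config")
}

#' Default configurations for all four model families
#' @param ... Per-algorithm override lists, e.g. `ann = list(sizes = 4)`.
#' @return A named list of [sdm_config()] objects.
#' @export
sdm_configs <- function(...) {
  over <- list(...)
  purrr::map(setNames(c("glm", "gam", "rf", "ann"), c("glm", "gam", "rf", "ann")),
             function(a) do.call(sdm_config, c(list(algorithm = a), over[[a]])))
}

#' Fit one species distribution model
#'
#' Fits the configured model family to a weighted presence/background
#' training set and returns a fitted object whose [predict()] method maps
#' predictor values to a probability of presence in `[0, 1]`. Fitting is
#' deterministic given `seed`. Non-convergence or separation surfaces as
#' an object of class `sdm_failure` rather than an error, so ensemble
#' runs can degrade gracefully.
#'
#' @param train A `training_set` tibble (`response`, `weight`, predictor
#'   columns).
#' @param config An [sdm_config()].
#' @param predictors Character vector of predictor columns to use.
#' @param seed Integer seed.
#' @return An object of class `sdm_fit` (or `sdm_failure`).
#' @export
fit_sdm <- function(train, config, predictors, seed = 1) {
  stopifnot(inherits(config, "sdm_config"))
  predictors <- intersect(predictors, names(train))
  if (length(predictors) == 0) abort("No predictor columns found in `train`.")
  d <- as_tibble(train)[, c("response", "weight", predictors)]
  d <- d[complete.cases(d), ]
  if (length(unique(d$response)) < 2) {
    return(structure(list(error = "single-class training set"), class = "sdm_failure"))
  }
  set.seed(as.integer(seed))
  res <- tryCatch(
    switch(config$algorithm,
      glm = fit_sdm_glm(d, predictors, config),
      gam = fit_sdm_gam(d, predictors, config),
      rf = fit_sdm_rf(d, predictors, config, seed),
      ann = fit_sdm_ann(d, predictors, config, seed)
    ),
    error = function(e) structure(list(error = conditionMessage(e)), class = "sdm_failure")
  )
  if (inherits(res, "sdm_failure")) return(res)
  structure(
    list(algorithm = config$algorithm, model = res$model,
         predictors = predictors, config = config, scaling = res$scaling),
    class = "sdm_fit"
  )
}

fit_sdm_glm <- function(d, predictors, config) {
  form <- as.formula(paste(
    "response ~",
    paste(sprintf("%s + I(%s^2)", predictors, predictors), collapse = " + ")
  ))
  fit <- suppressWarnings(glm(form, family = binomial(), data = d, weights = d$weight))
  if (isTRUE(config$step)) {
    fit <- suppressWarnings(MASS::stepAIC(
      fit, direction = "both", trace = 0,
      scope = list(lower = response ~ 1, upper = form)
    ))
  }
  list(model = fit, scaling = NULL)
}

fit_sdm_gam <- function(d, predictors, config) {
  terms <- purrr::map_chr(predictors, function(p) {
    k <- min(config$k, length(unique(d[[p]])) - 1)
    if (k >= 3) sprintf("s(%s, k = %d)", p, k) else p
  })
  form <- as.formula(paste("response ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(
    mgcv::gam(form, family = binomial(), data = d, weights = d$weight)
  )
  list(model = fit, scaling = NULL)
}

fit_sdm_rf <- function(d, predictors, config, seed) {
  fit <- ranger::ranger(
    y = factor(d$response, levels = c(0, 1)),
    x = d[, predictors, drop = FALSE],
    probability = TRUE,
    num.trees = config$num_trees,
    min.node.size = config$min_node,
    mtry = max(1, floor(length(predictors) / 3)),
    case.weights = d$weight,
    seed = seed, num.threads = 1
  )
  list(model = fit, scaling = NULL)
}

fit_sdm_ann <- function(d, predictors, config, seed) {
  x <- as.matrix(d[, predictors, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  y <- d$response
  grid <- expand.grid(size = config$sizes, decay = config$decays,
                      KEEP.OUT.ATTRS = FALSE)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(config$folds), length(idx)))
  }
  loss <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    ll <- purrr::map_dbl(seq_len(config$folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
      set.seed(seed + 1000 * g + f)
      net <- nnet::nnet(
        x = xs[tr, , drop = FALSE], y = y[tr], weights = d$weight[tr],
        size = grid$size[g], decay = grid$decay[g], maxit = config$maxit,
        entropy = TRUE, trace = FALSE
      )
      p <- pmin(1 - 1e-12, pmax(1e-12, predict(net, xs[!tr, , drop = FALSE])))
      -mean(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
    })
    mean(ll, na.rm = TRUE)
  })
  best <- which.min(loss)
  set.seed(seed)
  net <- nnet::nnet(
    x = xs, y = y, weights = d$weight,
    size = grid$size[best], decay = grid$decay[best], maxit = config$maxit,
    entropy = TRUE, trace = FALSE
  )
  list(model = net, scaling = list(center = ctr, scale = scl,
                                   size = grid$size[best], decay = grid$decay[best]))
}

#' Predict habitat suitability from a fitted SDM
#'
#' @param object An `sdm_fit`.
#' @param newdata A data frame containing the fit's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]` (`NA` where a
#'   predictor is missing).
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  nd <- as_tibble(newdata)[, object$predictors, drop = FALSE]
  ok <- complete.cases(nd)
  p <- rep(NA_real_, nrow(nd))
  if (!any(ok)) return(p)
  ndo <- nd[ok, , drop = FALSE]
  p[ok] <- switch(object$algorithm,
    glm = predict(object$model, newdata = ndo, type = "response"),
    gam = as.numeric(predict(object$model, newdata = ndo, type = "response")),
    rf = predict(object$model, data = ndo, num.threads = 1)$predictions[, "1"],
    ann = {
      xs <- scale(as.matrix(ndo), object$scaling$center, object$scaling$scale)
      as.numeric(predict(object$model, xs))
    }
  )
  pmin(1, pmax(0, p))
}

#' True skill statistic of probabilistic predictions
#'
#' `TSS = max over thresholds of (sensitivity + specificity - 1)`,
#' with the threshold grid at 0.01 steps in (0, 1) and presence called at
#' probability `>=` threshold.
#'
#' @param obs 0/1 observations.
#' @param pred Probabilities.
#' @param thresholds Threshold grid.
#' @return A single TSS value in `[-1, 1]` (`NA` for single-class `obs`).
#' @export
tss_score <- function(obs, pred, thresholds = seq(0.01, 0.99, by = 0.01)) {
  keep <- !is.na(obs) & !is.na(pred)
  obs <- obs[keep]; pred <- pred[keep]
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  tss <- purrr::map_dbl(thresholds, function(th) {
    pp <- pred >= th
    sens <- sum(pp & obs == 1) / n1
    spec <- sum(!pp & obs == 0) / n0
    sens + spec - 1
  })
  max(tss)
}

#' Area under the ROC curve via the rank (Mann-Whitney) statistic
#'
#' @inheritParams tss_score
#' @return AUC in `[0, 1]` (`NA` for single-class `obs`).
#' @export
auc_score <- function(obs, pred) {
  keep <- !is.na(obs) & !is.na(pred)
  obs <- obs[keep]; pred <- pred[keep]
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred)
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted SDM on a held-out test split
#'
#' @param fitted An `sdm_fit` (or `sdm_failure`).
#' @param test A held-out `training_set` tibble.
#' @return A one-row tibble (algorithm, tss, auc, note). Skill is `NA`
#'   with a note for failures or single-class test sets.
#' @export
evaluate_split <- function(fitted, test) {
  if (inherits(fitted, "sdm_failure")) {
    return(tibble(algorithm = NA_character_, tss = NA_real_, auc = NA_real_,
                  note = paste("fit failed:", fitted$error)))
  }
  p <- predict(fitted, test)
  tss <- tss_score(test$response, p)
  auc <- auc_score(test$response, p)
  note <- if (is.na(tss)) "single-class test set" else NA_character_
  tibble(algorithm = fitted$algorithm, tss = tss, auc = auc, note = note)
}

# Stratified train/test split indices (per-class sampling).
stratified_split <- function(response, test_frac, seed) {
  set.seed(as.integer(seed))
  test <- logical(length(response))
  for (cl in unique(response)) {
    idx <- which(response == cl)
    n_test <- max(1, round(test_frac * length(idx)))
    test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Run the full model-fitting design for an ensemble
#'
#' For every species x predictor set x split, the presence/background
#' rows are split into 80% training and 20% testing (stratified by class
#' so every test fold contains presences), each algorithm is fitted on
#' the training fold and scored on the test fold. Splits are shared
#' across algorithms within a (species, set, split) so skill differences
#' reflect the algorithms, not the folds. The per-split fitted models are
#' retained for the projection stage, where their predictions are
#' averaged.
#'
#' @param training_sets Named list (by species id) of `training_set`
#'   tibbles.
#' @param sets Named list of predictor sets.
#' @param configs Named list of [sdm_config()]s (default all four
#'   families).
#' @param n_splits Number of repeated evaluation splits.
#' @param test_frac Held-out fraction.
#' @param seed Integer seed.
#' @return A list of class `sdm_design`: `skill` (tibble with one row per
#'   species x algorithm x set x split) and `fits` (nested list
#'   `fits[[species]][[set]][[algorithm]]`, a list of per-split
#'   `sdm_fit`s).
#' @export
run_sdm_design <- function(training_sets, sets, configs = sdm_configs(),
                           n_splits = 10, test_frac = 0.2, seed = 1) {
  skill <- list()
  fits <- list()
  species <- names(training_sets)
  for (si in seq_along(species)) {
    sp <- species[si]
    train_full <- training_sets[[sp]]
    fits[[sp]] <- list()
    for (set_id in names(sets)) {
      fits[[sp]][[set_id]] <- purrr::map(configs, function(...) list())
      for (split in seq_len(n_splits)) {
        split_seed <- (seed * 10007L + si * 101L + match(set_id, names(sets)) * 11L +
                         split) %% .Machine$integer.max
        is_test <- stratified_split(train_full$response, test_frac, split_seed)
        tr <- train_full[!is_test, ]
        te <- train_full[is_test, ]
        for (alg in names(configs)) {
          fit <- fit_sdm(tr, configs[[alg]], sets[[set_id]], seed = split_seed)
          ev <- evaluate_split(fit, te)
          skill[[length(skill) + 1]] <- ev |>
            mutate(species_id = sp, algorithm = alg, set = set_id, split = split)
          fits[[sp]][[set_id]][[alg]][[split]] <- fit
        }
      }
    }
  }
  skill <- bind_rows(skill) |>
    select("species_id", "algorithm", "set", "split", "tss", "auc", "note")
  structure(list(skill = skill, fits = fits,
                 settings = list(sets = sets, configs = configs,
                                 n_splits = n_splits, seed = seed)),
            class = "sdm_design")
}

#' @export
print.sdm_design <- function(x, ...) {
  cat("<sdm_design>", n_distinct(x$skill$species_id), "species,",
      nrow(x$skill), "skill records\n")
  invisible(x)
}

#' Fitted thermal (or other single-predictor) optimum of an SDM
#'
#' Probes the fitted response along the realised environmental gradient:
#' predictions over the supplied climatology are binned by the focal
#' predictor and the bin-mean response curve's argmax is returned. This
#' respects the covariance structure of the environment (unlike holding
#' the other predictors at fixed values) and is the probe used by niche
#' recovery checks.
#'
#' @param fit An `sdm_fit`.
#' @param stack A `predictor_stack` to probe over.
#' @param predictor Focal predictor name.
#' @param bin_width Bin width in predictor units.
#' @return The predictor value at the maximum of the binned mean
#'   response.
#' @export
niche_optimum <- function(fit, stack, predictor = "sst", bin_width = 0.5) {
  p <- predict(fit, stack)
  v <- stack[[predictor]]
  bins <- seq(min(v, na.rm = TRUE), max(v, na.rm = TRUE) + bin_width,
              by = bin_width)
  prof <- tibble(v = v, p = p) |>
    mutate(bin = cut(.data$v, bins, include.lowest = TRUE)) |>
    group_by(.data$bin) |>
    summarise(v = mean(.data$v), p = mean(.data$p, na.rm = TRUE),
              .groups = "drop")
  prof$v[which.max(prof$p)]
}

#' Retain species by ensemble skill and presence count
#'
#' A species is retained when its mean TSS across all fitted members is
#' strictly greater than `tss_min` and it has at least `min_presences`
#' monthly grid presences. (The presence rule is frozen as inclusive,
#' `>= 75`, which matches the stated presence-to-predictor rationale.)
#'
#' @param skill The `skill` tibble of an [run_sdm_design()] result.
#' @param presence_counts A [presence_counts()] tibble.
#' @param tss_min Strict lower bound on mean TSS.
#' @param min_presences Inclusive lower bound on presences.
#' @return A tibble (species_id, mean_tss, n_presence, retained).
#' @export
select_species <- function(skill, presence_counts,
                           tss_min = 0.30, min_presences = 75) {
  skill |>
    group_by(.data$species_id) |>
    summarise(mean_tss = mean(.data$tss, na.rm = TRUE), .groups = "drop") |>
    left_join(presence_counts, by = "species_id") |>
    mutate(
      n_presence = coalesce(.data$n_presence, 0L),
      retained = .data$mean_tss > tss_min & .data$n_presence >= min_presences
    )
}
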