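#' SDM-specific binarisation threshold ranges
#'
#' Habitat suitability is converted to presence-absence over a range of
#' thresholds rather than a single cut: `[0.25, 0.40]` for the smoother
#' GLM/GAM/ANN responses and `[0.10, 0.25]` for the sharper random
#' forest, stepped by 0.01, with presence called at suitability `>=`
#' threshold.
#'
#' @param glm,gam,ann,rf Two-element `[lo, hi]` ranges per algorithm.
#' @param step Threshold step.
#' @return A list of class `threshold_policy`.
#' @export
threshold_policy <- function(glm = c(0.25, 0.40), gam = c(0.25, 0.40),
                             ann = c(0.25, 0.40), rf = c(0.10, 0.25),
                             step = 0.01) {
  pol <- list(glm = glm, gam = gam, ann = ann, rf = rf, step = step)
  for (a in c("glm", "gam", "ann", "rf")) {
    r <- pol[[a]]
    if (!(length(r) == 2 && r[1] > 0 && r[2] < 1 && r[1] < r[2])) {
      abort(sprintf("Threshold range for %s must satisfy 0 < lo < hi < 1.", a))
    }
  }
  structure(pol, class = "threshold_policy")
}

#' Thresholds applicable to one algorithm under a policy
#' @param policy A [threshold_policy()].
#' @param algorithm Algorithm name.
#' @return Numeric vector of thresholds.
#' @export
thresholds_for <- function(policy, algorithm) {
  r <- policy[[algorithm]]
  if (is.null(r)) abort(sprintf("No threshold range for algorithm '%s'.", algorithm))
  seq(r[1], r[2], by = policy$step)
}

#' Binarise annual habitat suitability at a threshold
#'
#' @param annual An annual HSI tibble ([annual_hsi()]).
#' @param threshold A single threshold; must lie inside each member
#'   algorithm's policy range.
#' @param policy A [threshold_policy()].
#' @return The input with a logical `present` column (`hsi >= threshold`).
#' @export
binarize_hsi <- function(annual, threshold, policy = threshold_policy()) {
  for (alg in unique(annual$algorithm)) {
    r <- policy[[alg]]
    if (is.null(r) || threshold < r[1] - 1e-9 || threshold > r[2] + 1e-9) {
      abort(sprintf(
        "Threshold %.2f is outside the [%.2f, %.2f] range for %s members.",
        threshold, r[1] %||% NA, r[2] %||% NA, alg
      ))
    }
  }
  annual |> mutate(present = .data$hsi >= threshold)
}

#' Partition temporal Jaccard dissimilarity into turnover and nestedness
#'
#' For two assemblages over a common species universe with `a` shared
#' species and `b`, `c` exclusive ones, total dissimilarity is
#' `beta_jac = (b + c) / (a + b + c)`, the true-turnover (replacement)
#' component is `beta_jtu = 2 * min(b, c) / (a + 2 * min(b, c))`, and the
#' nestedness (richness-change) component is the exact remainder
#' `beta_jne = beta_jac - beta_jtu`. Two empty assemblages return all
#' components 0 by convention.
#'
#' @param present,future Character vectors of species, or logical vectors
#'   over the same species universe.
#' @return A one-row tibble (a, b, c, beta_jac, beta_jtu, beta_jne).
#' @examples
#' jaccard_decompose(c("s1", "s2"), c("s3", "s4")) # complete replacement
#' @export
jaccard_decompose <- function(present, future) {
  if (is.logical(present) || is.logical(future)) {
    if (length(present) != length(future)) {
      abort("Logical assemblage vectors must share one species universe.")
    }
    a <- sum(present & future)
    b <- sum(present & !future)
    cc <- sum(!present & future)
  } else {
    present <- unique(present); future <- unique(future)
    a <- length(intersect(present, future))
    b <- length(setdiff(present, future))
    cc <- length(setdiff(future, present))
  }
  jaccard_from_abc(a, b, cc)
}

# Vectorised core of the partition.
jaccard_from_abc <- function(a, b, cc) {
  tot <- a + b + cc
  m <- pmin(b, cc)
  beta_jac <- ifelse(tot == 0, 0, (b + cc) / tot)
  beta_jtu <- ifelse(a + 2 * m == 0, 0, 2 * m / (a + 2 * m))
  tibble(a = a, b = b, c = cc,
         beta_jac = beta_jac, beta_jtu = beta_jtu,
         beta_jne = beta_jac - beta_jtu)
}

#' Ensemble turnover fields from present and future suitability cubes
#'
#' For every matched ensemble member (same algorithm and predictor set;
#' future members additionally carry an ESM) and every threshold in the
#' member algorithm's policy range, binarises the annual suitability of
#' both periods, computes the per-cell Jaccard partition over the species
#' group, and averages the components over members x thresholds.
#'
#' @param present_cube,future_cube `hsi_cube`s (monthly) or annual HSI
#'   tibbles.
#' @param policy A [threshold_policy()].
#' @param species Optional species subset (e.g. one trophic group).
#' @return A tibble per cell: means and standard deviations of the true
#'   turnover (`st`), nestedness (`jne`) and total Jaccard (`jac`)
#'   components, plus `n_combos`.
#' @export
turnover_ensemble <- function(present_cube, future_cube,
                              policy = threshold_policy(), species = NULL) {
  to_annual <- function(x) {
    if ("month" %in% names(x)) annual_hsi(x) else as_tibble(x)
  }
  p_ann <- to_annual(present_cube)
  f_ann <- to_annual(future_cube)
  if (!is.null(species)) {
    p_ann <- filter(p_ann, .data$species_id %in% species)
    f_ann <- filter(f_ann, .data$species_id %in% species)
  }
  sp_all <- sort(unique(c(p_ann$species_id, f_ann$species_id)))
  cells <- sort(unique(c(p_ann$cell, f_ann$cell)))

  to_matrix <- function(d) {
    m <- matrix(0, nrow = length(cells), ncol = length(sp_all),
                dimnames = list(cells, sp_all))
    m[cbind(match(d$cell, cells), match(d$species_id, sp_all))] <- d$hsi
    m
  }

  members <- inner_join(
    distinct(p_ann, .data$algorithm, .data$set),
    distinct(f_ann, .data$algorithm, .data$set, .data$esm),
    by = c("algorithm", "set")
  )

  acc <- NULL
  n_combo <- 0
  for (i in seq_len(nrow(members))) {
    alg <- members$algorithm[i]
    pm <- to_matrix(filter(p_ann, .data$algorithm == alg, .data$set == members$set[i]))
    fm <- to_matrix(filter(f_ann, .data$algorithm == alg, .data$set == members$set[i],
                           .data$esm == members$esm[i]))
    for (th in thresholds_for(policy, alg)) {
      pb <- pm >= th
      fb <- fm >= th
      a <- unname(rowSums(pb & fb))
      b <- unname(rowSums(pb & !fb))
      cc <- unname(rowSums(!pb & fb))
      dec <- jaccard_from_abc(a, b, cc)
      n_combo <- n_combo + 1
      if (is.null(acc)) {
        acc <- list(st = dec$beta_jtu, jne = dec$beta_jne, jac = dec$beta_jac,
                    st2 = dec$beta_jtu^2, jne2 = dec$beta_jne^2, jac2 = dec$beta_jac^2)
      } else {
        acc$st <- acc$st + dec$beta_jtu
        acc$jne <- acc$jne + dec$beta_jne
        acc$jac <- acc$jac + dec$beta_jac
        acc$st2 <- acc$st2 + dec$beta_jtu^2
        acc$jne2 <- acc$jne2 + dec$beta_jne^2
        acc$jac2 <- acc$jac2 + dec$beta_jac^2
      }
    }
  }
  if (n_combo == 0) abort("No matched ensemble members between the two cubes.")
  sd_of <- function(s, s2) {
    v <- pmax(0, s2 / n_combo - (s / n_combo)^2)
    sqrt(v * n_combo / max(1, n_combo - 1))
  }
  tibble(
    cell = as.integer(cells),
    st_mean = acc$st / n_combo, st_sd = sd_of(acc$st, acc$st2),
    jne_mean = acc$jne / n_combo, jne_sd = sd_of(acc$jne, acc$jne2),
    jac_mean = acc$jac / n_combo, jac_sd = sd_of(acc$jac, acc$jac2),
    n_combos = n_combo
  )
}
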