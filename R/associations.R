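#' Two-by-two co-occurrence contingency table
#'
#' @param a_pres,b_pres Logical presence vectors for the two species over
#'   the same cell universe.
#' @return A one-row tibble (k11 both present, k12 A only, k21 B only,
#'   k22 neither, n).
#' @export
contingency <- function(a_pres, b_pres) {
  if (length(a_pres) != length(b_pres)) {
    abort("The two species must share one cell universe.")
  }
  tibble(
    k11 = sum(a_pres & b_pres),
    k12 = sum(a_pres & !b_pres),
    k21 = sum(!a_pres & b_pres),
    k22 = sum(!a_pres & !b_pres),
    n = length(a_pres)
  )
}

#' Signed log-likelihood-ratio association score
#'
#' The unsigned score is the Dunning G-squared statistic of the 2x2
#' table, `2 * sum(k_ij * ln(k_ij * N / (k_i. * k_.j)))` with
#' `0 * ln 0 = 0` (equivalently `2N * (H(rows) + H(cols) - H(cells))`
#' with `H` the Shannon entropy). The sign is flipped to negative when
#' the observed co-occurrence `k11` falls below the independence
#' expectation `k1. * k.1 / N`, so negative scores mark avoidance-like
#' (one-sided occurrence or co-absence) association. Tables with a zero
#' row or column margin score 0.
#'
#' @param k11,k12,k21,k22 Cell counts (vectorised).
#' @return Signed LLR value(s).
#' @examples
#' llr_score(10, 0, 0, 10) # 40 * log(2), perfect co-occurrence
#' @export
llr_score <- function(k11, k12, k21, k22) {
  n <- k11 + k12 + k21 + k22
  if (any(n == 0)) abort("Empty contingency table (N = 0).")
  r1 <- k11 + k12; r2 <- k21 + k22
  c1 <- k11 + k21; c2 <- k12 + k22
  term <- function(k, r, cc) {
    out <- rep(0, length(k))
    pos <- k > 0
    out[pos] <- k[pos] * log(k[pos] * n[pos] / (r[pos] * cc[pos]))
    out
  }
  g2 <- 2 * (term(k11, r1, c1) + term(k12, r1, c2) +
               term(k21, r2, c1) + term(k22, r2, c2))
  g2[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- 0
  sign_flip <- k11 < r1 * c1 / n
  ifelse(sign_flip, -g2, g2)
}

#' Score all pairwise species associations in an assemblage
#'
#' Computes the signed LLR for every unordered pair of species present in
#' at least one cell of the binary assemblage matrix. The pair counts are
#' obtained by cross-products, so the result matches a cell-by-cell count
#' exactly.
#'
#' @param assemblage A logical cells x species matrix, or a tibble with
#'   `cell`, `species_id` and logical `present`.
#' @return An edge tibble (species_a, species_b, k11, k12, k21, k22,
#'   llr), `species_a < species_b`.
#' @export
score_associations <- function(assemblage) {
  m <- if (is.matrix(assemblage)) {
    assemblage
  } else {
    d <- as_tibble(assemblage)
    stopifnot(all(c("cell", "species_id", "present") %in% names(d)))
    wide <- tidyr::pivot_wider(
      d |> select("cell", "species_id", "present"),
      names_from = "species_id", values_from = "present", values_fill = FALSE
    )
    as.matrix(wide[, -1, drop = FALSE])
  }
  storage.mode(m) <- "integer"
  m <- m[, colSums(m) > 0, drop = FALSE]
  sp <- colnames(m)
  if (length(sp) < 2) {
    return(tibble(species_a = character(), species_b = character(),
                  k11 = integer(), k12 = integer(), k21 = integer(),
                  k22 = integer(), llr = numeric()))
  }
  n_cell <- nrow(m)
  k11 <- crossprod(m)
  tot <- colSums(m)
  ij <- which(upper.tri(k11), arr.ind = TRUE)
  k11v <- unname(k11[ij])
  k12v <- unname(tot[ij[, 1]]) - k11v
  k21v <- unname(tot[ij[, 2]]) - k11v
  k22v <- n_cell - k11v - k12v - k21v
  tibble(
    species_a = sp[ij[, 1]], species_b = sp[ij[, 2]],
    k11 = as.integer(k11v), k12 = as.integer(k12v),
    k21 = as.integer(k21v), k22 = as.integer(k22v),
    llr = llr_score(k11v, k12v, k21v, k22v)
  )
}

#' Retain significant associations by the 75th-percentile rule
#'
#' Negative scores, and positive scores not exceeding the 75th percentile
#' (linear-interpolation, type 7) of the positive scores of the same
#' scenario, are non-significant. A scenario with a single positive score
#' therefore retains nothing and is flagged degenerate.
#'
#' @param scores An edge tibble from [score_associations()].
#' @param prob Percentile of the positive-score distribution.
#' @return The retained edges, with the threshold attached as attribute
#'   `q_threshold`.
#' @export
significant_pairs <- function(scores, prob = 0.75) {
  pos <- filter(scores, .data$llr > 0)
  if (nrow(pos) == 0) {
    warn("No positive association scores; returning an empty set.")
    out <- scores[0, ]
    attr(out, "q_threshold") <- NA_real_
    return(out)
  }
  q <- quantile(pos$llr, prob, type = 7, names = FALSE)
  out <- filter(pos, .data$llr > q)
  if (nrow(pos) == 1) {
    warn("Single positive score: the percentile rule retains nothing (degenerate).")
  }
  attr(out, "q_threshold") <- q
  out
}

pair_keys <- function(edges) {
  if (nrow(edges) == 0) return(character())
  paste(pmin(edges$species_a, edges$species_b),
        pmax(edges$species_a, edges$species_b), sep = "|")
}

#' Compare present and future interactomes
#'
#' @param present,future Edge tibbles of significant associations for one
#'   matched ensemble member.
#' @return A one-row tibble with `constant`, `lost`, `gained` counts and
#'   the corresponding fractions of the union.
#' @export
compare_interactomes <- function(present, future) {
  p <- pair_keys(present)
  f <- pair_keys(future)
  u <- union(p, f)
  constant <- length(intersect(p, f))
  lost <- length(setdiff(p, f))
  gained <- length(setdiff(f, p))
  denom <- max(1, length(u))
  tibble(
    constant = constant, lost = lost, gained = gained, union = length(u),
    frac_constant = constant / denom,
    frac_lost = lost / denom,
    frac_gained = gained / denom
  )
}

#' Median and IQR of interactome change across ensemble members
#'
#' @param comparisons A tibble of [compare_interactomes()] rows (one per
#'   matched member).
#' @return A tibble with the median and IQR of each fraction.
#' @export
interactome_summary <- function(comparisons) {
  comparisons |>
    summarise(across(
      c("frac_constant", "frac_lost", "frac_gained"),
      list(median = median, iqr = stats::IQR)
    ))
}
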