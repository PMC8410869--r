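test_that("contingency tables count the four cells exactly", {
  a <- rep(TRUE, 20); b <- rep(FALSE, 20)
  t1 <- contingency(a, b)
  expect_equal(unlist(t1[, 1:4]), c(k11 = 0, k12 = 20, k21 = 0, k22 = 0))
  a2 <- c(rep(TRUE, 10), rep(FALSE, 10))
  t2 <- contingency(a2, a2)
  expect_equal(unlist(t2[, 1:4]), c(k11 = 10, k12 = 0, k21 = 0, k22 = 10))
  # random fixture vs a brute-force cell loop
  set.seed(9)
  x <- runif(50) > 0.5; y <- runif(50) > 0.6
  t3 <- contingency(x, y)
  loop <- c(0, 0, 0, 0)
  for (i in 1:50) {
    loop <- loop + c(x[i] && y[i], x[i] && !y[i], !x[i] && y[i], !x[i] && !y[i])
  }
  expect_equal(unname(unlist(t3[, 1:4])), loop)
  expect_error(contingency(x, y[1:10]), "universe")
})

test_that("the signed LLR equals the G2 oracle on all small tables", {
  # exhaustive over 2x2 tables with N <= 14, spot magnitudes at N = 40
  for (n in c(4, 9, 14)) {
    combos <- expand.grid(k11 = 0:n, k12 = 0:n, k21 = 0:n)
    combos <- combos[rowSums(combos) <= n, ]
    for (r in seq_len(nrow(combos))) {
      k <- combos[r, ]
      k22 <- n - sum(k)
      got <- llr_score(k$k11, k$k12, k$k21, k22)
      want <- oracle_g2(k$k11, k$k12, k$k21, k22)
      expect_equal(abs(got), want, tolerance = 1e-10)
      expn <- (k$k11 + k$k12) * (k$k11 + k$k21) / n
      if (k$k11 < expn) expect_lte(got, 0)
    }
  }
  expect_equal(llr_score(10, 0, 0, 10), 40 * log(2))
  expect_equal(llr_score(0, 10, 10, 0), -40 * log(2))
  expect_equal(llr_score(25, 25, 25, 25), 0) # exact independence
  expect_equal(llr_score(5, 0, 5, 0), 0)     # zero column margin
  expect_error(llr_score(0, 0, 0, 0), "N = 0")
})

test_that("LLR is symmetric in the pair and scales linearly with N", {
  set.seed(4)
  for (i in 1:20) {
    k <- rmultinom(1, 60, runif(4, 0.05, 1))
    expect_equal(llr_score(k[1], k[2], k[3], k[4]),
                 llr_score(k[1], k[3], k[2], k[4])) # swap the two species
  }
  base <- llr_score(12, 4, 6, 18)
  expect_equal(llr_score(10 * 12, 10 * 4, 10 * 6, 10 * 18), 10 * base,
               tolerance = 1e-9)
})

test_that("all-pairs scoring matches per-pair computation", {
  set.seed(14)
  m <- matrix(runif(200) > 0.5, nrow = 20,
              dimnames = list(NULL, sprintf("s%02d", 1:10)))
  edges <- score_associations(m)
  expect_equal(nrow(edges), choose(10, 2))
  for (r in sample(nrow(edges), 10)) {
    e <- edges[r, ]
    tt <- contingency(m[, e$species_a], m[, e$species_b])
    expect_equal(unlist(e[, c("k11", "k12", "k21", "k22")]),
                 unlist(tt[, 1:4]))
    expect_equal(e$llr, llr_score(tt$k11, tt$k12, tt$k21, tt$k22))
  }
})

test_that("the percentile rule retains only the top quartile of positive scores", {
  scores <- tibble::tibble(
    species_a = sprintf("a%d", 1:6), species_b = sprintf("b%d", 1:6),
    llr = c(1, 2, 3, 4, -5, -1)
  )
  sig <- significant_pairs(scores)
  # type-7 Q75 of {1,2,3,4} is 3.25; only 4 exceeds it
  expect_equal(attr(sig, "q_threshold"), 3.25)
  expect_equal(sig$llr, 4)
  # all-negative scenario: empty with a warning
  neg <- dplyr::mutate(scores, llr = -abs(llr))
  expect_warning(out <- significant_pairs(neg), "No positive")
  expect_equal(nrow(out), 0)
  # single positive score: degenerate, retains nothing
  one <- scores[1, ]
  expect_warning(out1 <- significant_pairs(one), "degenerate")
  expect_equal(nrow(out1), 0)
})

test_that("interactome comparison counts constant, lost and gained edges", {
  mk <- function(pairs) tibble::tibble(
    species_a = purrr::map_chr(pairs, 1), species_b = purrr::map_chr(pairs, 2)
  )
  p <- mk(list(c("a", "b"), c("b", "c")))
  f <- mk(list(c("b", "c"), c("c", "d")))
  cmp <- compare_interactomes(p, f)
  expect_equal(cmp$constant, 1)
  expect_equal(cmp$lost, 1)
  expect_equal(cmp$gained, 1)
  # identity
  cmp_id <- compare_interactomes(p, p)
  expect_equal(cmp_id$frac_constant, 1)
  expect_equal(cmp_id$lost + cmp_id$gained, 0)
  # disjoint equal-size sets split the union evenly
  p5 <- mk(purrr::map(1:5, ~ c(sprintf("x%d", .x), sprintf("y%d", .x))))
  f5 <- mk(purrr::map(6:10, ~ c(sprintf("x%d", .x), sprintf("y%d", .x))))
  cmp5 <- compare_interactomes(p5, f5)
  expect_equal(cmp5$frac_lost, 0.5)
  expect_equal(cmp5$frac_gained, 0.5)
  # edge order within a pair does not matter
  frev <- mk(list(c("c", "b"), c("d", "c")))
  expect_equal(compare_interactomes(p, frev)$constant, 1)
  s <- interactome_summary(dplyr::bind_rows(cmp, cmp_id))
  expect_named(s, c("frac_constant_median", "frac_constant_iqr",
                    "frac_lost_median", "frac_lost_iqr",
                    "frac_gained_median", "frac_gained_iqr"))
})
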