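test_that("contingency chi-square matches closed forms and symmetries", {
  r <- chi2_contingency(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic_value, 0)
  expect_equal(r$p_value, 1)
  r <- chi2_contingency(matrix(c(20, 10, 10, 20), 2))
  expect_equal(round(r$statistic_value, 3), 6.667)  # n(ad-bc)^2 / products
  expect_equal(r$df, 1L)
  # invariant under row and column swaps
  set.seed(9)
  tab <- matrix(sample(5:40, 6), 2)
  expect_equal(chi2_contingency(tab)$statistic_value,
               chi2_contingency(tab[2:1, ])$statistic_value)
  expect_equal(chi2_contingency(tab)$statistic_value,
               chi2_contingency(tab[, c(2, 1, 3)])$statistic_value)
  expect_error(chi2_contingency(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("binned length chi-square merges bins and matches hand computation", {
  set.seed(10)
  a <- c(rep(10, 20), rep(16, 25), rep(22, 18), rep(31, 9))
  b <- c(rep(10, 30), rep(16, 15), rep(22, 20), rep(31, 3))
  r <- chi2_binned(a, b, bin_width = 3, min_expected = 5)
  # independent recomputation: histogram on the same grid, same merge rule
  breaks <- seq(9, 33, by = 3)
  ca <- hist(a, breaks = breaks, right = FALSE, plot = FALSE)$counts
  cb <- hist(b, breaks = breaks, right = FALSE, plot = FALSE)$counts
  tab <- rbind(ca, cb)
  repeat {
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(expct < 5, 2, any))
    if (length(bad) == 0) break
    j <- max(bad); if (j == 1) j <- 2
    tab[, j - 1] <- tab[, j - 1] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  want <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(r$statistic_value, unname(want$statistic))
  expect_equal(r$df, unname(want$parameter))
  expect_equal(r$n_bins, ncol(tab))
})

test_that("identical samples give zero chi-square; separated ones reject", {
  x <- rep(c(30, 60, 90, 120), each = 10)
  r <- chi2_binned(x, x, bin_width = 3)
  expect_equal(r$statistic_value, 0)
  r <- chi2_binned(rep(c(30, 33), 30), rep(c(300, 303), 30), bin_width = 3)
  expect_lt(r$p_value, 1e-10)
  expect_error(chi2_binned(rep(10, 3), rep(10, 4)), "insufficient spread")
})

test_that("Mann-Whitney U follows the documented conventions", {
  x <- c(1, 2, 3, 4)
  r <- mann_whitney_u(x, x, method = "normal")
  expect_equal(r$statistic_value, length(x)^2 / 2)  # identical samples
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12, 13))
  expect_equal(r$statistic_value, 0)  # first sample entirely below
  r <- mann_whitney_u(c(10, 11, 12, 13), c(1, 2, 3))
  expect_equal(r$statistic_value, 12)  # n1 * n2 at the other extreme
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3), method = "exact"), "ties")
})

test_that("exact Mann-Whitney p equals exhaustive enumeration", {
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- sample(1:50, n1 + n2)  # distinct -> tie-free
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    r <- mann_whitney_u(a, b, method = "exact")
    expect_equal(r$p_value, enumerate_mw_p(a, b))
  }
})

test_that("signed-rank test drops zeros, reports Z, rejects degenerate input", {
  a <- c(1, 2, 3, 4, 5)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
  expect_message(r <- wilcoxon_signed_rank(c(a, 7), c(a + 1, 7),
                                           method = "normal"),
                 "zero difference")
  expect_equal(r$n_dropped, 1L)
  # constant positive shift: V is maximal n(n+1)/2
  r <- wilcoxon_signed_rank(a + 10, a, method = "normal")
  expect_equal(r$statistic_value, 5 * 6 / 2)
  expect_gt(r$z, 0)
})

test_that("exact signed-rank p equals exhaustive sign enumeration", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    d <- sample(setdiff(-30:30, 0), n)  # distinct magnitudes likely
    if (anyDuplicated(abs(d)) > 0) next
    a <- cumsum(abs(d)) + 100
    b <- a - d
    r <- wilcoxon_signed_rank(a, b, method = "exact")
    expect_equal(r$p_value, enumerate_wilcoxon_p(a, b))
  }
})

test_that("Bonferroni adjustment is capped and monotone", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 10), 1)
  p <- c(0.001, 0.02, 0.4)
  expect_true(all(bonferroni(p) >= p))
  expect_equal(bonferroni(p), pmin(1, p * 3))
})
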