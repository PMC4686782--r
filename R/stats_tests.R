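#' @title Statistical comparisons used by the pipeline
#' @description Thin, contract-explicit wrappers around base R tests so every
#'   reported statistic (chi-square, U, V, Z, p) has a single, documented
#'   convention: Pearson chi-square without continuity correction; Mann-Whitney
#'   U of the first sample with tie-corrected normal p (exact for small
#'   tie-free samples); Wilcoxon signed-rank with zero differences dropped and
#'   a reported Z. All p-values are two-sided.
#' @name stats_tests
NULL

test_result <- function(statistic_name, statistic_value, p_value, df = NA_integer_,
                        n1 = NA_integer_, n2 = NA_integer_, correction = "none",
                        extra = list()) {
  structure(
    c(list(statistic_name = statistic_name,
           statistic_value = as.numeric(statistic_value),
           df = if (is.na(df)) NA_integer_ else as.integer(df),
           p_value = as.numeric(p_value),
           n1 = n1, n2 = n2, correction = correction),
      extra),
    class = "site_test_result"
  )
}

#' @export
print.site_test_result <- function(x, ...) {
  cat(sprintf("<%s = %.4g%s, p = %.3g%s%s>\n",
              x$statistic_name, x$statistic_value,
              if (!is.na(x$df)) paste0(", df = ", x$df) else "",
              x$p_value,
              if (!is.na(x$n1)) sprintf(", n1 = %d, n2 = %d", x$n1, x$n2) else "",
              if (x$correction != "none") paste0(" [", x$correction, "]") else ""))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) with
#' `df = (r - 1)(c - 1)`.
#'
#' @param table Numeric matrix of counts (r x c, all `>= 0`, no zero marginal).
#' @return A `site_test_result` with the chi-square statistic, df and p-value.
#' @examples
#' chi2_contingency(matrix(c(20, 10, 10, 20), 2))
#' @export
chi2_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative cell count")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("chi2", unname(ct$statistic), ct$p.value,
              df = unname(ct$parameter))
}

#' Chi-square comparison of two length distributions on shared bins
#'
#' Histograms both samples on shared bins of width `bin_width` nt, merges
#' adjacent bins right-to-left until every expected cell of the resulting
#' 2 x k table is at least `min_expected`, then applies the uncorrected
#' Pearson chi-square with `df = k - 1`.
#'
#' @param lengths_a,lengths_b Numeric vectors (non-empty).
#' @param bin_width Bin width in nt (default 3).
#' @param min_expected Minimum expected cell count after merging (default 5).
#' @return A `site_test_result`; `extra` fields `n_bins` (after merging) and
#'   `bin_width` document the binning actually used.
#' @export
chi2_binned <- function(lengths_a, lengths_b, bin_width = 3, min_expected = 5) {
  stopifnot(length(lengths_a) >= 1L, length(lengths_b) >= 1L)
  lo <- floor(min(lengths_a, lengths_b) / bin_width) * bin_width
  hi <- ceiling((max(lengths_a, lengths_b) + 1e-9) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 2L) breaks <- c(lo, lo + bin_width)
  ca <- as.vector(table(cut(lengths_a, breaks, right = FALSE, include.lowest = TRUE)))
  cb <- as.vector(table(cut(lengths_b, breaks, right = FALSE, include.lowest = TRUE)))
  tab <- rbind(a = ca, b = cb)

  repeat {
    k <- ncol(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(expected < min_expected, 2L, any))
    if (length(bad) == 0L) break
    if (k <= 2L) stop("insufficient spread: fewer than 2 bins remain after merging")
    j <- max(bad)
    if (j == 1L) j <- 2L              # leftmost bin merges into its right neighbour
    tab[, j - 1L] <- tab[, j - 1L] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  res <- chi2_contingency(tab)
  res$n1 <- length(lengths_a); res$n2 <- length(lengths_b)
  res$n_bins <- ncol(tab); res$bin_width <- bin_width
  res
}

#' Mann-Whitney U test (two independent samples)
#'
#' U is reported for the first sample (number of pairs `(x, y)` with `x > y`,
#' counting ties as 1/2), so two samples with identical values give
#' `U = n1 * n2 / 2` and `a` entirely below `b` gives `U = 0`. The p-value is
#' two-sided: exact when `method = "exact"`, or under `"auto"` when both
#' samples have fewer than 50 values and no ties; otherwise the tie-corrected
#' normal approximation (no continuity correction).
#'
#' @param a,b Numeric vectors (non-empty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return A `site_test_result` with `statistic_value = U`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(method,
                  exact = TRUE,
                  normal = FALSE,
                  auto = !ties && length(a) < 50L && length(b) < 50L)
  if (exact && ties) stop("exact Mann-Whitney p-value unavailable with ties")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  test_result("U", unname(wt$statistic), wt$p.value,
              n1 = length(a), n2 = length(b),
              extra = list(method = if (exact) "exact" else "normal"))
}

#' Wilcoxon signed-rank test (paired samples)
#'
#' Differences `a - b` are formed pairwise; zero differences are dropped (with
#' a message). The statistic is V, the sum of ranks of positive differences.
#' Under `"normal"` (or `"auto"` with ties among the absolute differences or
#' 50+ non-zero pairs) the tie-corrected normal approximation is used and Z is
#' reported; under the exact path Z is computed from the same approximation
#' for reference but the p-value is exact.
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return A `site_test_result` with `statistic_value = V` and extra fields
#'   `z` and `n_dropped`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 1L)
  d <- paired_a - paired_b
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) stop("degenerate pairing: all differences are zero")
  if (n_dropped > 0L) message(n_dropped, " zero difference(s) dropped")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu) / sqrt(sigma2)
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- switch(method,
                  exact = TRUE,
                  normal = FALSE,
                  auto = !ties && n < 50L)
  if (exact && ties) stop("exact signed-rank p-value unavailable with ties")
  p <- if (exact) {
    suppressWarnings(stats::wilcox.test(d, exact = TRUE, correct = FALSE))$p.value
  } else {
    2 * stats::pnorm(-abs(z))
  }
  test_result("V", V, p, n1 = n,
              extra = list(z = z, n_dropped = n_dropped,
                           method = if (exact) "exact" else "normal"))
}

#' Bonferroni adjustment of p-values
#'
#' `min(1, p * m)` elementwise, `m` defaulting to the number of p-values.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param m Number of tests (default `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = NULL) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  if (is.null(m)) m <- length(p_values)
  pmin(1, p_values * m)
}
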