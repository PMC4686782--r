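test_that("boundary resampling respects the junction-slot domain", {
  reps <- resample_boundaries(L = 30, m = 0, n_replicates = 5, seed = 1)
  expect_true(all(lengths(reps) == 0L))
  reps <- resample_boundaries(L = 2, m = 1, n_replicates = 5, seed = 1)
  expect_true(all(vapply(reps, identical, logical(1), 1L)))
  expect_error(resample_boundaries(L = 5, m = 5), "slots")
  reps <- resample_boundaries(L = 50, m = 7, n_replicates = 20, seed = 9)
  for (ks in reps) {
    expect_length(ks, 7L)
    expect_false(anyDuplicated(ks) > 0)
    expect_true(all(ks >= 1 & ks <= 49))
  }
})

test_that("resampling is deterministic given a seed and leaves the RNG alone", {
  set.seed(77)
  before <- .Random.seed
  r1 <- resample_boundaries(100, 4, 50, seed = 5)
  expect_identical(.Random.seed, before)
  r2 <- resample_boundaries(100, 4, 50, seed = 5)
  expect_identical(r1, r2)
  p1 <- permute_site_positions(40, 5, 20, seed = 5)
  p2 <- permute_site_positions(40, 5, 20, seed = 5)
  expect_identical(p1, p2)
})

test_that("minimum exon length constraint is honoured when requested", {
  reps <- resample_boundaries(60, 4, 50, seed = 3, min_exon_len = 6)
  for (ks in reps) {
    expect_true(all(diff(c(0L, ks, 60L)) >= 6L))
  }
  expect_error(resample_boundaries(10, 4, 1, seed = 1, min_exon_len = 6),
               "infeasible")
})

test_that("expected borders in area have the hypergeometric mean", {
  area <- list(nt_start = 100L, nt_end = 199L)
  nd <- expected_borders_in_area(area, L = 300, m = 5, n_replicates = 20000,
                                 seed = 12)
  mean_hat <- mean(nd$replicate_values)
  want <- 5 * (199 - 100) / 299  # m * slots / (L - 1)
  se <- stats::sd(nd$replicate_values) / sqrt(nd$n_replicates)
  expect_lt(abs(mean_hat - want), 3 * se)
  # whole-CDS area contains every junction in every replicate
  nd <- expected_borders_in_area(list(nt_start = 1L, nt_end = 60L),
                                 L = 60, m = 4, n_replicates = 10, seed = 1)
  expect_true(all(nd$replicate_values == 4L))
})

test_that("site-position permutation is uniform and respects eligibility", {
  reps <- permute_site_positions(10, 10, 5, seed = 2)
  expect_true(all(vapply(reps, identical, logical(1), 1:10)))
  reps <- permute_site_positions(10, 1, 20000, seed = 3)
  freq <- tabulate(unlist(reps), 10) / 20000
  expect_true(all(abs(freq - 0.1) < 3 * sqrt(0.1 * 0.9 / 20000)))
  reps <- permute_site_positions(50, 3, 50, seed = 4,
                                 eligible_positions = 11:20)
  expect_true(all(unlist(reps) %in% 11:20))
  expect_error(permute_site_positions(50, 11, 1, eligible_positions = 11:20),
               "cannot draw")
})

test_that("permutation-expected phase fractions hit degenerate limits", {
  # every junction phase 0: expected phase-0 fraction is 1 in every replicate
  genes <- list(gene_model("g1", c(9, 9, 9)), gene_model("g2", c(6, 12)))
  names(genes) <- c("g1", "g2")
  sites <- list(site_annotation("p1", "g1", "s1", "L", "amines", c(2, 5)),
                site_annotation("p2", "g2", "s2", "L", "amines", c(1, 4)))
  nd <- expected_phase_fractions(genes, sites, n_replicates = 30, seed = 6)
  expect_true(all(nd$replicate_values[, "phase0"] == 1))
  # single-exon sample: no junctions anywhere
  solo <- list(g1 = gene_model("g1", 9))
  s <- list(site_annotation("p", "g1", "s", "L", "amines", 1))
  expect_error(expected_phase_fractions(solo, s, 5, seed = 1), "no junctions")
})

test_that("phase fractions are reproducible and sum to one per replicate", {
  d <- make_toy_dataset(seed = 21)
  nd1 <- expected_phase_fractions(d$genes, d$sites, n_replicates = 40, seed = 8)
  nd2 <- expected_phase_fractions(d$genes, d$sites, n_replicates = 40, seed = 8)
  expect_identical(nd1$replicate_values, nd2$replicate_values)
  expect_equal(unname(rowSums(nd1$replicate_values)),
               rep(1, nrow(nd1$replicate_values)))
})
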