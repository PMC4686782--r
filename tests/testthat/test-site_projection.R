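mk_site <- function(gene_id, residues, site_id = "s1", category = "amines",
                    buffer = FALSE) {
  site_annotation("p", gene_id, site_id, "LIG", category, residues,
                  is_buffer_ligand = buffer)
}

test_that("EC/ENC labels mark exactly the exons coding site residues", {
  g <- gene_model("g", c(9, 9))
  ex <- classify_exons(g, list(mk_site("g", 1)))
  expect_equal(ex$label, c("EC", "ENC"))
  expect_true(all(ex$is_terminal))
  # a codon crossing the junction makes both exons EC
  g2 <- gene_model("g", c(4, 5))
  expect_equal(classify_exons(g2, list(mk_site("g", 2)))$label, c("EC", "EC"))
  # no sites: everything ENC
  expect_equal(classify_exons(g, list())$label, c("ENC", "ENC"))
})

test_that("EC/ENC labels form a partition and match a brute-force scan", {
  set.seed(202)
  for (i in 1:100) {
    len <- random_gene_lengths()
    g <- gene_model("g", len)
    n_res <- g$L %/% 3L
    residues <- sort(sample.int(n_res, min(n_res, sample.int(5L, 1L))))
    ex <- classify_exons(g, list(mk_site("g", residues)))
    expect_equal(ex$label, oracle_ec_labels(len, residues))
    expect_equal(sum(ex$label == "EC") + sum(ex$label == "ENC"), nrow(ex))
  }
})

test_that("sites with residues beyond the protein are skipped with a warning", {
  g <- gene_model("g", c(9, 9))
  expect_warning(ex <- classify_exons(g, list(mk_site("g", 99))), "skipped")
  expect_equal(ex$label, c("ENC", "ENC"))
  expect_error(classify_exons(g, list(mk_site("other", 1))), "different gene")
})

test_that("site area spans first to last residue on protein and CDS", {
  a <- build_site_area(mk_site("g", c(10, 45, 47)))
  expect_equal(c(a$first, a$last, a$nt_start, a$nt_end), c(10, 47, 28, 141))
  a <- build_site_area(mk_site("g", 5))
  expect_equal(c(a$first, a$last, a$nt_start, a$nt_end), c(5, 5, 13, 15))
  expect_equal(a$nt_end - a$nt_start + 1L, 3L * (a$last - a$first + 1L))
})

test_that("observed discontinuity counts borders inside the site area", {
  g <- gene_model("g", c(9, 9))
  pr <- observed_discontinuity(g, mk_site("g", c(1, 2)))
  expect_equal(pr$n_internal_borders_in_area, 0L)
  expect_equal(pr$n_exons_spanning_area, 1L)
  g2 <- gene_model("g", c(4, 5))
  pr <- observed_discontinuity(g2, mk_site("g", c(1, 3)))
  expect_equal(pr$n_internal_borders_in_area, 1L)
  expect_equal(pr$n_exons_spanning_area, 2L)
  expect_equal(pr$exon_indices, c(0L, 1L))
})

test_that("discontinuity equals junction enumeration on random instances", {
  set.seed(303)
  for (i in 1:100) {
    len <- random_gene_lengths()
    g <- gene_model("g", len)
    n_res <- g$L %/% 3L
    residues <- sort(sample.int(n_res, min(n_res, sample.int(4L, 1L))))
    pr <- observed_discontinuity(g, mk_site("g", residues))
    want <- oracle_borders_in_area(len, min(residues), max(residues))
    expect_equal(pr$n_internal_borders_in_area, want)
    expect_equal(pr$n_exons_spanning_area, want + 1L)
  }
})

test_that("adding a residue never shrinks the area or its border count", {
  set.seed(404)
  for (i in 1:50) {
    len <- random_gene_lengths()
    g <- gene_model("g", len)
    n_res <- g$L %/% 3L
    if (n_res < 3L) next
    residues <- sort(sample.int(n_res, min(n_res - 1L, 3L)))
    extra <- sample(setdiff(seq_len(n_res), residues), 1L)
    before <- observed_discontinuity(g, mk_site("g", residues))
    after <- observed_discontinuity(g, mk_site("g", c(residues, extra)))
    expect_gte(after$n_internal_borders_in_area,
               before$n_internal_borders_in_area)
    a1 <- build_site_area(mk_site("g", residues))
    a2 <- build_site_area(mk_site("g", c(residues, extra)))
    expect_gte(a1$nt_start, a2$nt_start)
    expect_lte(a1$nt_end, a2$nt_end)
  }
})

test_that("a single-residue site spans one or two exons when exons >= 3 nt", {
  set.seed(505)
  for (i in 1:50) {
    len <- 3L * sample(1:12, sample(1:6, 1L), replace = TRUE)
    g <- gene_model("g", len)
    r <- sample.int(g$L %/% 3L, 1L)
    pr <- observed_discontinuity(g, mk_site("g", r))
    expect_true(pr$n_exons_spanning_area %in% 1:2)
  }
})

test_that("buffer-ligand filtering drops exactly the listed categories", {
  sites <- list(mk_site("g", 1, "s1", "amines"),
                mk_site("g", 2, "s2", "buffer_crystallization", buffer = TRUE),
                mk_site("g", 3, "s3", "alcohols"))
  expect_identical(filter_buffer_ligands(sites, character(0)), sites)
  expect_message(
    kept <- filter_buffer_ligands(sites, "buffer_crystallization"),
    "1 site")
  expect_equal(vapply(kept, `[[`, character(1), "site_id"), c("s1", "s3"))
  expect_message(
    none <- filter_buffer_ligands(sites, c("amines", "alcohols",
                                           "buffer_crystallization")),
    "3 site")
  expect_length(none, 0L)
  expect_warning(filter_buffer_ligands(sites, "no_such_category"),
                 "not present")
})
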