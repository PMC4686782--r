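test_that("generated genes are in frame with controllable junction phases", {
  cfg <- generator_config(n_genes = 40, seed = 31,
                          phase3_probs = c(1, 0, 0))
  d <- generate_dataset(cfg)
  expect_length(d$genes, 40L)
  for (g in d$genes) {
    expect_false(g$incomplete)
    ph <- compute_phases(g)
    expect_true(all(ph$phase3 == 0L))  # every junction phase 0
  }
})

test_that("junction phase frequencies recover the configured distribution", {
  cfg <- generator_config(n_genes = 400, seed = 32,
                          phase3_probs = c(0.5, 0.3, 0.2))
  d <- generate_dataset(cfg)
  # internal junctions are the 3' phases of non-last exons
  j_phases <- unlist(lapply(d$genes, function(g) {
    p <- compute_phases(g)
    head(p$phase3, -1L)
  }))
  expect_gt(length(j_phases), 2000L)
  freq <- tabulate(j_phases + 1L, 3L) / length(j_phases)
  expect_true(all(abs(freq - c(0.5, 0.3, 0.2)) < 0.03))
})

test_that("realized exon-length median tracks the configured median", {
  cfg <- generator_config(n_genes = 200, seed = 33,
                          exon_length = list(median_nt = 120, sdlog = 0.6,
                                             min_nt = 9L))
  d <- generate_dataset(cfg)
  lens <- unlist(lapply(d$genes, `[[`, "exon_cds_lengths"))
  expect_gt(length(lens), 1000L)
  expect_lt(abs(median(lens) - 120) / 120, 0.10)
})

test_that("clustered placement confines sites to single exons when feasible", {
  cfg <- generator_config(n_genes = 50, seed = 34,
                          exon_length = list(median_nt = 150, sdlog = 0.3,
                                             min_nt = 90L),
                          site_placement = "clustered", cluster_window = 15L)
  d <- generate_dataset(cfg)
  spans <- project_sites(d$genes, d$sites)$n_exons_spanning
  expect_true(all(spans == 1L))
  expect_identical(d$truth$site_placement, "clustered")
})

test_that("uniform placement spreads residues over the whole protein", {
  cfg <- generator_config(n_genes = 100, seed = 35, site_placement = "uniform",
                          residues_per_site = list(lambda = 0, min = 1L))
  d <- generate_dataset(cfg)
  # pooled relative residue positions should cover (0,1] roughly uniformly
  rel <- unlist(lapply(d$sites, function(s) {
    s$residues / (d$genes[[s$gene_id]]$L / 3)
  }))
  expect_gt(length(rel), 300L)
  expect_lt(abs(mean(rel) - 0.5), 0.05)
  expect_gt(min(rel), 0)
  expect_lte(max(rel), 1)
})

test_that("same seed reproduces the dataset byte for byte on disk", {
  d1 <- make_toy_dataset(seed = 36)
  d2 <- make_toy_dataset(seed = 36)
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  write_dataset(d1, t1, fasta = TRUE)
  write_dataset(d2, t2, fasta = TRUE)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)),
                     info = f)
  }
})

test_that("write then read reproduces gene structures and sites exactly", {
  d <- make_toy_dataset(seed = 37)
  out <- withr::local_tempdir()
  write_dataset(d, out)
  genes2 <- read_gene_models(file.path(out, "genes.gtf"))
  expect_setequal(names(genes2), names(d$genes))
  for (gid in names(d$genes)) {
    expect_equal(genes2[[gid]]$exon_cds_lengths, d$genes[[gid]]$exon_cds_lengths)
    expect_equal(genes2[[gid]]$species, d$genes[[gid]]$species)
    gi1 <- d$genes[[gid]]$genomic_intervals
    gi2 <- genes2[[gid]]$genomic_intervals
    rownames(gi1) <- rownames(gi2) <- NULL
    expect_equal(gi2, gi1)
  }
  sites2 <- read_sites(file.path(out, "sites.tsv"), genes = genes2)
  expect_length(sites2, length(d$sites))
  for (i in seq_along(d$sites)) {
    expect_equal(unclass(sites2[[i]]), unclass(d$sites[[i]]))
  }
})

test_that("generated GTF passes an independent line-level format check", {
  d <- make_toy_dataset(seed = 38, n_genes = 5)
  out <- withr::local_tempdir()
  write_dataset(d, out)
  lines <- readLines(file.path(out, "genes.gtf"))
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  expect_true(all(lengths(fields) == 9L))
  for (f in fields) {
    expect_equal(f[3], "CDS")
    expect_false(is.na(suppressWarnings(as.integer(f[4]))))
    expect_lte(as.integer(f[4]), as.integer(f[5]))
    expect_true(f[7] %in% c("+", "-"))
    expect_true(f[8] %in% c("0", "1", "2"))
    expect_match(f[9], 'gene_id "[^"]+"; transcript_id "[^"]+"')
  }
})

test_that("degenerate generator configurations are rejected", {
  expect_error(generator_config(n_genes = 0), "n_genes")
  expect_error(generator_config(site_placement = "clustered",
                                cluster_window = 1L,
                                residues_per_site = list(lambda = 1, min = 4L)),
               "cluster_window")
  expect_error(write_dataset(list(genes = list()), withr::local_tempdir()))
})
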