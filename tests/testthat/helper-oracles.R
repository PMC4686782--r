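# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's arithmetic: everything is computed by walking
# nucleotides one at a time or by exhaustive enumeration.

# Walk the CDS nucleotide by nucleotide, tracking the codon offset (1, 2, 3),
# and record at each exon end how many nucleotides of the current codon have
# been emitted. That count IS the 3' phase; the 5' phase is the state when the
# exon starts.
oracle_phases <- function(lengths) {
  ends <- cumsum(lengths)
  phase5 <- integer(length(lengths))
  phase3 <- integer(length(lengths))
  in_codon <- 0L  # nucleotides of the current codon already emitted
  e <- 1L
  phase5[1L] <- 0L
  for (nt in seq_len(sum(lengths))) {
    in_codon <- in_codon + 1L
    if (in_codon == 3L) in_codon <- 0L
    if (nt == ends[e]) {
      phase3[e] <- in_codon
      if (e < length(lengths)) phase5[e + 1L] <- in_codon
      e <- e + 1L
    }
  }
  data.frame(exon_index = seq_along(lengths) - 1L,
             phase5 = phase5, phase3 = phase3,
             symmetric = phase5 == phase3)
}

# Which exon owns each CDS nucleotide; residue -> exons by direct lookup.
oracle_exon_of_nt <- function(lengths) rep(seq_along(lengths) - 1L, lengths)

oracle_residue_exons <- function(lengths, r) {
  sort(unique(oracle_exon_of_nt(lengths)[(3L * r - 2L):(3L * r)]))
}

# EC labels by scanning every residue codon against every exon nucleotide.
oracle_ec_labels <- function(lengths, residues) {
  owner <- oracle_exon_of_nt(lengths)
  ec <- rep(FALSE, length(lengths))
  for (r in residues) {
    for (e in unique(owner[(3L * r - 2L):(3L * r)])) ec[e + 1L] <- TRUE
  }
  ifelse(ec, "EC", "ENC")
}

# Borders inside the site area by enumerating junction slots one by one.
oracle_borders_in_area <- function(lengths, first, last) {
  junctions <- cumsum(lengths)[-length(lengths)]
  n <- 0L
  for (k in seq_len(sum(lengths) - 1L)) {
    if (k %in% junctions && k >= 3L * first - 2L && k <= 3L * last - 1L) {
      n <- n + 1L
    }
  }
  n
}

# Random in-frame gene: small exons (1 nt allowed) so codons can span several
# junctions; last exon padded into frame.
random_gene_lengths <- function(max_exons = 8L, max_len = 30L) {
  n <- sample.int(max_exons, 1L)
  len <- sample.int(max_len, n, replace = TRUE)
  len[n] <- len[n] + (3L - sum(len) %% 3L) %% 3L
  if (len[n] == 0L) len[n] <- 3L
  len
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (tie-free inputs only). Mirrors the
# convention: lower tail doubled below the mean, upper tail doubled above.
enumerate_mw_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(idx, 2L, function(i) u_of(pool[i], pool[-i]))
  u_obs <- u_of(a, b)
  mu <- n1 * length(b) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
enumerate_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1L, function(s) sum(r[s]))
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(vs >= v_obs) else 2 * mean(vs <= v_obs)
  min(1, p)
}

# Tiny deterministic dataset used by several I/O and pipeline tests.
make_toy_dataset <- function(seed = 11L, n_genes = 12L,
                             placement = "uniform") {
  generate_dataset(generator_config(
    n_genes = n_genes, seed = seed,
    exon_count = list(lambda = 3, min = 2L),
    exon_length = list(median_nt = 60, sdlog = 0.4, min_nt = 9L),
    sites_per_gene = list(lambda = 1, min = 1L),
    residues_per_site = list(lambda = 2, min = 2L),
    site_placement = placement, cluster_window = 10L))
}
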