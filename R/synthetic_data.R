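#' Default ligand category nomenclature for simulated sites
#'
#' A compact stand-in for a ligand chemical nomenclature: category labels with
#' sampling probabilities and a flag marking categories that typically enter
#' crystal structures through buffering or crystallization rather than
#' biological binding.
#'
#' @return A `data.frame` with columns `label`, `probability`, `is_buffer`.
#' @export
default_ligand_categories <- function() {
  data.frame(
    label = c("amines", "alcohols", "organic_acid_derivatives",
              "complex_organic_compounds", "carbohydrates", "nucleotides",
              "buffer_crystallization"),
    probability = c(0.15, 0.12, 0.18, 0.25, 0.08, 0.12, 0.10),
    is_buffer = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Configuration for the synthetic gene/site generator
#'
#' Defines the statistical structure of a simulated dataset of multi-exon
#' coding genes and ligand-binding-site annotations. Defaults describe a
#' vertebrate-like sample: about 9 coding exons per gene (shifted Poisson,
#' minimum 2), log-normal exon lengths with a median of 120 nt, internal
#' junction 3'-phases distributed roughly (0.47, 0.30, 0.23) as in vertebrate
#' genomes, several sites per protein and a handful of residues per site.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exon_count List `(lambda, min)`: exon count per gene is
#'   `min + Poisson(lambda)`.
#' @param exon_length Either `list(kind = "lognormal", median_nt, sdlog,
#'   min_nt)` (the default; raw exon lengths log-normal with
#'   `meanlog = log(median_nt)`, floored at `min_nt`) or
#'   `list(kind = "uniform_junctions", mean_nt)`, which draws the gene's
#'   junction slots uniformly without replacement over the CDS — the exact
#'   placement model of the boundary-resampling null, used for calibration
#'   studies (phase3_probs has no effect in this mode).
#' @param phase3_probs Probabilities `(p0, p1, p2)` for the 3'-phase of each
#'   internal junction; must sum to 1.
#' @param sites_per_gene List `(lambda, min)`: shifted Poisson.
#' @param residues_per_site List `(lambda, min)`: shifted Poisson.
#' @param site_placement `"uniform"` (residues uniform without replacement
#'   over the protein) or `"clustered"` (residues drawn within a short window
#'   lying inside one exon when possible).
#' @param cluster_window Window width in residues for clustered placement.
#' @param ligand_categories `data.frame` as in [default_ligand_categories()].
#' @param seed Integer master seed; per-gene streams are derived from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 1000L,
                             exon_count = list(lambda = 7, min = 2L),
                             exon_length = list(kind = "lognormal",
                                                median_nt = 120, sdlog = 0.6,
                                                min_nt = 9L),
                             phase3_probs = c(0.47, 0.30, 0.23),
                             sites_per_gene = list(lambda = 5, min = 1L),
                             residues_per_site = list(lambda = 3, min = 2L),
                             site_placement = c("clustered", "uniform"),
                             cluster_window = 20L,
                             ligand_categories = default_ligand_categories(),
                             seed = 1L) {
  site_placement <- match.arg(site_placement)
  if (is.null(exon_length$kind)) exon_length$kind <- "lognormal"
  stopifnot(n_genes >= 1L,
            abs(sum(phase3_probs) - 1) < 1e-8, length(phase3_probs) == 3L,
            all(phase3_probs >= 0),
            abs(sum(ligand_categories$probability) - 1) < 1e-8,
            exon_count$min >= 2L,
            exon_length$kind %in% c("lognormal", "uniform_junctions"),
            sites_per_gene$min >= 1L, residues_per_site$min >= 1L,
            cluster_window >= 1L)
  if (exon_length$kind == "lognormal") stopifnot(exon_length$min_nt >= 1L)
  else stopifnot(exon_length$mean_nt >= 3)
  if (site_placement == "clustered" &&
      cluster_window < residues_per_site$min) {
    stop("cluster_window smaller than the minimum residues per site")
  }
  structure(
    list(n_genes = as.integer(n_genes), exon_count = exon_count,
         exon_length = exon_length, phase3_probs = phase3_probs,
         sites_per_gene = sites_per_gene,
         residues_per_site = residues_per_site,
         site_placement = site_placement,
         cluster_window = as.integer(cluster_window),
         ligand_categories = ligand_categories,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

rshifted_pois <- function(n, spec) spec$min + stats::rpois(n, spec$lambda)

# Draw one gene. Default ("lognormal"): raw log-normal exon lengths, then a
# 0-2 nt addition to each internal exon so its junction's 3'-phase follows
# phase3_probs, then a 0-2 nt pad on the final exon to close the reading
# frame; the <=2 nt adjustments leave the length distribution essentially
# untouched. Alternative ("uniform_junctions"): junction slots drawn uniformly
# without replacement over the CDS, exactly matching the boundary-resampling
# null's placement assumption (phase3_probs does not apply); used to validate
# the null machinery under its own model.
generate_gene <- function(config, gid) {
  n_ex <- rshifted_pois(1L, config$exon_count)
  el <- config$exon_length
  if (identical(el$kind, "uniform_junctions")) {
    L <- max(3L * n_ex, as.integer(round(n_ex * el$mean_nt / 3)) * 3L)
    ks <- if (n_ex > 1L) sort(sample.int(L - 1L, n_ex - 1L)) else integer(0)
    return(as.integer(diff(c(0L, ks, L))))
  }
  len <- pmax(el$min_nt,
              as.integer(round(stats::rlnorm(n_ex, log(el$median_nt), el$sdlog))))
  if (n_ex > 1L) {
    target <- sample.int(3L, n_ex - 1L, replace = TRUE,
                         prob = config$phase3_probs) - 1L
    for (i in seq_len(n_ex - 1L)) {
      cum <- sum(len[seq_len(i)])
      len[i] <- len[i] + (target[i] - cum) %% 3L
    }
  }
  L <- sum(len)
  len[n_ex] <- len[n_ex] + (3L - L %% 3L) %% 3L
  len
}

# Clustered placement: a window of cluster_window residues inside one exon
# when some exon is wide enough, else anywhere on the protein; residues are
# then drawn without replacement within the window.
place_site_residues <- function(config, gene, n_res) {
  P <- gene$L %/% 3L
  n_res <- min(n_res, P)
  if (config$site_placement == "uniform") {
    return(sort(sample.int(P, n_res)))
  }
  w <- max(config$cluster_window, n_res)
  iv <- exon_cds_intervals(gene)
  # residues whose whole codon lies inside exon e: ceil((start+2)/3) .. floor(end/3)
  res_lo <- ceiling((iv$cds_start + 2L) / 3)
  res_hi <- floor(iv$cds_end / 3)
  fits <- which(res_hi - res_lo + 1L >= w)
  if (length(fits) > 0L) {
    e <- fits[sample.int(length(fits), 1L)]
    start <- res_lo[e] + sample.int(res_hi[e] - res_lo[e] + 1L - w + 1L, 1L) - 1L
  } else {
    if (w > P) w <- P
    start <- sample.int(P - w + 1L, 1L)
  }
  sort(start - 1L + sample.int(w, n_res))
}

#' Generate a synthetic dataset of genes and functional sites
#'
#' Draws gene structures and site annotations according to a
#' [generator_config()]. Each gene's random stream is derived from the master
#' seed and the gene id, so regeneration of any subset reproduces the full
#' run. The returned `truth` records the generating parameters for
#' parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return A list with `genes` (list of [gene_model]), `sites` (list of
#'   [site_annotation]) and `truth` (list: placement mode and config echo).
#' @examples
#' d <- generate_dataset(generator_config(n_genes = 3, seed = 42))
#' length(d$genes); length(d$sites)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  genes <- vector("list", config$n_genes)
  sites <- list()
  cat_df <- config$ligand_categories
  intron_len <- 200L
  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("gene%05d", i)
    genes[[i]] <- with_seed(derive_seed(config$seed, gid), {
      len <- generate_gene(config, gid)
      strand <- sample(c("+", "-"), 1L)
      # genomic layout on one synthetic chromosome, fixed-length introns;
      # on the minus strand transcription order runs right-to-left, so the
      # genomic widths are laid out reversed before flipping back
      glen <- if (strand == "-") rev(len) else len
      gstarts <- cumsum(c((i - 1L) * 100000L + 1L,
                          head(glen, -1L) + intron_len))
      gi <- data.frame(chrom = "chrS1", start = as.integer(gstarts),
                       end = as.integer(gstarts + glen - 1L), strand = strand)
      if (strand == "-") {
        gi <- gi[rev(seq_len(nrow(gi))), ]
        rownames(gi) <- NULL
      }
      g <- gene_model(gid, len, species = "synthetic", genomic_intervals = gi)
      n_sites <- rshifted_pois(1L, config$sites_per_gene)
      gsites <- lapply(seq_len(n_sites), function(s) {
        n_res <- rshifted_pois(1L, config$residues_per_site)
        cat_i <- sample.int(nrow(cat_df), 1L, prob = cat_df$probability)
        site_annotation(
          protein_id = paste0("prot", substring(gid, 5L)),
          gene_id = gid,
          site_id = sprintf("%s_site%02d", gid, s),
          ligand_id = sprintf("LIG_%s_%02d", cat_df$label[cat_i], s),
          ligand_category = cat_df$label[cat_i],
          residues = place_site_residues(config, g, n_res),
          is_buffer_ligand = cat_df$is_buffer[cat_i])
      })
      list(gene = g, sites = gsites)
    })
    sites <- c(sites, genes[[i]]$sites)
    genes[[i]] <- genes[[i]]$gene
  }
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  list(genes = genes, sites = sites,
       truth = list(site_placement = config$site_placement,
                    cluster_window = config$cluster_window,
                    phase3_probs = config$phase3_probs,
                    exon_length_median_nt = config$exon_length$median_nt,
                    seed = config$seed))
}

#' Write a dataset to standard file formats
#'
#' Emits `genes.gtf` (CDS features), `sites.tsv`, `protein_gene_map.tsv` and
#' `truth.json`; optionally `proteins.fasta` with poly-X sequences of the
#' correct lengths (no analysis consumes amino-acid identities). Re-reading
#' with [read_gene_models()] / [read_sites()] reproduces the in-memory
#' objects.
#'
#' @param dataset A list as returned by [generate_dataset()] (fields `genes`,
#'   `sites`, optional `truth`).
#' @param out_dir Output directory (created if needed).
#' @param fasta Also write poly-X protein FASTA (default `FALSE`).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(dataset, out_dir, fasta = FALSE) {
  stopifnot(length(dataset$genes) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(out_dir, "genes.gtf"),
             sites = file.path(out_dir, "sites.tsv"),
             map = file.path(out_dir, "protein_gene_map.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_gene_models_gtf(dataset$genes, paths[["genes"]])
  write_sites(dataset$sites, paths[["sites"]])
  map <- unique(data.frame(
    protein_id = vapply(dataset$sites, `[[`, character(1), "protein_id"),
    gene_id = vapply(dataset$sites, `[[`, character(1), "gene_id")))
  utils::write.table(map, paths[["map"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(dataset$truth %||% list(), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (fasta) {
    paths <- c(paths, fasta = file.path(out_dir, "proteins.fasta"))
    con <- file(paths[["fasta"]], "w")
    on.exit(close(con))
    for (g in dataset$genes) {
      writeLines(c(paste0(">prot", substring(g$gene_id, 5L)),
                   strrep("X", g$L %/% 3L)), con)
    }
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
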