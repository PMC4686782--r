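#' Randomized exon-boundary placement
#'
#' Null model for site discontinuity: each replicate redraws the gene's real
#' number of exon borders uniformly, without replacement, over the CDS junction
#' slots `1 .. L-1` (the positions between consecutive coding nucleotides).
#' Intron genomic lengths play no role — the counted statistic lives entirely
#' in CDS coordinates.
#'
#' @param L Total CDS length (nt).
#' @param m Number of junctions to place (`0 <= m <= L - 1`).
#' @param n_replicates Number of replicates (default 10).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param min_exon_len Optional minimum fragment length enforced between
#'   consecutive junctions (and the CDS ends); `NULL` (default) places
#'   junctions freely.
#' @return A list of `n_replicates` sorted integer vectors of junction slots.
#' @export
resample_boundaries <- function(L, m, n_replicates = 10L, seed = NULL,
                                min_exon_len = NULL) {
  L <- as.integer(L); m <- as.integer(m)
  stopifnot(L >= 1L, n_replicates >= 1L)
  if (m < 0L || m > L - 1L) {
    stop("cannot place ", m, " junctions in ", L - 1L, " slots")
  }
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      if (m == 0L) return(integer(0))
      if (is.null(min_exon_len) || min_exon_len <= 1L) {
        return(sort(sample.int(L - 1L, m)))
      }
      # rejection sampling under a minimum-fragment constraint
      g <- as.integer(min_exon_len)
      if ((m + 1L) * g > L) stop("min_exon_len infeasible for L and m")
      repeat {
        ks <- sort(sample.int(L - 1L, m))
        frag <- diff(c(0L, ks, L))
        if (all(frag >= g)) return(ks)
      }
    })
  })
}

#' Null distribution of exon borders inside a site area
#'
#' Applies [resample_boundaries()] and counts, per replicate, how many
#' resampled junctions fall inside the site area (slots
#' `nt_start .. nt_end - 1`). The replicate mean converges to the
#' hypergeometric expectation `m * s / (L - 1)` where `s` is the number of
#' slots in the area.
#'
#' @param site_area A site area as returned by [build_site_area()] (list with
#'   `nt_start`, `nt_end`).
#' @param L CDS length (nt).
#' @param m Real junction count of the gene.
#' @param n_replicates,seed,min_exon_len Passed to [resample_boundaries()].
#' @return An object of class `null_distribution`: list with
#'   `replicate_values` (integer counts), `n_replicates`, `seed`,
#'   `statistic_name = "borders_in_area"`.
#' @export
expected_borders_in_area <- function(site_area, L, m, n_replicates = 10L,
                                     seed = NULL, min_exon_len = NULL) {
  stopifnot(site_area$nt_start >= 1L, site_area$nt_end <= L,
            site_area$nt_start <= site_area$nt_end)
  reps <- resample_boundaries(L, m, n_replicates, seed, min_exon_len)
  counts <- vapply(reps, function(ks) {
    sum(ks >= site_area$nt_start & ks <= site_area$nt_end - 1L)
  }, integer(1))
  structure(
    list(replicate_values = counts,
         n_replicates = as.integer(n_replicates),
         seed = seed,
         statistic_name = "borders_in_area"),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution '%s': %d replicates, mean %.4g>\n",
              x$statistic_name, x$n_replicates, mean(x$replicate_values)))
  invisible(x)
}

#' Random transposition of site residue positions
#'
#' Null model for the phase analyses: each replicate redraws the site's number
#' of residues uniformly, without replacement, from the eligible protein
#' positions (all positions by default).
#'
#' @param protein_length Protein length in residues.
#' @param n_residues Number of residues per replicate.
#' @param n_replicates Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @param eligible_positions Optional integer vector of allowed positions
#'   (e.g. to exclude residues coded by terminal exons).
#' @return A list of `n_replicates` sorted integer vectors.
#' @export
permute_site_positions <- function(protein_length, n_residues,
                                   n_replicates = 1000L, seed = NULL,
                                   eligible_positions = NULL) {
  if (is.null(eligible_positions)) {
    eligible_positions <- seq_len(protein_length)
  } else {
    eligible_positions <- as.integer(eligible_positions)
    stopifnot(all(eligible_positions >= 1L),
              all(eligible_positions <= protein_length))
  }
  if (n_residues > length(eligible_positions)) {
    stop("cannot draw ", n_residues, " residues from ",
         length(eligible_positions), " eligible positions")
  }
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      sort(eligible_positions[sample.int(length(eligible_positions), n_residues)])
    })
  })
}

# Per-residue boundary-phase incidence matrix of one gene: row r gives how
# many phase-0/1/2 events a site residue at position r would generate. A
# phase-0 junction flanks two codons, so it contributes to two rows.
phase_event_matrix <- function(gene) {
  check_complete(gene)
  P <- gene$L %/% 3L
  M <- matrix(0L, nrow = P, ncol = 3L,
              dimnames = list(NULL, c("phase0", "phase1", "phase2")))
  for (k in internal_junctions(gene)) {
    r <- k %% 3L
    if (r == 0L) {
      i <- k %/% 3L
      if (i >= 1L && i <= P) M[i, 1L] <- M[i, 1L] + 1L        # 3' flank
      if (i + 1L <= P) M[i + 1L, 1L] <- M[i + 1L, 1L] + 1L    # 5' flank
    } else if (r == 1L) {
      M[(k + 2L) %/% 3L, 2L] <- M[(k + 2L) %/% 3L, 2L] + 1L   # split, phase 1
    } else {
      M[(k + 1L) %/% 3L, 3L] <- M[(k + 1L) %/% 3L, 3L] + 1L   # split, phase 2
    }
  }
  M
}

#' Expected boundary-phase fractions under site transposition
#'
#' For each replicate, every site's residues are re-placed uniformly at random
#' on its protein ([permute_site_positions()]), boundary-phase events are
#' collected over all permuted site codons across the whole sample, and the
#' fraction of events in each phase (0, 1, 2) is recorded. Replicates with no
#' events are dropped (with a message).
#'
#' @param genes List of complete [gene_model]s, named or identified by
#'   `gene_id`.
#' @param sites List of [site_annotation]s referencing those genes.
#' @param n_replicates Number of permutation replicates (default 1000).
#' @param seed Integer seed; per-gene streams are derived from it so the
#'   result does not depend on gene processing order.
#' @param eligible Optional function `(gene) -> integer vector` of eligible
#'   residue positions (default: all).
#' @return A list of class `null_distribution` with `replicate_values` a
#'   3-column matrix of phase fractions (rows = kept replicates), plus
#'   `replicate_counts` (event counts per phase per replicate),
#'   `n_replicates`, `seed`, `statistic_name = "phase_fractions"`.
#' @export
expected_phase_fractions <- function(genes, sites, n_replicates = 1000L,
                                     seed = NULL, eligible = NULL) {
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  names(genes) <- gene_ids
  if (!any(vapply(genes, function(g) length(internal_junctions(g)) > 0L,
                  logical(1)))) {
    stop("no junctions: every gene in the sample is single-exon")
  }
  counts <- matrix(0, nrow = n_replicates, ncol = 3L,
                   dimnames = list(NULL, c("phase0", "phase1", "phase2")))
  for (gid in unique(vapply(sites, `[[`, character(1), "gene_id"))) {
    gene <- genes[[gid]]
    if (is.null(gene)) stop("site references unknown gene '", gid, "'")
    gsites <- Filter(function(s) identical(s$gene_id, gid), sites)
    gsites <- validate_sites(gene, gsites)
    if (length(gsites) == 0L) next
    M <- phase_event_matrix(gene)
    P <- nrow(M)
    elig <- if (is.null(eligible)) seq_len(P) else as.integer(eligible(gene))
    ne <- length(elig)
    for (s in gsites) {
      n <- length(s$residues)
      if (n > ne) {
        stop("site '", s$site_id, "': more residues than eligible positions")
      }
      # one uniform without-replacement draw per replicate, accumulated in bulk
      idx <- with_seed(
        if (is.null(seed)) NULL else derive_seed(seed, paste0(gid, "/", s$site_id)),
        vapply(seq_len(n_replicates),
               function(j) elig[sample.int(ne, n)], integer(n)))
      dim(idx) <- c(n, n_replicates)
      for (p in 1:3) {
        counts[, p] <- counts[, p] +
          .colSums(matrix(M[, p][idx], n, n_replicates), n, n_replicates)
      }
    }
  }
  tot <- rowSums(counts)
  keep <- tot > 0
  if (any(!keep)) {
    message(sum(!keep), " replicate(s) with zero boundary-phase events dropped")
  }
  if (!any(keep)) stop("no boundary-phase events in any replicate")
  structure(
    list(replicate_values = counts[keep, , drop = FALSE] / tot[keep],
         replicate_counts = counts[keep, , drop = FALSE],
         n_replicates = as.integer(sum(keep)),
         seed = seed,
         statistic_name = "phase_fractions"),
    class = "null_distribution"
  )
}
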