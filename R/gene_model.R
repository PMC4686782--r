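#' Construct a coding gene model
#'
#' A `gene_model` holds the ordered coding-exon structure of one gene: the CDS
#' length of each exon in transcription (5' to 3') order, plus optional genomic
#' intervals used only for file round-trips. All coordinate arithmetic
#' downstream (codon spans, exon phases, site projection) is done on the
#' concatenated CDS in 1-based inclusive nucleotide coordinates.
#'
#' A CDS whose total length is not a multiple of 3 cannot be translated in
#' frame; such models are flagged `incomplete` and rejected by every analysis
#' function rather than silently truncated.
#'
#' @param gene_id Character scalar identifying the gene.
#' @param exon_cds_lengths Integer vector of per-exon coding lengths (nt),
#'   5' to 3'. All must be >= 1.
#' @param species Optional species label, carried through to reports.
#' @param genomic_intervals Optional `data.frame` with columns `chrom`,
#'   `start`, `end`, `strand`, one row per exon in transcription order,
#'   1-based inclusive. Used only by the GTF/BED12 writers.
#' @return An object of class `gene_model` with fields `gene_id`, `species`,
#'   `exon_cds_lengths`, `genomic_intervals`, `L` (total CDS length) and
#'   `incomplete` (`TRUE` when `L %% 3 != 0`).
#' @examples
#' g <- gene_model("g1", c(100, 50))
#' g$L
#' compute_phases(g)
#' @export
gene_model <- function(gene_id, exon_cds_lengths, species = NA_character_,
                       genomic_intervals = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  gene_id <- unname(gene_id)
  exon_cds_lengths <- unname(as.integer(exon_cds_lengths))
  if (length(exon_cds_lengths) == 0L) {
    stop("gene '", gene_id, "': exon list is empty")
  }
  if (anyNA(exon_cds_lengths) || any(exon_cds_lengths < 1L)) {
    stop("gene '", gene_id, "': every exon CDS length must be a positive integer")
  }
  if (!is.null(genomic_intervals)) {
    stopifnot(is.data.frame(genomic_intervals),
              all(c("chrom", "start", "end", "strand") %in% names(genomic_intervals)))
    if (nrow(genomic_intervals) != length(exon_cds_lengths)) {
      stop("gene '", gene_id, "': genomic_intervals rows must match exon count")
    }
    widths <- genomic_intervals$end - genomic_intervals$start + 1L
    if (!all(widths == exon_cds_lengths)) {
      stop("gene '", gene_id, "': genomic interval widths disagree with CDS lengths")
    }
  }
  L <- sum(exon_cds_lengths)
  structure(
    list(gene_id = gene_id,
         species = species,
         exon_cds_lengths = exon_cds_lengths,
         genomic_intervals = genomic_intervals,
         L = L,
         incomplete = (L %% 3L != 0L)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s: %d exon(s), CDS %d nt%s>\n",
              x$gene_id, length(x$exon_cds_lengths), x$L,
              if (x$incomplete) ", INCOMPLETE (L %% 3 != 0)" else ""))
  invisible(x)
}

# Stop unless the model is a usable, in-frame CDS.
check_complete <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (gene$incomplete) {
    stop("gene '", gene$gene_id, "' has incomplete CDS (L = ", gene$L,
         " not divisible by 3) and is excluded from analyses")
  }
  invisible(gene)
}

#' Per-exon CDS intervals
#'
#' 1-based inclusive start/end of each exon on the concatenated CDS.
#'
#' @param gene A [gene_model].
#' @return A `data.frame` with columns `exon_index` (0-based), `cds_start`,
#'   `cds_end`, `cds_length`.
#' @export
exon_cds_intervals <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ends <- cumsum(gene$exon_cds_lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(exon_index = seq_along(ends) - 1L,
             cds_start = starts, cds_end = as.integer(ends),
             cds_length = gene$exon_cds_lengths)
}

#' Internal junction positions of a gene
#'
#' A junction slot `k` denotes the intron falling between CDS nucleotides `k`
#' and `k + 1`. Real junctions sit at the 3' end of every exon except the last.
#'
#' @param gene A [gene_model].
#' @return Integer vector of junction slots (possibly empty).
#' @export
internal_junctions <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ends <- cumsum(gene$exon_cds_lengths)
  as.integer(head(ends, -1L))
}

#' Compute 5' and 3' phases of every exon
#'
#' The phase of an intron records where it breaks the reading frame: 0 when it
#' falls between codons, 1 when one nucleotide of the codon precedes it, 2 when
#' two do. Each exon therefore carries a 5' phase (of the upstream intron; 0
#' for the first exon) and a 3' phase (of the downstream intron; 0 after the
#' terminal codon). An exon whose two phases are equal is symmetric, the
#' classical precondition for clean exon shuffling.
#'
#' @param gene A complete [gene_model] (`L` divisible by 3).
#' @return A `data.frame` with columns `exon_index` (0-based), `phase5`,
#'   `phase3`, `symmetric`.
#' @examples
#' compute_phases(gene_model("g", c(4, 5, 3)))
#' @export
compute_phases <- function(gene) {
  check_complete(gene)
  ends <- cumsum(gene$exon_cds_lengths)
  phase3 <- as.integer(ends %% 3L)
  phase5 <- c(0L, head(phase3, -1L))
  data.frame(exon_index = seq_along(ends) - 1L,
             phase5 = phase5, phase3 = phase3,
             symmetric = phase5 == phase3)
}

#' Codon span of a protein residue on the CDS
#'
#' Residue `i` (1-based) is encoded by CDS nucleotides `3i - 2 .. 3i`.
#'
#' @param gene A complete [gene_model].
#' @param residue_index 1-based residue position.
#' @return A list with `residue_index`, `nt_start`, `nt_end`.
#' @export
codon_span <- function(gene, residue_index) {
  check_complete(gene)
  residue_index <- as.integer(residue_index)
  stopifnot(length(residue_index) == 1L)
  n_res <- gene$L %/% 3L
  if (is.na(residue_index) || residue_index < 1L || residue_index > n_res) {
    stop("residue ", residue_index, " outside CDS of gene '", gene$gene_id,
         "' (protein length ", n_res, ")")
  }
  list(residue_index = residue_index,
       nt_start = 3L * residue_index - 2L,
       nt_end = 3L * residue_index)
}

#' Exons encoding a given protein residue
#'
#' Returns the (0-based) indices of every exon whose CDS interval intersects
#' the residue's codon span. Most codons lie inside one exon; a codon split by
#' an intron maps to two (or, with exons shorter than 3 nt, more).
#'
#' @param gene A complete [gene_model].
#' @param residue_index 1-based residue position.
#' @return Sorted integer vector of 0-based exon indices (length >= 1).
#' @examples
#' residue_to_exons(gene_model("g", c(4, 5)), 2)  # codon 2 spans the junction
#' @export
residue_to_exons <- function(gene, residue_index) {
  cs <- codon_span(gene, residue_index)
  iv <- exon_cds_intervals(gene)
  iv$exon_index[iv$cds_start <= cs$nt_end & iv$cds_end >= cs$nt_start]
}

#' Junction phases touching a residue's codon
#'
#' For residue `i` (codon nucleotides `3i-2 .. 3i`) every internal junction
#' `k` with `3i - 3 <= k <= 3i` is reported: `k = 3i - 3` is a phase-0 intron
#' immediately 5' of the codon, `k = 3i - 2` and `k = 3i - 1` split the codon
#' in phases 1 and 2, and `k = 3i` is a phase-0 intron immediately 3' of it.
#' An empty result means the codon is interior to one exon and not adjacent to
#' any junction. Phase-0 adjacency is counted per residue, so one junction can
#' be reported for both residues flanking it.
#'
#' @param gene A complete [gene_model].
#' @param residue_index 1-based residue position.
#' @return A `data.frame` with columns `junction` (CDS slot `k`), `phase`
#'   (0/1/2) and `side` (`"5prime"`, `"split"`, `"3prime"`); zero rows when the
#'   codon touches no junction.
#' @export
boundary_phase_of_site_codon <- function(gene, residue_index) {
  cs <- codon_span(gene, residue_index)
  ks <- (3L * cs$residue_index - 3L):(3L * cs$residue_index)
  hit <- ks[ks %in% internal_junctions(gene)]
  off <- hit - (3L * cs$residue_index - 3L)  # 0..3 within the candidate window
  data.frame(junction = hit,
             phase = as.integer(off %% 3L),
             side = c("5prime", "split", "split", "3prime")[off + 1L])
}
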