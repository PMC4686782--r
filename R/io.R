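#' Read gene models from GTF or BED12
#'
#' GTF: `CDS` features grouped by `transcript_id` (Ensembl-style attributes),
#' 1-based inclusive coordinates. BED12: one record per transcript; the blocks
#' are taken as the CDS intervals (0-based half-open on disk, converted on
#' read). Minus-strand transcripts are reordered into transcription direction,
#' so downstream logic never sees strand. When a gene has several transcripts
#' (GTF only), the one with the longest CDS is kept by default.
#'
#' Transcripts whose total CDS length is not a multiple of 3 are excluded with
#' a warning; their ids are attached as `attr(result, "excluded")`.
#'
#' @param path File path.
#' @param format `"gtf"` or `"bed12"` (default guessed from the extension).
#' @param multi_isoform `"longest"` (default) or `"error"`.
#' @return Named list of [gene_model] objects.
#' @export
read_gene_models <- function(path, format = NULL,
                             multi_isoform = c("longest", "error")) {
  multi_isoform <- match.arg(multi_isoform)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  format <- match.arg(tolower(format), c("gtf", "bed12"))
  if (format == "gtf") read_gene_models_gtf(path, multi_isoform)
  else read_gene_models_bed12(path)
}

finish_gene_set <- function(models) {
  complete <- !vapply(models, `[[`, logical(1), "incomplete")
  if (any(!complete)) {
    warning(sum(!complete), " transcript(s) with CDS length not divisible by 3 ",
            "excluded: ", paste(names(models)[!complete], collapse = ", "),
            call. = FALSE)
  }
  res <- models[complete]
  attr(res, "excluded") <- names(models)[!complete]
  res
}

read_gene_models_gtf <- function(path, multi_isoform = "longest") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  tx <- gr$transcript_id
  if (is.null(tx)) stop("GTF lacks transcript_id attributes: ", path)
  parts <- split(gr, tx)
  gene_of <- vapply(parts, function(p) {
    gid <- unique(p$gene_id)
    if (length(gid) != 1L || is.na(gid[1])) names(parts)[1] else gid
  }, character(1))
  # isoform choice: keep one transcript per gene
  cds_len <- vapply(parts, function(p) sum(GenomicRanges::width(p)), numeric(1))
  keep <- unlist(lapply(split(seq_along(parts), gene_of), function(idx) {
    if (length(idx) > 1L && multi_isoform == "error") {
      stop("gene '", gene_of[idx[1]], "' has multiple transcripts")
    }
    idx[which.max(cds_len[idx])]
  }), use.names = FALSE)
  models <- lapply(keep, function(i) {
    p <- parts[[i]]
    o <- order(GenomicRanges::start(p))
    p <- p[o]
    minus <- as.character(GenomicRanges::strand(p))[1] == "-"
    if (minus) p <- rev(p)
    gi <- data.frame(chrom = as.character(GenomicRanges::seqnames(p)),
                     start = GenomicRanges::start(p),
                     end = GenomicRanges::end(p),
                     strand = as.character(GenomicRanges::strand(p)))
    sp <- if (!is.null(p$species)) unique(p$species)[1] else NA_character_
    gene_model(unname(gene_of[i]), GenomicRanges::width(p), species = sp,
               genomic_intervals = gi)
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  finish_gene_set(models)
}

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("BED file lacks block (BED12) fields: ", path)
  models <- lapply(seq_along(gr), function(i) {
    rec <- gr[i]
    bl <- rec$blocks[[1]]  # 1-based relative to the record start
    abs_start <- GenomicRanges::start(rec) + GenomicRanges::start(bl) - 1L
    abs_end <- GenomicRanges::start(rec) + GenomicRanges::end(bl) - 1L
    strand <- as.character(GenomicRanges::strand(rec))
    o <- order(abs_start)
    if (strand == "-") o <- rev(o)
    gi <- data.frame(chrom = as.character(GenomicRanges::seqnames(rec)),
                     start = abs_start[o], end = abs_end[o], strand = strand)
    gene_model(rec$name, gi$end - gi$start + 1L, genomic_intervals = gi)
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  finish_gene_set(models)
}

# Genomic intervals for writing; fabricated on a synthetic contig when the
# model carries none (CDS laid end-to-end with 200-nt introns).
intervals_for_write <- function(gene, offset = 1L) {
  if (!is.null(gene$genomic_intervals)) return(gene$genomic_intervals)
  len <- gene$exon_cds_lengths
  starts <- cumsum(c(offset, head(len, -1L) + 200L))
  data.frame(chrom = "chrU1", start = as.integer(starts),
             end = as.integer(starts + len - 1L), strand = "+")
}

#' Write gene models as GTF (CDS features)
#'
#' One `CDS` feature per exon with `gene_id`, `transcript_id` and `species`
#' attributes and correct frame column. Volatile comment headers are stripped
#' so identical inputs produce byte-identical files.
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gtf <- function(genes, path) {
  grs <- lapply(genes, function(g) {
    gi <- intervals_for_write(g)
    cum_before <- c(0L, head(cumsum(g$exon_cds_lengths), -1L))
    frame <- (3L - cum_before %% 3L) %% 3L
    GenomicRanges::GRanges(
      gi$chrom, IRanges::IRanges(gi$start, gi$end), strand = gi$strand,
      source = "exonsite", type = "CDS", score = NA_real_,
      phase = as.integer(frame),
      gene_id = g$gene_id, transcript_id = g$gene_id,
      species = if (is.na(g$species)) "NA" else g$species)
  })
  gr <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(gr, path, format = "gtf")
  lines <- readLines(path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' One record per gene; blocks are the CDS intervals, thick region spans them.
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  grs <- lapply(genes, function(g) {
    gi <- intervals_for_write(g)
    gi <- gi[order(gi$start), ]
    span <- IRanges::IRanges(min(gi$start), max(gi$end))
    GenomicRanges::GRanges(
      gi$chrom[1], span, strand = gi$strand[1],
      name = g$gene_id, score = 0L, thick = span,
      blocks = IRanges::IRangesList(
        IRanges::IRanges(gi$start - min(gi$start) + 1L,
                         gi$end - min(gi$start) + 1L)))
  })
  gr <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read functional-site annotations from TSV
#'
#' Expects a tab-separated file with header columns `protein_id`, `gene_id`,
#' `site_id`, `ligand_id`, `ligand_category`, `residues` (comma-separated
#' 1-based integers) and optionally `is_buffer_ligand`. Rows with unparsable
#' residues, or referencing a gene absent from `genes` (when supplied), are
#' rejected with a warning.
#'
#' @param path File path.
#' @param genes Optional named list of [gene_model]s for referential checks.
#' @return List of [site_annotation] objects.
#' @export
read_sites <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("protein_id", "gene_id", "site_id", "ligand_id",
                "ligand_category", "residues")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sites TSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    res <- suppressWarnings(as.integer(strsplit(df$residues[i], ",")[[1]]))
    if (length(res) == 0L || anyNA(res) || any(res < 1L)) {
      warning("row ", i, ": unparsable residues '", df$residues[i],
              "'; row rejected", call. = FALSE)
      next
    }
    if (!is.null(genes) && !(df$gene_id[i] %in% names(genes))) {
      warning("row ", i, ": unknown gene_id '", df$gene_id[i],
              "'; row rejected", call. = FALSE)
      next
    }
    buf <- if ("is_buffer_ligand" %in% names(df)) {
      tolower(df$is_buffer_ligand[i]) %in% c("true", "1", "yes")
    } else FALSE
    out[[length(out) + 1L]] <- site_annotation(
      df$protein_id[i], df$gene_id[i], df$site_id[i], df$ligand_id[i],
      df$ligand_category[i], res, is_buffer_ligand = buf)
  }
  out
}

#' Write functional-site annotations to TSV
#'
#' @param sites List of [site_annotation] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  df <- data.frame(
    protein_id = vapply(sites, `[[`, character(1), "protein_id"),
    gene_id = vapply(sites, `[[`, character(1), "gene_id"),
    site_id = vapply(sites, `[[`, character(1), "site_id"),
    ligand_id = vapply(sites, `[[`, character(1), "ligand_id"),
    ligand_category = vapply(sites, `[[`, character(1), "ligand_category"),
    residues = vapply(sites, function(s) paste(s$residues, collapse = ","),
                      character(1)),
    is_buffer_ligand = vapply(sites, `[[`, logical(1), "is_buffer_ligand"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
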