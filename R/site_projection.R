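#' Construct a functional-site annotation
#'
#' One ligand-binding (functional) site: a set of 1-based residue positions on
#' a protein, with the ligand it binds and a coarse chemical category. Residue
#' lists are sorted and de-duplicated. Sites binding ligands that typically
#' enter structures during buffering or crystallization can be flagged so
#' analyses can be repeated without them.
#'
#' @param protein_id,gene_id,site_id,ligand_id Character identifiers.
#' @param ligand_category Character label from the user's category nomenclature.
#' @param residues Integer vector of 1-based residue positions (non-empty).
#' @param is_buffer_ligand Logical; `TRUE` for crystallization/buffer ligands.
#' @return An object of class `site_annotation`.
#' @export
site_annotation <- function(protein_id, gene_id, site_id, ligand_id,
                            ligand_category = NA_character_, residues,
                            is_buffer_ligand = FALSE) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0L || anyNA(residues) || any(residues < 1L)) {
    stop("site '", site_id, "': residues must be a non-empty set of positive integers")
  }
  structure(
    list(protein_id = as.character(protein_id),
         gene_id = as.character(gene_id),
         site_id = as.character(site_id),
         ligand_id = as.character(ligand_id),
         ligand_category = as.character(ligand_category),
         residues = residues,
         is_buffer_ligand = isTRUE(is_buffer_ligand)),
    class = "site_annotation"
  )
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf("<site %s on %s/%s: ligand %s [%s]%s, %d residue(s)>\n",
              x$site_id, x$protein_id, x$gene_id, x$ligand_id,
              x$ligand_category, if (x$is_buffer_ligand) " (buffer)" else "",
              length(x$residues)))
  invisible(x)
}

# Drop sites whose residues fall outside the protein; warn with the reason.
validate_sites <- function(gene, sites) {
  n_res <- gene$L %/% 3L
  keep <- vapply(sites, function(s) {
    if (max(s$residues) > n_res) {
      warning("site '", s$site_id, "' has residue ", max(s$residues),
              " beyond protein length ", n_res, " of gene '", gene$gene_id,
              "'; site skipped", call. = FALSE)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  sites[keep]
}

#' Classify exons as site-coding (EC) or non-site-coding (ENC)
#'
#' An exon is labelled `EC` when it codes at least one residue of at least one
#' functional site, i.e. its CDS interval intersects some site residue's codon
#' span; otherwise `ENC`. A codon split by an intron makes both flanking exons
#' EC. Terminal status and whether the exon codes a site residue at its very
#' first / last coding nucleotide are recorded for the phase analyses.
#'
#' @param gene A complete [gene_model].
#' @param sites List of [site_annotation] objects for this gene (may be empty).
#' @return A `data.frame` with one row per exon: `gene_id`, `exon_index`,
#'   `cds_length`, `phase5`, `phase3`, `symmetric`, `label` (`"EC"`/`"ENC"`),
#'   `is_terminal`, `codes_site_residue_at_5prime`,
#'   `codes_site_residue_at_3prime`.
#' @examples
#' g <- gene_model("g", c(9, 9))
#' s <- site_annotation("p", "g", "s1", "ATP", "nucleotides", residues = 1)
#' classify_exons(g, list(s))
#' @export
classify_exons <- function(gene, sites) {
  check_complete(gene)
  bad_gene <- vapply(sites, function(s) !identical(s$gene_id, gene$gene_id), logical(1))
  if (any(bad_gene)) stop("classify_exons: sites reference a different gene")
  sites <- validate_sites(gene, sites)
  iv <- exon_cds_intervals(gene)
  ph <- compute_phases(gene)
  n_ex <- nrow(iv)

  residues <- sort(unique(unlist(lapply(sites, `[[`, "residues"))))
  ec <- rep(FALSE, n_ex)
  at5 <- rep(FALSE, n_ex)
  at3 <- rep(FALSE, n_ex)
  if (length(residues) > 0L) {
    nt_start <- 3L * residues - 2L
    nt_end <- 3L * residues
    for (e in seq_len(n_ex)) {
      hit <- nt_start <= iv$cds_end[e] & nt_end >= iv$cds_start[e]
      ec[e] <- any(hit)
      # site codon covering the exon's first / last coding nucleotide
      at5[e] <- any(nt_start <= iv$cds_start[e] & nt_end >= iv$cds_start[e])
      at3[e] <- any(nt_start <= iv$cds_end[e] & nt_end >= iv$cds_end[e])
    }
  }
  data.frame(gene_id = gene$gene_id,
             exon_index = iv$exon_index,
             cds_length = iv$cds_length,
             phase5 = ph$phase5, phase3 = ph$phase3, symmetric = ph$symmetric,
             label = ifelse(ec, "EC", "ENC"),
             is_terminal = iv$exon_index %in% c(0L, n_ex - 1L),
             codes_site_residue_at_5prime = at5,
             codes_site_residue_at_3prime = at3)
}

#' Functional-site area on the protein and CDS
#'
#' The site area is the protein-sequence segment bounded by the first and last
#' site residues, regardless of gaps between them; `nt_span` is its image on
#' the CDS (`3*first - 2 .. 3*last`).
#'
#' @param site A [site_annotation].
#' @return A list with `first`, `last` (residues) and `nt_start`, `nt_end`
#'   (CDS nucleotides, 1-based inclusive).
#' @export
build_site_area <- function(site) {
  stopifnot(inherits(site, "site_annotation"))
  first <- min(site$residues)
  last <- max(site$residues)
  list(first = first, last = last,
       nt_start = 3L * first - 2L, nt_end = 3L * last)
}

#' Observed discontinuity of a site on the exon structure
#'
#' Counts the real exon borders (internal junctions) falling inside the site
#' area — junction slots `k` with `nt_start <= k <= nt_end - 1` — and derives
#' the number of exons spanning the area (= borders + 1). Also collects, per
#' site residue, the phases of junctions splitting or flanking its codon.
#'
#' @param gene A complete [gene_model].
#' @param site A [site_annotation] on this gene.
#' @return A list of class `projection_result`: `site_id`,
#'   `n_internal_borders_in_area`, `n_exons_spanning_area`, `exon_indices`
#'   (0-based exons intersecting the area), `boundary_phase_events`
#'   (`data.frame` of `residue`, `junction`, `phase`, `side`).
#' @examples
#' g <- gene_model("g", c(4, 5))
#' s <- site_annotation("p", "g", "s1", "HEM", "porphyrins", residues = c(1, 3))
#' observed_discontinuity(g, s)
#' @export
observed_discontinuity <- function(gene, site) {
  check_complete(gene)
  if (length(validate_sites(gene, site = list(site))) == 0L) {
    stop("site '", site$site_id, "' invalid for gene '", gene$gene_id, "'")
  }
  area <- build_site_area(site)
  j <- internal_junctions(gene)
  n_borders <- sum(j >= area$nt_start & j <= area$nt_end - 1L)
  iv <- exon_cds_intervals(gene)
  exon_idx <- iv$exon_index[iv$cds_start <= area$nt_end & iv$cds_end >= area$nt_start]
  ev <- do.call(rbind, lapply(site$residues, function(r) {
    d <- boundary_phase_of_site_codon(gene, r)
    if (nrow(d) > 0L) cbind(residue = r, d) else NULL
  }))
  if (is.null(ev)) {
    ev <- data.frame(residue = integer(0), junction = integer(0),
                     phase = integer(0), side = character(0))
  }
  structure(
    list(site_id = site$site_id,
         n_internal_borders_in_area = as.integer(n_borders),
         n_exons_spanning_area = as.integer(n_borders + 1L),
         exon_indices = exon_idx,
         boundary_phase_events = ev),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection %s: %d border(s) in area, %d exon(s) spanning>\n",
              x$site_id, x$n_internal_borders_in_area, x$n_exons_spanning_area))
  invisible(x)
}

#' Remove sites binding buffer/crystallization ligands
#'
#' Drops sites whose `ligand_category` is in the exclusion list. Intended for
#' repeating analyses without ligands that are likely crystallization or
#' buffering artefacts rather than biological partners.
#'
#' @param sites List of [site_annotation] objects.
#' @param exclusion_categories Character vector of category labels to remove;
#'   empty vector is the identity.
#' @return The surviving sites; the number removed is reported via `message()`.
#' @export
filter_buffer_ligands <- function(sites, exclusion_categories = character(0)) {
  if (length(exclusion_categories) == 0L) return(sites)
  present <- unique(vapply(sites, `[[`, character(1), "ligand_category"))
  unknown <- setdiff(exclusion_categories, present)
  if (length(unknown) > 0L) {
    warning("exclusion categories not present in data: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop <- vapply(sites, function(s) s$ligand_category %in% exclusion_categories,
                 logical(1))
  if (any(drop)) {
    message(sum(drop), " site(s) removed by buffer-ligand exclusion")
  }
  sites[!drop]
}
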