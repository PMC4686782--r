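---
title: "Projecting protein functional sites onto exon-intron gene structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting protein functional sites onto exon-intron gene structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonsite)
```

## The question

Ligand-binding sites are small sets of residues, often far apart in the
protein sequence, that carry most of a protein's function. Because exons are
the units that recombine during exon shuffling, how a functional site is
distributed over the exons of its coding gene constrains how freely that gene
can evolve: a site split across many exons can be destroyed by a single
shuffling event, while a site confined to one exon travels with it. This
package quantifies that relationship along four axes:

1. **Lengths** — are exons that code at least one site residue (EC) longer
   than exons that code none (ENC)?
2. **Discontinuity** — does the *site area* (the protein segment from the
   first to the last site residue) contain fewer exon borders than expected
   if borders fell at random?
3. **Phases** — are the reading-frame phases of introns at EC exon ends, and
   of introns splitting or flanking site codons, biased relative to a
   site-position permutation null?
4. **Ligand categories** — which chemical categories of ligand dominate among
   sites coded by symmetric phase 0-0 exons?

## Coordinate model

All computation happens on the concatenated coding sequence (CDS) in 1-based
nucleotide coordinates. Residue $i$ occupies nucleotides $3i-2 \dots 3i$; a
junction slot $k$ is the point between nucleotides $k$ and $k+1$, and a gene
with exon CDS lengths $l_1, \dots, l_n$ has junctions at the partial sums
$k_e = \sum_{j \le e} l_j$ for $e < n$. The 3' phase of exon $e$ is
$k_e \bmod 3$; the 5' phase of the next exon equals it; an exon with equal 5'
and 3' phases is *symmetric*. A junction with $k = 3i-2$ or $k = 3i-1$ splits
codon $i$ (phase 1 and 2); $k = 3i-3$ or $k = 3i$ flanks it in phase 0. A
phase-0 junction therefore touches two codons, and is counted once for each
flanking residue that belongs to a site — per-residue counting, a deliberate
choice where either convention is defensible.

Genes whose total CDS length is not a multiple of 3 cannot be assigned a
reading frame and are excluded with a warning, never silently truncated.
Minus-strand genes are reordered into transcription direction at file-reading
time, so every downstream function is strand-free.

## The two nulls

**Boundary resampling** (discontinuity stage): for a gene of CDS length $L$
with $m$ real junctions, each replicate redraws $m$ junction slots uniformly
without replacement from $\{1, \dots, L-1\}$ and counts those falling in the
site area. Ten replicates per gene are the default. The replicate mean
converges to the hypergeometric expectation $m\,s/(L-1)$, with $s$ the
number of slots in the area — an identity the test suite checks at $10^5$
replicates. Intron genomic lengths never enter: the statistic lives in CDS
space, which is why the null samples CDS slots rather than genomic
positions.

**Site-position permutation** (phase stage): each replicate re-places every
site's residues uniformly without replacement over its protein (1,000
replicates by default), recollects the phases of junctions splitting or
flanking the permuted site codons, and records the per-phase fractions.
Under uniform placement, the expected event count for phase $p$ in a gene is
$n_{\text{res}}\, w_p / P$ with $P$ the protein length and $w_p$ the number
of junction-adjacent codon slots of phase $p$ ($2m_0$, $m_1$, $m_2$) — the
length-weighted expectation the acceptance tests verify.

Both nulls derive per-gene (and per-site) seeds from one master seed and the
identifiers, so results are independent of processing order and exactly
reproducible.

## Which comparison is calibrated, and which is faithful

The classical presentation of the discontinuity result pools all null
replicates and compares them to the observed counts with an unpaired
Mann-Whitney test. We report that test (`mann_whitney_counts`) because it is
the recognizable headline, but it is structurally conservative: a site's
observed count and its own ten replicates share the site span, so the pooled
groups are positively dependent and the U variance is overestimated. In our
simulations under a true null this test essentially never rejects.

The calibrated version of the same question is the paired signed-rank test
(`wilcoxon_counts_paired`) of each site's observed count against one matched
null replicate; pairing removes the shared-span dependence. Its nominal
behaviour is verified by simulation: when gene structures place junctions
exactly as the null assumes (`exon_length = list(kind = "uniform_junctions",
...)`) and sites are uniform, it rejects at 5% within the binomial band over
1,000 simulated datasets.

A caveat worth stating plainly: with realistic (log-normal) exon lengths the
position-uniform boundary null is *mildly misspecified* even for uniformly
placed sites. Real junctions keep away from the CDS edges (exons have a
minimum length), whereas a uniformly located site span covers central slots
preferentially; in our measurements this inflates the observed border count
about 6% above the null mean. The null is the field's standard and we keep
it, but rejections of marginal size should not be over-read — the clustered
signal the pipeline is designed to detect acts in the opposite direction and
is far larger.

## The synthetic generator

The generator emulates the statistical skeleton of a curated site-to-gene
sample without any database access. Defaults, chosen once as a
vertebrate-like regime: 2 + Poisson(7) coding exons per gene (~9 on
average); log-normal exon lengths with median 120 nt (sdlog 0.6, floor 9
nt); internal junction 3'-phases ~(0.47, 0.30, 0.23); 1 + Poisson(5) sites
per protein and 2 + Poisson(3) residues per site; seven ligand categories
with one flagged as buffer/crystallization (10%). Phases are imposed by
adding 0-2 nt to each internal exon after length sampling, so phase and
length distributions are controlled nearly independently; the final exon is
padded into frame.

Two placement modes matter scientifically. `"clustered"` draws a site's
residues inside a short window (default 20 residues) lying wholly within one
exon whenever an exon is wide enough — the regime the analyses should flag:
site areas span one exon, EC exons are longer than ENC (window placement
favours wide exons), and clustered-mode sites rarely have split codons.
`"uniform"` scatters residues over the whole protein and is the no-signal
reference for calibration. Protein sequences themselves are never generated;
no analysis consumes amino-acid identities, so protein length suffices
(poly-X FASTA is available for format tests only). Genomic coordinates are
fabricated on one synthetic contig with fixed 200-nt introns, on both
strands.

What passing tests on these data do **not** show: real exon-length and
site-size distributions are heavier-tailed and mutually correlated; real
sites overlap within proteins and across homologues (redundancy filtering is
out of scope — inputs are assumed non-redundant); and the generator encodes
no causal link between site presence and phase, so phase-stage findings on
synthetic data reflect the null machinery, not biology.

## Statistical conventions

Pearson chi-square without continuity correction throughout; for length
distributions, shared 3-nt bins merged right-to-left until every expected
cell reaches 5 (the realized binning is reported in the result). The
Mann-Whitney U is reported for the first sample, with a tie-corrected normal
p-value (exact for small tie-free samples). The signed-rank test drops zero
differences and reports Z alongside V. Within the phase stage, all tests
form one Bonferroni family (the only correction applied). Two-sided
p-values everywhere. Degenerate inputs (empty EC or ENC class, single-exon
samples, all-zero pairings, tables with a zero marginal) produce `"no data"`
or a skipped-test status rather than errors, so the pipeline runs to
completion on pathological inputs.

The paired Wilcoxon of the phase stage compares, within each gene, the
fraction of phase-0 5' ends among EC exons that code a site residue at their
first coding nucleotide with the same fraction among ENC exons; genes
lacking either class are dropped and counted in the metadata. The pairing
unit is a genuine interpretation choice (per gene, not per exon rank) and is
declared in the report metadata. Terminal exons are excluded from the phase
stage always, from other stages only on request — length and discontinuity
analyses keep them by default, with
`run_config(exclude_terminal_everywhere = TRUE)` as the flag to drop them.

## Problem sizes

Test-suite simulations use 50-400 genes and 20-1,000 null replicates per
check, sized so each property is resolved well inside its Monte-Carlo error;
the oracle-equivalence checks run 1,000 random genes exhaustively. The
acceptance script analyses the default 1,000-gene clustered dataset with the
default 10 boundary replicates and 1,000 permutations — the same
configuration a user gets from `generator_config()` and `run_config()`
untouched.

## Worked example

```{r example, eval = FALSE}
d <- generate_dataset(generator_config(n_genes = 200, seed = 1))
reports <- run_pipeline(d$genes, d$sites, run_config(seed = 1),
                        out_dir = "exonsite_out")
reports$lengths$tables$summary
reports$discontinuity$tests$mann_whitney_counts
reports$phases$tables$phase_counts
```

## Known limitations

Single isoform per gene (longest CDS wins on multi-isoform GTFs); no UTRs,
frameshifts or selenocysteine recoding; ligand categories are input
annotations, never inferred from chemistry; the boundary null does not
preserve empirical exon-length distributions (a length-preserving null would
be a natural extension); and cross-species contrasts are out of scope —
species is a pass-through label.
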