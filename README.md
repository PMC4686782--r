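# exonsite

Analysis of how protein functional (ligand-binding) sites project onto the
exon-intron structure of their coding genes.

A functional site is a small set of residues, often discontiguous in
sequence, that binds a ligand or catalyses a reaction. Because exons are the
units of exon shuffling, the way a site is distributed over exons constrains
gene evolution. `exonsite` implements the full analysis chain for asking
whether sites respect exon structure:

- **Coordinate engine** — exact residue → codon → exon mapping on the
  concatenated CDS; exon 5'/3' phases (`phase3 = cumulative CDS length mod
  3`) and symmetry; identification of junctions that split a site codon
  (phase 1/2) or flank it between codons (phase 0).
- **EC/ENC classification** — exons coding at least one site residue (EC)
  versus exons coding none (ENC), with length comparisons (binned χ²,
  Mann-Whitney U).
- **Discontinuity** — the number of exon borders inside the *site area*
  (first to last site residue), compared against a null that re-places each
  gene's real number of borders uniformly over the CDS junction slots
  (expected count `m·s/(L−1)` for `m` junctions and an area of `s` slots);
  both a classical pooled Mann-Whitney and a calibrated paired signed-rank
  are reported.
- **Phase analyses** — phase-0 representation at 5'/3' ends of EC vs ENC
  exons (2×2 χ²), symmetric 0-0 exons, and the phases of junctions touching
  site codons against a 1,000-fold site-position permutation null, with
  Bonferroni correction and a per-gene paired Wilcoxon.
- **Synthetic data generator** — multi-exon gene models with configurable
  exon-count, exon-length and junction-phase distributions, plus site
  annotations placed either clustered within one exon or uniformly — so the
  whole pipeline is testable without any database.
- **I/O** — GTF and BED12 gene structures (via `rtracklayer`), TSV site
  tables, deterministic TSV + JSON report bundles, and a command-line
  front end (`exec/exonsite`).

## Worked example

```r
library(exonsite)

d <- generate_dataset(generator_config(n_genes = 200, seed = 1))
reports <- run_pipeline(d$genes, d$sites, run_config(seed = 1))

reports$lengths$tables$summary
#>   label n_exons mean_length median_length
#> 1    EC     852    156.4073           136
#> 2   ENC    1005    137.1771           116

reports$discontinuity$tests$mann_whitney_counts
#> <U = 5.525e+06, p = 6.33e-81, n1 = 1204, n2 = 12040>

reports$phases$tables$phase_counts
#>        phase observed observed_fraction expected_fraction
#> phase0     0       18                 1         0.6330062
#> phase1     1        0                 0         0.1943434
#> phase2     2        0                 0         0.1726504
```

With the default clustered site placement, site-coding (EC) exons are ~19 nt
longer on average than non-coding (ENC) exons; site areas span fewer exons
than the boundary-resampling null expects (here every site sits in a single
exon, against an expected mean of ~1.27 — hence the very small Mann-Whitney
p-value); and the junctions that touch site codons are pure phase 0 (a
clustered site's codons lie wholly inside an exon, so only flanking phase-0
contacts remain), against a permutation expectation of ~64% phase 0.

The methods vignette (`vignettes/site-exon-projection.Rmd`) documents the
coordinate model, both resampling nulls, which discontinuity comparison is
calibrated and why, the generator's assumptions, and known limitations.

## Command line

```sh
exec/exonsite simulate --seed 7 --n-genes 100 --out data/
exec/exonsite run-all --genes data/genes.gtf --sites data/sites.tsv \
    --seed 7 --out results/
```

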