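# riboStart

Genome-wide analysis of context-specific inhibition of bacterial
translation initiation from ribosome profiling.

Some initiation inhibitors that bind in the E site of the 30S subunit's
mRNA channel act unevenly across the genome: how strongly a gene is shut
down depends on the mRNA nucleotide immediately preceding its start codon
(the −1 base, with G most conducive to arrest) and on whether the gene is
translationally coupled — its start codon overlapping the stop codon of the
upstream cistron in the same operon, which attenuates the drug's effect.
riboStart quantifies these signatures from aligned Ribo-seq and RNA-seq
reads, and ships a synthetic footprint simulator encoding the mechanistic
model (drug-arrested 70S complexes sitting on start codons) so the whole
pipeline is testable without external data. It is written for
bacterial-translation and antibiotic-mechanism labs working with Ribo-seq.

## The statistics at its core

* **A-site density**: each footprint adds unit mass at its A-site codon's
  first base, `(3′ end − 12 nt)`; an N-nt RNA-seq read adds 1/N per covered
  base.
* **Translation efficiency**: `TE_g = RPKM_ribo(g) / RPKM_rna(g)` over the
  CDS; drug effect `ΔTE_g = log2 TE_drug(g) − log2 TE_ctrl(g)` with an
  RPKM-scale pseudocount.
* **Head enrichment**: `HE_g = mean(head density) / mean(body density)`
  (head = first five codons; body = the rest minus the stop region), with
  `ΔHE_g = log2 HE_drug − log2 HE_ctrl` and Spearman's ρ between ΔHE and
  ΔTE.
* **Context enrichment**: for each base b and position p in −15..+17 around
  the start codon, the signed score is
  `−log10 Pr[Binomial(n, q_bp) ≥ k_bp]` for overrepresentation in the top-5%
  most-inhibited set (k of n foreground genes) against the expressed-gene
  background frequency q, with a Bonferroni line at
  `−log10(α / (4·33)) ≈ 3.42`.
* **Coupling categories**: other / nonoverlapping_operonic /
  overlapping_operonic (start codon at or before the upstream stop codon's
  last base), compared by pairwise Welch t tests; −1-base groups by
  pairwise Mann–Whitney U; both Bonferroni-adjusted.

## Worked example

```r
library(riboStart)

cfg <- simConfig(nOperons = 20L, riboDepth = 3e4, rnaDepth = 3e4, seed = 7L)
gn <- buildGenome(cfg)
gn
#> SimGenome: 56 genes on 1 replicon(s) of 36796 nt
#>   categories: nonoverlapping_operonic=24 other=20 overlapping_operonic=12

res <- runAll(cfg)
tapply(res$delta$log2_te_change, res$delta$minus1_base, median)
#>          A          C          G          T
#>  0.5145115 -0.4602892 -2.7767659  0.5300864
res$spearman$rho
#> [1] -0.3096516
res$motif
#> MotifResult: fg n = 5 , width 33 , threshold 3.422
#>   significant overrepresentation:
#>     G at -1 (score 3.89)
```

Reading the output: genes with G at −1 lose ~2.8 log2 units of translation
efficiency under the drug while A/U(−1) genes are barely affected (the
positive values reflect normalization against the shrunken drug library);
the drug-induced gain in start-codon occupancy anticorrelates with the TE
change (ρ ≈ −0.31); and the only significant context enrichment among the
most-inhibited genes is G at position −1, above the Bonferroni line. With
real data, replace the simulated inputs:

```r
genes <- readAnnotation("genes.gff3", "operons.tsv")
res <- runAnalysis("ribo_drug.sam", "rna_drug.sam",
                   "ribo_ctrl.sam", "rna_ctrl.sam",
                   genes, "genome.fa", outdir = "results/")
```

`relativeOccupancy()` additionally rescales per-gene profiles by a measured
global residual-translation fraction (e.g. from ³⁵S labeling) for
occupancy plots comparable across conditions.

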