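# enhancerscape

Enhancer-landscape analysis for paired tumor/normal histone-mark ChIP-seq
and RNA-seq, for researchers studying how cis-regulatory activity is
rewired in cancer. From peak calls, signal tracks, a gene annotation and a
count matrix, the package:

1. builds the **active-enhancer catalog** per condition: H3K27ac peaks
   supported by H3K4me1, kept only when TSS-distal (boundary ≥ 1.5 kb *or*
   center ≥ 3 kb from every TSS), stitched when gaps are < 12.5 kb;
2. calls **super enhancers** on the H3K27ac rank curve: with ranks and
   signal scaled to [0, 1], the cutoff is the first rank whose local slope
   exceeds 1 (the tangent-slope-1 point); enhancers above it are super,
   the rest typical;
3. calls **variant enhancer loci (VELs)** on the union catalog:
   FC = (tumor RPKM + 1)/(normal RPKM + 1), *gain* when FC ≥ 2, *lost*
   when FC ≤ 0.5 — and **VSELs**, the same logic restricted to loci that
   are super in the relevant condition;
4. calls **DEGs** from counts: FPKM normalisation, Welch test on
   log2(FPKM + 1), *up/down* when |log2FC| ≥ 1 and p < 0.05;
5. **integrates**: each locus is assigned the gene with the nearest TSS;
   gain-VEL genes ∩ up DEGs (and lost ∩ down), multi-TF target-list
   intersections, and the three-way coordinated-gene overlap
   (TF targets ∩ up DEGs ∩ gain-VEL genes);
6. ranks **known motifs** (JASPAR PWMs, log2-odds scans of both strands)
   by one-sided hypergeometric enrichment of gain-VEL sequences against a
   dinucleotide-shuffled or genome-sampled background — the analysis that
   flags AP-1-family factors (TPA-response element `TGACTCA`) in
   squamous-carcinoma enhancer gains;
7. provides QC: 2-kb-binned Spearman track correlations and peak-centered
   metagene profiles.

A first-class **synthetic-data module** generates a toy genome with
planted typical/super enhancers, gain/lost VELs wired to up/down genes,
negative-binomial ChIP and RNA noise, and planted motif instances, so
every stage is verifiable against ground truth with no external data.

## Worked example

```r
library(enhancerscape)
cfg <- pipeline_config(seed = 42, outdir = "demo_run")
res <- run_all(cfg)        # simulates inputs, writes every stage table

table(res$vels$status)
#>   gain   lost stable
#>     56     56    208
```

56 gain and 56 lost VELs are called — exactly the planted 50 typical +
6 super variant loci per direction. The strongest VELs:

```r
head(res$vels[, c("name", "tumor_rpkm", "normal_rpkm", "fold_change",
                  "status", "proximal_gene")], 3)
#>        name tumor_rpkm normal_rpkm fold_change status proximal_gene
#> 1 union_244      65.57       413.1      0.1608   lost     gene_0244
#> 2 union_109      55.72       349.9      0.1616   lost     gene_0109
#> 3 union_276      62.23       379.3      0.1662   lost     gene_0276
```

Fold changes are pseudocounted RPKM ratios; `proximal_gene` is the gene
with the nearest TSS to the locus center. The normal-condition rank curve
puts 23 of 320 loci above the tangent-slope-1 cutoff (the 20 planted
supers plus a handful of borderline typicals), DEG calling finds 55 up /
57 down of 800 genes (56 planted each way), and the planted AP-1 site
dominates the motif ranking:

```r
head(as.data.frame(res$enrichment)[, c("motif_id", "fg_hits", "fg_total",
                                       "bg_hits", "p_value", "rank")], 3)
#>   motif_id fg_hits fg_total bg_hits  p_value rank
#> 1      AP1      48       56       9 2.89e-14    1
#> 2 decoy_10      12       56       7 1.57e-01    2
#> 3  decoy_4      11       56       7 2.20e-01    3
```

`score_against_truth(res)` compares every call against the planted truth
(≥ 50 % reciprocal-overlap matching); on this run all recovery rates are
0.98–1.00. Real data enters through the same `pipeline_config(simulate =
FALSE, paths = list(...))` surface, or stage by stage via
`read_intervals()`, `read_signal()`, `call_enhancers()`, `call_vels()`,
`call_degs()`, `enrich_motifs()` and friends.

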