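---
title: "Methods: tumor/normal enhancer-landscape analysis"
author: "enhancerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor/normal enhancer-landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscape)
```

# The analysis

Active enhancers are distal regulatory elements carrying both H3K4me1 and
H3K27ac. Comparing their H3K27ac signal between a tumor and its matched
normal tissue identifies *variant enhancer loci* (VELs): loci whose
acetylation rises at least two-fold in tumor (gain) or falls to at most
half (lost). Super enhancers — stitched clusters with exceptionally high
total H3K27ac — are treated the same way to give variant super enhancer
loci (VSELs). Coupling enhancer changes to expression changes through
each locus' nearest gene, and to transcription-factor programs through
motif enrichment and target-set intersections, yields a compact picture
of the regulatory rewiring: which loci changed, which genes they drive,
and which factors (canonically the AP-1 family at `TGACTCA` sites in
squamous carcinoma) sit upstream.

This package implements that pipeline downstream of alignment and peak
calling: peaks, signal tracks, a gene annotation and a count matrix are
inputs; read-level processing is out of scope.

## Enhancer catalog

Per condition, in order:

1. **Active filter** (`filter_active`): an H3K27ac peak enters the
   catalog only if it overlaps an H3K4me1 peak (≥ 1 bp by default;
   `min_overlap_frac` tightens this to a fraction of the peak). The
   overlap fraction is a free choice — no consensus value exists — so it
   is a parameter, with "any overlap" as the permissive default.
2. **Distal filter** (`filter_distal`): a peak is kept only if, for
   *every* TSS, its boundary is ≥ 1,500 bp away *or* its center is
   ≥ 3,000 bp away. A TSS inside a peak has boundary distance 0. The two
   sub-rules are stated jointly; we read the "or" literally, and expose
   `combine = "and"` for the conservative reading so the ambiguity is a
   flag, not a guess. A separate, coarser pre-filter
   (`filter_tss_proximal`, default 2,000 bp) is available where a single
   TSS-distance rule is wanted.
3. **Stitching** (`stitch`): single-linkage merging of consecutive peaks
   whose gap is *strictly* less than 12,500 bp ("shorter than 12.5 kb";
   a gap of exactly 12,500 splits). Merging is transitive; the unit
   tests verify equality with an O(n²) transitive-closure oracle.
4. **Quantification** (`quantify`): raw signal is the integral of the
   track over the stitched span; RPKM divides by span length (kb) and
   library size (millions). Both are kept: RPKM for cross-condition fold
   changes, raw totals for super-enhancer ranking.

## Super enhancers

Enhancers are sorted ascending by *total* H3K27ac signal. Ranks are
scaled to [0, 1] by `(i−1)/(N−1)` and signal by its maximum; the cutoff
is the first rank (scanning left to right) whose local slope strictly
exceeds 1 — the tangent-slope-1 ("inflection") point of the hockey-stick
curve. Loci with signal strictly greater than the cutoff signal are
super.

Numerical conventions, pinned because rank-curve implementations differ
here:

* slope by central finite differences, forward/backward at the ends, no
  smoothing;
* *first* crossing wins (the curve is monotone, but noise can make the
  finite-difference slope dip back below 1);
* strict `>` on both the slope test and the signal threshold, so a curve
  of constant slope 1 (`y = x`) yields zero supers and the cutoff locus
  itself is typical;
* all-equal signals: warning, zero supers; fewer than 3 loci: error.

On `y = x³` sampled at 1,001 ranks the crossing lands at rank fraction
0.57–0.59, bracketing the analytic tangent point `x = 3^(−1/2) ≈ 0.5774`;
this closed-form case is a permanent test.

Ranking uses the **raw total** signal, not RPKM: a super enhancer's
stitched span includes the gaps between constituents, so per-kb
normalisation dilutes exactly the accumulation the rank curve is meant to
expose. (RPKM remains the right scale for cross-condition comparison of
one locus with itself, where span length cancels.)

## Differential layer

Replicates are pooled before anything else (values summed run-wise,
library sizes added), matching the pooled-replicates design; pooling
before normalisation keeps quantification linear, and a test asserts
`quantify(pool) = Σ quantify(rep)`.

The per-condition catalogs are merged into a union catalog (≥ 1 bp
overlap joins; provenance flags record presence and super status per
condition). Each union locus gets

`FC = (tumor RPKM + c) / (normal RPKM + c)`, default pseudocount
`c = 1` RPKM — how zero-signal loci were handled is never stated in such
analyses, so the guard is explicit and configurable. Status: gain when
FC ≥ 2, lost when FC ≤ 0.5, else stable. The classification is symmetric
(swapping conditions swaps gain and lost) and invariant to rescaling both
tracks and their library sizes together; both are property-tested.

**VSELs** restrict the same logic to loci super in ≥ 1 condition. By
default a gain VSEL must be super *in tumor* and a lost VSEL super *in
normal* — "variant super enhancer" is read as "the super enhancer state
is what varies". The pure fold-change reading is available with
`directional = FALSE`.

**DEGs**: FPKM (`counts / (length_kb × total/1e6)`), then
`log2FC = log2((mean tumor FPKM + 1)/(mean normal FPKM + 1))` with a
two-sided Welch test on `log2(FPKM + 1)`; up/down requires |log2FC| ≥ 1
and p < 0.05. The Welch-on-log stand-in replaces a negative-binomial
fitter deliberately: it is self-contained, its type-I error is checked by
simulation (null false-positive rate within [0.03, 0.08] at α = 0.05 in
the acceptance suite), and an external DE table can be substituted
anywhere downstream since only the `deg_records` columns matter.
P-values are raw to match the stated p < 0.05 rule; `fdr = TRUE` switches
to Benjamini–Hochberg.

## Integration

"Proximal gene" = the gene whose TSS is nearest the locus center, with
ties broken by the lexicographically smaller gene id and no distance cap
by default (a `max_dist` cap exists for sensitivity analyses). Nearest
TSS is the simplest reproducible rule; annotation-priority schemes are
tool-specific and not reproducible from their descriptions.

Set logic is plain and fully enumerated: gain-VEL genes ∩ up DEGs,
lost-VEL genes ∩ down DEGs, k-way TF target intersections, and the
three-way coordinated set (TF targets ∩ up DEGs ∩ gain-VEL genes), each
with all exclusive Venn-region counts. Inclusion–exclusion over these
counts is asserted on random set triples. `rank_top` orders a gene set by
descending log2FC (ties lexicographic) for "top-10 target" style tables.

## Motif enrichment

Known-motif enrichment stands in for de-novo discovery, which is out of
scope: the scientific claim exercised is the *ranking* of known TF
motifs in gain-VEL sequences. PWMs come from JASPAR text; counts get a
0.5 pseudocount per cell and are scored as log2 odds against a uniform
(configurable) background. Both strands are scanned; a window is a hit at
≥ 80 % of the maximum attainable score (`threshold_fraction`, a
length-independent convention); `N` scores as the position's minimum.
Per motif, sequences are dichotomised (≥ 1 hit or none — robust to hit
clustering within a sequence) and a one-sided hypergeometric test
compares foreground to background; motifs rank by ascending p, ties by
id. The p-value is checked against exhaustive enumeration of 2×2 tables
at 1e-12.

Backgrounds: `dinucleotide_shuffle` (Euler-path shuffle, exactly
preserving each sequence's dinucleotide counts and length) or
`genomic_sample` (length-matched windows excluding the foreground loci).
Both are provided because the appropriate null is data-dependent; no
equivalence between them is claimed.

## QC

Genome-wide comparisons use 2-kb windows (exact tiling, short last bin;
binning conserves total signal) and Spearman correlation with average
ranks for ties; bins zero in *both* tracks are excluded by default, since
the empty genome otherwise dominates the coefficient. Metagene profiles
average per-bp signal in 50-bp bins over ±3 kb around peak *centers*;
off-chromosome bins contribute only their covered part.

# The synthetic study

`sim_config()` defines the default study the tests and the acceptance
script run: 2 chromosomes × 12.5 Mb, 800 genes, 320 planted enhancer
records — 200 stable typicals, 50 gain + 50 lost typical VELs, and 20
supers of which 6 gain and 6 lost — with three replicates per condition,
planted signal ratios 4 (gain) and 0.25 (lost) so truth clears the
2-fold thresholds with margin, negative-binomial noise (dispersion 0.05;
dispersion → 0 recovers Poisson and is tested as such), RNA depth 1e6
with planted log2FC ±2, and the AP-1 heptamer planted in 80 % of
gain-VEL sequences.

Layout guarantees make truth well-defined under the pipeline's own rules:
one record per 30-kb block (inter-record gaps > 12.5 kb, so stitching can
never merge two truth records), super constituents 3–5 peaks with gaps
< 12.5 kb, every enhancer boundary ≥ 3 kb from every TSS (truth survives
the distal filter by construction), and each variant locus wired to a
gene in its own block whose TSS is the nearest. Infeasible layouts
(genome too small) error out with the required size.

Two deliberate realism choices, made once:

* **Background-dominated libraries** (background 0.2 reads/bp,
  enhancer enrichment 2 reads/bp): in real ChIP libraries most reads fall
  outside called enhancers, so per-library RPKM scaling is only mildly
  perturbed by the condition-specific signal itself. With enhancer-
  dominated toy libraries, the planted gains/losses would shift the
  normaliser and bias every fold change — a property of the toy, not of
  the method.
* **DE genes a minority of the transcriptome** (112 of 800): for the
  same reason, on the RNA side, total-count FPKM normalisation assumes
  most genes are unchanged.
* **Super boost** (× 5 constituent enrichment): super enhancers carry
  far higher H3K27ac than typicals; without this, a 4-fold-gained typical
  VEL in tumor would be indistinguishable from a super enhancer on the
  rank curve and the planted classes would not be separable even in
  principle.

The generator emits per-replicate coverage tracks *and* peak sets (truth
constituents whose realised coverage exceeds 5× background) — emulating
an upstream peak caller without implementing one. It does **not** emulate
read-level artifacts: fragment-size effects, GC bias, mappability,
duplicate reads, copy-number changes, or spatially structured background.
Passing recovery tests therefore demonstrates the correctness of the
calling logic under the stated noise model, not robustness to everything
real data can do.

One expected asymmetry: in the *tumor* catalog, 4-fold-gained typical
loci can legitimately cross the tangent cutoff (tumor-acquired super
status is genuine biology), so super/typical class recovery is scored on
the normal-condition catalog, where every planted super is active at
super level and every typical at typical level.

# Problem sizes and determinism

The test suite and `scripts/acceptance.R` use the default study (320
loci, 800 genes; seconds per run), 50 seeded peak sets of up to 1,000
peaks for the stitching oracle, 500 peaks × 100 genes for the distal
oracle, 20-seed nulls for calibration, and 20-seed motif-ranking
replicates against 10 decoy PWMs. All randomness flows from a single
seed (`--seed` in the acceptance script); generator streams are derived
per stage, and two runs of `run_all` with one seed produce byte-identical
output files (asserted over file checksums).

# Limitations

* No replicate-aware dispersion modelling of ChIP signal: fold changes
  are point estimates from pooled tracks, with a pseudocount rather than
  a variance model.
* The DEG stand-in is a location test on log FPKM, not a count model;
  for real data a dedicated DE package's table can and should be plugged
  into the downstream stages.
* Proximal-gene assignment ignores 3D contacts and enhancer–promoter
  annotation priority.
* Known-motif enrichment cannot discover unrepresented motifs, and the
  two background models can disagree on sequences with strong
  composition bias.
* bedGraph is the canonical signal format; bigWig input should be
  converted upstream.
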