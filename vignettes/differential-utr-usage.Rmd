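---
title: "Detecting differential exon and 3' UTR usage with binsplice"
author: "binsplice maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential exon and 3' UTR usage with binsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(message = FALSE, warning = FALSE)
```

# Background

Most RNA-seq analyses summarize reads at the gene level and therefore miss
changes in how a gene's output is distributed across its parts. Two such
changes are of particular biological interest: differential exon usage (DEU),
and changes in 3' UTR length driven by alternative polyadenylation (APA) —
shortened or lengthened 3' UTRs alter miRNA- and RBP-binding site content and
thereby transcript stability, localization and translation. Because APA
isoforms differ only in a terminal stretch of UTR, standard isoform
quantification is poorly suited to detecting them; a more robust strategy is
to partition the annotation into small disjoint *bins*, count reads per bin,
and test each bin's abundance against the rest of its gene.

`binsplice` implements that strategy end to end:

1. **Bin preparation** — exons are flattened into the widest intervals over
   which the set of overlapping annotated features is constant; bins are
   labeled `CDS`, `UTR`, `3UTR` or `non-coding`; annotated poly(A) sites are
   then used to segment existing 3' UTR bins and to extend genes with new
   3' UTR bins, so that usage of alternative poly(A) sites becomes visible
   as differential usage of the corresponding bins.
2. **Counting** — every usable alignment is assigned once to every bin it
   overlaps by at least one base.
3. **Testing** — per-bin weighted linear models (voom/limma) followed by a
   moderated t-test of each bin's log2 fold change against the
   precision-weighted average of the other bins of its gene, aggregated to
   genes by Simes' method.

# The statistical model

For bin $k$ of a gene with $N$ bins, let $\hat\beta_k$ be the estimated log2
fold change of the tested condition coefficient, and $u_k$ the square root of
the corresponding diagonal element of the unscaled covariance matrix
$(X^TVX)^{-1}$, where $X$ is the design matrix and $V$ the voom precision
weights. The bin is compared to the weighted average of the *other* bins,

$$\hat B_k = \frac{\sum_{i \ne k} w_i \hat\beta_i}{\sum_{i \ne k} w_i},
\qquad \hat C_k = \hat\beta_k - \hat B_k .$$

Two variants of the moderated t-statistic are provided.

**Classical statistic** (`method = "diffSplice"`). Weights are
$w_i = 1/u_i^2$; the residual variances of a gene's bins are averaged, the
gene-level values are squeezed by empirical Bayes into a common posterior
$s_g^2$ per gene, and the coefficient is rescaled before testing:

$$\hat D_k = \hat C_k \sqrt{1 - w_k / \textstyle\sum_i w_i}, \qquad
t_k = \frac{\hat D_k}{u_k\, s_g}.$$

The rescaling makes $\mathrm{var}(\hat D_k) = u_k^2 s^2$ exactly (the
leave-one-out average contributes $s^2 / \sum_{i\neq k} w_i$ to
$\mathrm{var}(\hat C_k)$), so the statistic is calibrated.

**Improved statistic** (`method = "diffSplice2"`, the default) makes three
changes: residual variances are *not* assumed constant within a gene — each
bin's variance is squeezed directly into a posterior $s_i^2$; the weights
incorporate those variances, $w_i = 1/(s_i^2 u_i^2)$; and the unscaled
coefficient is tested directly,

$$t_k = \frac{\hat C_k}{u_k\, s_k}.$$

In both cases two-sided p-values use a t distribution with moderated degrees
of freedom (residual df plus the empirical-Bayes prior df, capped at the
total residual df), bins are adjusted by Benjamini–Hochberg, and gene-level
p-values are Simes' $\min_i N p_{(i)}/i$ over each gene's sorted bin
p-values, again BH-adjusted across genes. For a UTR-centred analysis, the
p-values of all bins that are not (3') UTR bins are set to 1 before
aggregation, so gene-level significance reflects UTR bins only; since
p-values only move up, this masking can never make a gene more significant.

A consequence of dropping the $\hat D$ rescaling is that
$\mathrm{var}(\hat C_k)$ exceeds $u_k^2 s_k^2$ by roughly a factor
$1 + 1/(N-1)$, so the improved statistic is mildly anti-conservative at the
bin level (about 0.065–0.08 of null bins at $p<0.05$ with 4–8 bins per gene
in our simulations, versus 0.04–0.05 for the classical statistic). This is
the documented trade-off of the method: it ranks genuinely affected genes
better — which is what the gene-level benchmark measures — at the price of
imperfect finite-sample FDR control. Users needing strict bin-level error
control should prefer the classical statistic or validate hits downstream.

# Bin preparation details

*Coordinates.* Internally everything is 1-based and inclusive (the GTF
convention); BED input is converted on read and BED-like output states its
convention in the header.

*Flattening.* `flattenExons()` fragments the exon annotation at every exon
boundary (`GenomicRanges::disjoin`), records the covering transcripts per
bin, and — when a bin is covered by exons of several genes — duplicates it
once per gene with `geneAmbiguous = TRUE`, so that each gene contains the
shared fragment once. With `genewise = TRUE` each gene is flattened in
isolation instead.

*Labeling.* A bin overlapping any CDS interval is `CDS`; a CDS-free bin
whose transcripts include a protein-coding one is `UTR`, refined to `3UTR`
when it lies strand-aware downstream of the last CDS of one of its coding
transcripts; bins without any protein-coding transcript are `non-coding`.
A transcript counts as protein-coding if it has a CDS record *or* carries
the `protein_coding` biotype (GTF dialects differ in which they provide);
transcripts that are coding by biotype only provide no stop-codon boundary,
so their UTR bins conservatively keep the plain `UTR` label.

*APA segmentation.* For every stranded poly(A) site, the nearest strand-aware
upstream CDS/UTR bin edge is found and a new 3' UTR bin is created from that
boundary (exclusive) to the site (inclusive), inheriting the boundary bin's
gene and transcript set; sites are processed in transcription order so
consecutive sites yield consecutive segments. A site falling inside an
existing UTR/3' UTR bin splits it at the site (a site on an existing 3' edge
is a no-op); sites inside CDS bins are ignored, since new UTRs are defined
only from CDS/UTR context. Candidates wider than `maxUTRbinSize` (default
15,000 bp) are discarded as unlikely to be real UTRs, as are candidates
whose nearest upstream feature is a gene start rather than a CDS/UTR bin
(to avoid assigning sequence across an intervening gene). Two points the
interval rules leave open were resolved as follows: the gene-start guard
considers gene spans on the same strand as the site, because upstream and
downstream are strand-defined notions; and an APA-derived bin inherits *all*
transcripts of its boundary bin, since read counts in the new bin cannot
distinguish which isoform 3' end they extend. Unstranded annotations are
rejected for APA processing.

# Counting

Counting deliberately assigns each read once to **every** bin it overlaps
(≥ 1 bp): many bins are shorter than the read length, and fractional or
unique assignment would systematically under-count short bins. Column sums
can therefore exceed the number of reads. Overlap is evaluated against the
aligned CIGAR blocks, so intron-spanning reads do not count bins inside
their gaps; paired-end templates count once per bin hit by either mate;
unmapped, secondary and supplementary alignments are excluded; duplicates
are kept unless `dropDuplicates = TRUE` (deduplication of RNA-seq counts is
contentious and off by default); the MAPQ threshold defaults to 0. The
library size of a sample is its number of usable alignments, whether or not
they hit a bin.

# Pre-processing defaults

The chain upstream of the test is the conventional one for weighted linear
modeling of counts, with these recorded choices:

* **Filtering**: keep bins with ≥ 10 reads (CPM-equivalent at the median
  library size) in at least as many samples as the smallest group and ≥ 15
  reads in total (`edgeR::filterByExpr` defaults).
* **Normalization**: TMM with 30% trimming on M-values, 5% on A-values,
  reference library by the 75th-percentile rule
  (`edgeR::calcNormFactors`).
* **Precision weights**: `limma::voom` — log2((count + 0.5)/(effective
  library size + 1) × 1e6), lowess trend (span 0.5) of sqrt residual
  standard deviation on average log count, weights = inverse fourth power of
  the trend at each fitted count, clamped at the fitted range.
* **Empirical Bayes**: `limma::squeezeVar` moment estimator (non-robust by
  default; `robust = TRUE` is available but not the default, as the
  moment estimator is the conventional choice here).

# Gene-level effect sizes

The gene tables answer "is there a change"; for "how big and in which
direction", `geneEffectScores()` condenses bin coefficients with
significance weights $\omega_k = \min(-\log_{10} p_k, 10)$:
DEU mode averages $|\hat C_k|$ over tested bins with weights $\omega_k$;
UTR mode averages the *signed* $\hat C_k$ over UTR bins with weights
$\omega_k$, each contribution additionally multiplied by the bin width in
kilobases, so that long lengthened UTR segments dominate and positive scores
indicate 3' UTR lengthening. No canonical formula exists for this summary;
the one above (with its configurable cap, which prevents a single extreme
bin from dominating) is this package's documented choice.

# The simulator

`simulateUtrCounts()` emulates, at the count level, a two-condition
experiment in which some genes express a short/long 3' UTR isoform pair.
Each gene is laid out as CDS bins, one shared 3' UTR bin and, for UTR-change
genes, one to three distal 3' UTR segments — the "next, second next or third
next" downstream poly(A) segment — present only in the long isoform. Both
isoforms start at equal abundance; in condition 2 one isoform is up- and the
other down-regulated by the same fold change drawn uniformly from
[1.3, 5] (lengthening or shortening at random). Shared bins therefore shift
by $(f + 1/f)/2$ while long-only bins shift by $f$: the *relative* signal a
bin-vs-gene statistic must find. To make ranking non-trivial, 30% of the
UTR-change genes and an equal number of unaffected genes additionally
receive a whole-gene fold change (also U(1.3, 5), random direction) — a pure
expression change that a usage statistic must ignore. Counts are negative
binomial (dispersion 0.1, a typical bulk RNA-seq value) around log-normal
baseline bin means (median 150), 3 replicates per condition, and the latent
means are stored so tests can verify the mixture algebra exactly.

Defaults are 500 genes with 100 UTR-change genes — a 1:10 reduction of the
1000-transcript-pair benchmark design the simulator emulates, keeping its
proportions; at this scale generation takes about a second and the full
analysis a few seconds, so the whole benchmark is regenerated from its seed
on every run rather than stored.

What the simulator does *not* model: read-level effects (sequence errors,
positional/GC bias, mappability), partial coverage of bins, ambiguous gene
overlaps, and annotation errors. Passing benchmarks here demonstrates that
the statistics recover relative bin-usage changes from overdispersed counts;
it does not certify performance on real libraries, where bin preparation and
counting quality also matter.

# Worked example

```{r example, eval = FALSE}
library(binsplice)

## bins from an annotation plus poly(A) sites
toy <- makeToyAnnotation()
bins <- prepareBins(toy$gtf, apa = toy$bed)

## counts from BAM/SAM files would use countBinReads(bins, files, ...);
## here, a seeded benchmark with known differential UTR usage:
sim <- simulateUtrCounts(seed = 7)
res <- diffSpliceBins(sim$counts, method = "diffSplice2")
res <- utrGeneResults(res)

head(geneLevelResults(res, utr = TRUE))
topGenes(res, mode = "UTR", n = 10)
```

# Numerical and degenerate-input choices

* Bins with zero unscaled standard deviation (no estimable coefficient) are
  excluded with a warning; genes left with fewer than two usable bins are
  reported with `NA` statistics rather than silently dropped.
* If all residual variances are identical the empirical-Bayes prior df is
  infinite and every posterior equals the common value — handled, not an
  error. In that case the two statistics share identical $\hat C_k$ and
  differ only by the $\sqrt{1 - w_k/\sum w}$ factor.
* An APA site coinciding with an existing 3' edge creates no zero-width bin.
* All samples identical in a TMM input give unit factors; an all-zero
  sample keeps factor 1 with a warning.
* Bin identifiers are `gene:index` with bins sorted by (chrom, start, end,
  gene), making all outputs byte-stable across runs on identical input.

# Limitations

* The gene-start guard and transcript inheritance rules for APA extension
  are heuristics over ambiguous annotation semantics (documented above).
* The improved statistic trades bin-level calibration for gene-level
  ranking power, as quantified above.
* Only the moderated-t engine is implemented; negative-binomial GLM
  back-ends (edgeR/DEXSeq-style) are out of scope, as are APA site
  discovery from coverage and annotation liftover.
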