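---
title: "Screening for imprinted genes from opposing histone marks"
author: "imprintscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for imprinted genes from opposing histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The idea

Genomic imprinting silences one parental allele of a gene, so an imprinted
gene is expressed from a single allele in a parent-of-origin-dependent way.
Chromatin immunoprecipitation pools both alleles of a diploid cell: at the
promoter of an imprinted gene the expressed allele contributes marks of
activation (H3K4me3, H3K9Ac) while the silenced allele contributes the
repressive mark H3K9me3, and the pooled signal shows all three *at the same
promoter*. Biallelically expressed promoters show only the activation
marks, and fully repressed promoters at most H3K9me3. Concurrent,
transcriptionally opposing marks plus a promoter CpG island therefore
define an *ab initio* candidate set for imprinting -- no prior knowledge of
orthologous imprinted genes is needed. Candidates are then verified (or
rejected) by allele-specific expression in reciprocal crosses, which is
the only design that separates parent-of-origin effects from effects of
allele identity. Bisulfite clone sequencing of the promoter CpG island
asks whether differential DNA methylation accompanies the imprint.

imprintscan implements this whole chain as testable components plus a
synthetic-data generator with planted truth, so the strategy's operating
characteristics can be measured without any external data.

## Coordinates and promoters

All coordinates are 0-based half-open; BED input is native, GTF is
converted on read. One putative promoter per gene is anchored at the
annotated 5' end: 5,000 bases upstream to 500 downstream of the TSS
(`promoter_config()`, both adjustable). On the minus strand the window is
mirrored, so derivation is strand-symmetric under genome reflection.
Transcript-level promoters are out of scope; the single anchor keeps the
gene the unit of screening.

Overlap everywhere means "share at least one base" (half-open abutment is
not overlap), strand is ignored, and overlap counting is per source
interval, never per merged region. The engine is backed by IRanges and is
cross-checked in the test suite against a brute-force all-pairs
enumeration on a thousand random instances.

## The full-overlap refinement tier

Complete mutual overlap of the three marks' peaks is a stricter signature
than mere co-occurrence, and empirically enriches for genuinely
monoallelic candidates. "100 % overlap" is not well defined for peak
callers that never produce identical boundaries, so the package adopts the
strictest workable reading: per mark, select the peak with the longest
intersection with the promoter; the tier passes iff the shortest selected
peak is contained in every other selected peak (equivalently, the length
of the joint intersection equals the shortest peak's length). Ties on
intersection length break to the leftmost then shortest peak, making the
tier deterministic and invariant to mark ordering.

## Peak calling

The caller consumes binned fragment counts (default 50-bp bins) for a
treatment and an input track. Each bin is scored with the Poisson upper
tail `P(X >= count)` against a local background expectation: the maximum
of the genome-wide input rate and input rates over 5-kb and 10-kb windows
centered on the bin, scaled by the treatment/input depth ratio, and
floored at a pseudocount rate (0.1 counts/bin) so empty control regions
cannot produce p = 0. Bins at p <= 1e-5 are merged across gaps of up to
100 bp, and merged peaks shorter than 200 bp are dropped. These defaults
mimic common narrow-peak practice and are all exposed in
`peak_caller_config()`.

Because the expectation is normalized by the depth ratio, calls depend on
the control only through that ratio: rescaling the control track leaves
the output unchanged (a literal joint rescaling of both count vectors
changes Poisson power, as it must for any count-based test). Under the
null the significant-window rate is bounded well below 10x the threshold;
the suite verifies this on a million simulated windows. Fragment-size
modeling, duplicate filtering and FDR control are upstream of the
package's inputs and out of scope.

## The candidate screen

A gene is a candidate iff its promoter overlaps significant H3K4me3,
H3K9Ac and H3K9me3 peaks *and* an annotated CpG island. Genes known to be
imprinted but lacking the signature can be forced into the downstream
assays via `force_include` (sensitivity of the chromatin signature is not
assumed perfect). H3K27me3 can be profiled with `mark_distribution()` --
a diffuse mark mostly occupying intergenic space is useless for promoter
screening -- but never participates in selection.

Male-derived cells carry a single X, so every expressed X-linked gene is
monoallelic without being imprinted and a sound screen must call no
X-linked candidates; `haploid_control_check()` turns this into an
explicit internal control that fails the run when violated.

## Classifying candidates from reciprocal crosses

Genotypes are called from allele pileups by a fraction rule (minimum 20x
coverage; heterozygous when both alleles reach 20 % of reads) -- the 20x
floor is the canonical candidate-SNP rule, and likelihood-based genotyping
adds nothing at the depths simulated here. An F1's SNP is *trackable* when
the F1 is heterozygous and at least one parent is homozygous, so both
alleles have an unambiguous parental origin; a heterozygous F1 whose
allele is absent from both called parents is a Mendelian inconsistency and
aborts that gene's classification rather than being dropped silently.

Pyrosequencing replicates are averaged arithmetically; a spread above 3
percentage points raises a discordance flag. Per animal, bias is maternal
at >= 70 % maternal fraction and paternal at <= 30 %. The 70 % default
sits below the weakest imprinted observation the strategy is designed to
catch and far above binomial noise at realistic depths; it is
configurable, and when raw read counts are supplied an exact binomial
test against 0.5 (alpha 0.01) is additionally required. Gene calls:

* **imprinted** (maternal- or paternal-expressed): every informative
  animal biased toward the same parent, with informative animals in both
  cross directions;
* **allele-biased**: bias consistently tracks one stock's physical allele
  across both directions -- monoallelic but not imprinted;
* **biallelic**: every animal unbiased;
* **undetermined**: a single informative cross direction (bias cannot be
  attributed to parent or allele) or conflicting patterns.

Leakage -- residual expression of the repressed allele -- is reported as
the mean of `100 - expressed-allele fraction` over informative animals.

```{r classify}
classify_gene(data.frame(
  animal = c("a1", "a2"), cross_type = c("AxB", "BxA"),
  maternal_fraction = c(92, 77), maternal_stock = c("A", "B")))
```

## Bisulfite methylation

`tabulate_clones()` converts gaplessly aligned clone sequences into a
clones x CpG matrix (C = methylated, T = unmethylated at CpG cytosines).
Non-CpG cytosines act as conversion controls; clones converting fewer
than 98 % of them are excluded -- a standard QC threshold, exposed in the
interface. Regional state follows the mean per-CpG fraction: <= 0.2
hypomethylated, >= 0.8 hypermethylated.

When a phasing SNP partitions clones by allele (at least 5 passing clones
per allele, a repository default), each CpG gets a 2x2 exact test
computed as the one-sided hypergeometric tail in the direction of the
overall observed difference, with Benjamini-Hochberg correction across
CpGs. The region is a DMR iff more than half the CpGs pass adjusted
alpha = 0.01 *and* the mean between-allele fraction difference reaches
0.5. These thresholds make a qualitative judgment reproducible; the
per-CpG p-values are verified in the suite against full enumeration of
tables with fixed margins. Without a phasing SNP the verdict is
`not_assessable`, which is itself an informative outcome.

## The synthetic study and what it does (and does not) show

`truth_config()` fixes the study conditions: 5 autosomes of 2 Mb plus a
1.2-Mb haploid X; 500 genes (90 per autosome, 50 on X); class proportions
giving 5 maternally and 5 paternally expressed imprinted genes, 10
allele-biased, 150 repressed and 330 biallelic genes; expressed-allele
fraction 0.9 with per-animal spread 0.02 and beta-binomial overdispersion
0.01; ChIP background 10 fragments per 50-bp bin with 10-fold promoter
enrichment; 500-read pileups; two pyrosequencing replicates with 1-point
Gaussian noise (replicates agree within 3 points in ~97 % of pairs, by
the closed form); 16 bisulfite clones per allele at conversion rate
0.995. Imprinted and allele-biased promoters receive each mark at *half*
the homozygous fold -- each parental allele contributes one mark class to
the pooled ChIP -- which is exactly the quantitative signature the screen
exploits. Every stage is seeded through a single master seed and
reproducible byte for byte.

```{r run, eval = FALSE}
res <- run_all(truth_config(seed = 1))
score_truth_recovery(res)[1:4]
```

At these conditions the pipeline recovers 100 % of planted imprinted
genes as candidates with the correct parental direction, calls no
biallelic gene imprinted, and keeps the haploid chromosome clean. The
generator emulates the *structure* of real data, not its messiness: it
has no annotation error (real 5'-end misannotation moves promoters off
their true positions), no mappability or GC artifacts, no PCR or
allele-specific amplification bias, clean binomial pileups, and
enrichment folds that are homogeneous across genes. Passing tests
therefore certify the decision logic and its statistics, not performance
on a real genome, where sensitivity is bounded by annotation quality and
informative-SNP density.

## Numerical choices and degenerate inputs

Percentages are reported rounded to the nearest integer, ties away from
zero. Empty query sets yield a warned 0 % rather than NaN. The Poisson
tail is computed in the upper tail directly and is accurate to 1e-11
relative error down to the double underflow limit (~1e-300). Peak merging
is idempotent. Interval tables out of coordinate order are canonicalized
with a warning on read; empty intervals, inverted coordinates and unknown
chromosomes are hard errors naming the offending line. Problem sizes in
the test suite (a 500-gene genome, 1e6 null windows, 200 DMR replicates,
1,000 random oracle instances) are the package's chosen defaults for
exercising every claim at desk scale.

## Limitations

The package consumes binned coverage and pileup counts, not reads;
alignment, duplicate marking and fragment modeling are upstream. It
screens one promoter per gene, does not detect imprinting control regions
or clusters, and treats expression state as an input flag. The
allele-biased class is detected but not explained (no eQTL machinery).
DMR assessment requires a phasing SNP inside the amplicon -- as in real
studies, its absence leaves allele-specific methylation unresolved.
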