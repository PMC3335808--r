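---
title: "Digital gene expression tag profiling with TagDGE: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital gene expression tag profiling with TagDGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TagDGE)
```

# The assay and the pipeline

Digital gene expression tag profiling (DGEP) is a SAGE-style counting
assay: poly(A)+ mRNA is captured on oligo-dT beads, cut with NlaIII, and
the fragment downstream of each transcript's 3'-most CATG is tagged by
MmeI, which cuts 17 bp past the recognition junction. Each sequenced
molecule therefore contributes one 21-nt tag (CATG + 17 nt) read in the
sense orientation, embedded in a 35-nt read together with the 3'
adaptor. Counting tags counts transcripts.

TagDGE implements the complete downstream analysis for a
single-replicate time course — here four libraries sampled at 0, 24, 48
and 72 h of moss protoplast reprogramming into stem cells, but nothing
in the code is specific to that design beyond the four labels:

1. **Cleaning** (`cleanReads`): raw reads become a `TagLibrary` of
   distinct clean tags with copy numbers and per-stage loss counters.
2. **Mapping** (`buildVirtualTagDB`, `mapTags`): every CATG+17-nt
   window of every reference transcript forms a *virtual tag database*;
   clean tags are assigned to genes allowing at most one substitution,
   and tags matching several genes are discarded. Gene expression is
   the sum of its uniquely assigned tag counts (`GeneCountMatrix`, a
   `SummarizedExperiment`).
3. **Testing** (`tmmFactors`, `callDEGs`): TMM scaling factors convert
   raw library sizes into effective sizes; each gene is tested between
   consecutive libraries with the Audic–Claverie exact test, adjusted
   by Benjamini–Hochberg, and called up/down when
   $|\log_2 FC| \ge 2$, $P \le 0.01$ and $FDR < 0.01$.
4. **Enrichment** (`enrich`, `topTerms`, `pathwayHeatmapMatrix`):
   hypergeometric GO and Fisher pathway enrichment of each DEG set with
   BH Q values, enrichment-factor ranking, and a $-\log_{10}P$ matrix
   over significant pathways with average-linkage row ordering.
5. **Clustering** (`expressionProfiles`, `clusterProfiles`,
   `labelPatterns`): K-means (Lloyd, Euclidean, k-means++ restarts) on
   the DEG union's log2 expression profiles, with peak-time pattern
   letters A–F.

A synthetic-data module (`generateReference`,
`simulateExpressionProfiles`, `simulateTagLibrary`,
`simulateCountMatrix`) generates inputs with the statistical structure
the pipeline assumes, so that every stage is verifiable without any
sequencing download.

# Statistical models

## The exact test

Tag counts are modelled as samples of fixed size drawn from a large
population of transcripts. For a gene with count $x$ in a library of
(effective) size $N_1$, the count $y$ in a second library of size
$N_2$ has, under the null of equal expression, the conditional
distribution

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},$$

a negative binomial in $y$ with size $x+1$ and success probability
$N_1/(N_1+N_2)$. `exactTestP` returns the two-sided P value
$\min(1,\; 2\min(P(Y\le y),\, P(Y\ge y)))$. Both tails are accumulated
directly in log space; the upper tail is summed from $y$ to well past
the mean plus twenty standard deviations rather than obtained by
complementing the lower sum, so no catastrophic cancellation occurs
even for counts in the thousands (the test suite checks agreement with
the closed-form negative-binomial tails to $10^{-10}$ over a
200-case grid).

Two remarks on this statistic. First, doubling the smaller tail makes
the test valid but conservative on discrete data; under null
simulations at mean count 50 the fraction of raw $P \le 0.01$ is about
0.8–0.9%, comfortably inside the expected band. Second, the statistic
is *not* exactly invariant under swapping $(x, N_1)$ with $(y, N_2)$:
the swapped conditional pmf is proportional, not equal, to the
original, so the two orientations can differ by a factor approaching
the tail discreteness. The package treats the comparison as ordered
(earlier library first), which fixes the orientation once for the whole
analysis.

## TMM normalisation

With one library per condition and substantial asymmetric differential
expression, raw library sizes misstate the sequencing effort available
to non-changing genes. `tmmFactors` computes, per library against a
reference, gene-wise $M$ (log2 count ratio after size correction) and
$A$ (average log2 abundance) over genes expressed in both libraries,
discards the extreme 30% of each $M$ tail and 5% of each $A$ tail, and
averages the surviving $M$ values weighted by inverse asymptotic
binomial variance. Factors are rescaled to unit geometric mean, and the
exact test receives *effective sizes* = library size × factor. The
implementation is checked in the tests against an independent
from-definition recomputation and against edgeR's weighted TMM, with
which it agrees to $10^{-10}$ on spiked matrices.

## The fold-change threshold and the pseudo-count

The calling rule combines the exact test with an absolute log2
fold-change threshold of 2. For genes observed in both libraries the
ratio uses raw normalised counts; a pseudo-count of 1 is added to both
counts only when one of them is zero, so that the four-fold threshold
keeps its exact meaning for co-expressed genes while absent/present
contrasts remain finite. `logFoldChange` itself exposes the
unconditional pseudo-count formula for display purposes.

One consequence is worth stating plainly because the validation suite
measures it: when a true effect sits **exactly** on the threshold
(a 4.00-fold change against a $\ge$ 4-fold rule), the observed fold
change of a truly changed gene falls below the threshold with
probability close to 1/2 at *any* depth — the sampling distribution of
the estimate is centred on the boundary. In the recovery suite (20% of
genes changed exactly four-fold, all DE-gene means above 50 counts) the
significance component alone recovers essentially all true positives
(sensitivity ~1.0 at $P \le 0.01$, $FDR < 0.01$) and no false
positives, while the joint call including the fold-change threshold
recovers ~50%. This is a property of thresholding at the effect size,
not an implementation defect; effects clear of the boundary are
recovered with correspondingly higher joint sensitivity.

## Enrichment

For a DEG set, `enrich` restricts the universe to annotated genes: $N$
annotated background genes, $n$ DEGs among them, $M$ genes carrying
the term, $m$ DEGs carrying it. The GO P value is the hypergeometric
upper tail

$$P \;=\; 1 - \sum_{i=0}^{m-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}} \;=\; P(X \ge m),$$

summed in log space; the pathway P value is the one-sided Fisher exact
test on the equivalent 2×2 table, which coincides with the
hypergeometric tail (property-tested on random tables). The two
significance conventions differ deliberately: GO terms are flagged at
raw $P < 0.05$, pathways at BH $Q < 0.05$. $P(X \ge m)$ (rather than
$P(X > m)$) is used, so $m = 0$ gives $P = 1$ and adding one annotated
DEG can only decrease $P$. Ranking for reporting uses the enrichment
factor $(m/n)/(M/N)$, ties broken by smaller $P$, then term id.

## Clustering and pattern labels

`clusterProfiles` runs Lloyd's algorithm (via `stats::kmeans`) from
k-means++ seeds, keeping the best of `nInit` restarts by inertia,
deterministically for a given seed. The default input is
$\log_2(\mathrm{CPM}+1)$ on TMM effective sizes — tag counts on a log2
scale — for the union of DEGs across the three comparisons; the
common-reference transform (`toCommonReference`, every library
expressed as a log2 ratio to the 0 h library) is available as an
alternative input via `expressionProfiles(method =
"commonReference")`, since both representations are natural for
time-course clustering. Rows are not standardised by default; a
caller preferring unit-variance profiles can scale before clustering.

Pattern letters: a cluster whose centroid peaks at time point
$t \in \{1,2,3,4\}$ and is not a monotone trend receives A–D
respectively; monotone clusters (all consecutive steps beyond a
flatness tolerance of 10% of the centroid's range, in one direction)
and any surplus cluster sharing a peak with a larger one receive E, F,
… by decreasing size, ties broken by earlier peak. The tolerance
prevents a sharp peak followed by a flat tail from being read as
monotone when centroid noise tips the flat steps slightly downhill.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated:

* **Reference** (`generateReference`): uniform-composition transcripts
  (default 300–1200 nt), each guaranteed one taggable CATG (planted at
  a random admissible position when chance provides none, which at
  default lengths is rare — the expected site count is length/256).
  GO/pathway annotations are sampled per term with sizes uniform on a
  configurable range.
* **Truth** (`simulateExpressionProfiles`): a fraction of genes
  (default 0.2) is differentially expressed with consecutive-pair mean
  ratios of exactly `fold` (default 4, the calling threshold's
  effect size); DE genes follow six trajectory shapes — peaks at each
  of the four times, monotone down, monotone up — and non-DE genes are
  flat at `baseMean`.
* **Reads** (`simulateTagLibrary`): per-gene molecule counts are
  multinomial at fixed depth, matching the fixed-library-size
  conditioning of the exact test (not Poisson); each molecule emits
  its gene's 3'-most tag plus 14 nt of a fixed adaptor
  (`defaultAdaptor()`, shared with the cleaner); contamination is
  controlled by an adaptor-only read fraction, an ambiguous-base
  fraction (an 'N' placed inside the tag region), and an independent
  per-base substitution error rate over the whole read. Errors are
  substitutions only, because the mapper tolerates only substitutions.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: PCR duplication and amplification bias,
quality-score-dependent error profiles, indels, 3'-bias or incomplete
digestion (every molecule yields its 3'-most tag exactly), non-uniform
base composition, and biological replicate variability (each library
is a single multinomial draw, exactly the situation the
Audic–Claverie test assumes; real biological dispersion would inflate
its false-positive rate).

# Numerical and interface choices

* **Adaptor trimming** requires at least 10 nt of 3'-anchored
  agreement with the adaptor prefix. Without a minimum overlap, chance
  1–4 nt suffix matches would false-trim roughly a quarter of genuine
  tags; with 10 nt the chance rate is $4^{-10} \approx 10^{-6}$ while
  the true adaptor always offers its full 14 nt on an error-free
  read. This is the same device as cutadapt's minimum-overlap option.
* **Filter order is observable**: adaptor-only removal, trimming,
  ambiguous-base ('N') removal, length/CATG structure filtering, then
  per-library singleton removal, each with its own counter; a
  single-copy tag containing 'N' is charged to the quality stage, not
  the singleton stage. "Low quality" means precisely "contains an
  ambiguous base" — no quality-score filtering is done.
* **Mapping** resolves by best stratum: exact matches take precedence
  over 1-mismatch matches; at the best stratum a tag whose gene set
  exceeds one is discarded as multigene and excluded from the
  mapped-distinct count. The 1-mismatch search enumerates all 63
  single-substitution neighbours against a hash of the database —
  at these scales identical in contract to a BWT aligner. Antisense
  windows are not enumerated (the protocol captures sense-strand 3'
  fragments). Mapping rates are reported as percentages rounded to
  two decimals, halves away from zero.
* **Saturation** subsamples tag instances without replacement as
  prefixes of one seeded permutation, so each curve is non-decreasing
  by construction and depths are nested.
* **Determinism**: every stochastic function takes a seed and restores
  the caller's RNG state afterwards.

# Validation problem sizes

The test suite and the acceptance script validate at desk scale,
chosen so the whole suite runs in well under a minute of compute per
stage: 500-gene references with $10^5$ reads for exact end-to-end
conservation; 20 replicate null simulations of 2000 genes at mean
count 50 for calibration; three replicates of 2000 genes (20% DE,
exactly four-fold, all DE means above 50 counts) for recovery; 200
grid cases for the exact-test oracle; 100 random tables plus 20
planted-term replicates for enrichment; 300 genes over six planted
archetypes for clustering; and a 200-gene library at saturating depth
for the saturation plateau. Library-summary and DEG-overlap
arithmetic (mapping rates; three comparisons of sizes 1095/2059/1870
with 197 genes shared by exactly two and none by all three giving
4827 distinct DEGs) is checked exactly.

# Known limitations

* No biological replication: the exact test conditions on two fixed
  library sizes and attributes all variation to sampling; it should
  not be read as controlling biological false positives.
* No dispersion estimation or GLMs; no multi-factor designs.
* Flat annotation: GO terms are taken as given, with no DAG
  propagation.
* The virtual tag database covers transcript sequences only — no
  genomic, spliced or antisense mapping.
* K = 6 is a fixed default; no model selection (gap statistic,
  silhouette) is provided.
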