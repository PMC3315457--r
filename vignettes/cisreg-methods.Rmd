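---
title: "Methods: motif statistics, spacing constraints, and two-tissue co-expression modules"
author: "cisreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif statistics, spacing constraints, and two-tissue co-expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisreg)
```

# Scope and model

`cisreg` implements the statistics used to connect a transcription factor's
genomic binding (ChIP peaks) to hormone- and maturation-driven
transcriptional programs: motif-match calibration and scanning, peak-level
motif enrichment against matched background, a permutation test for
constraints on the spacing of heterotypic motif pairs, gene-list overlap
and attenuation arithmetic, peak-to-gene assignment and differential
binding, and a two-tissue coherent co-expression module pipeline. All
stages run on synthetic data with known planted structure, so every claim a
green test makes is a recovery of structure the generator wrote down.

# Motif model

A motif of width $w$ is a column-stochastic $4 \times w$ probability matrix
over A, C, G, T. Columns come either from counts or from an IUPAC consensus
(each position uniform over the code's allowed bases); in both cases a
total pseudocount weight $\varepsilon$ per column, distributed in
proportion to the background $\pi$, gives
$p_j = (c_j + \varepsilon\,\pi) / (n_j + \varepsilon)$.

A window $x_{1..w}$ scores $s(x) = \sum_j \log\!\big(p_j(x_j)/\pi(x_j)\big)$
in **nats**. Both strands are scanned; a reverse-strand site is reported at
the forward-strand start of its window, and windows containing non-ACGT
characters are skipped (masked-genome practice). Overlapping matches are
all reported; collapsing to per-sequence presence happens downstream.

**Threshold calibration.** The exact distribution of $s$ for a background
window is computed by positionwise convolution on a score grid (bin width
$10^{-3}$ nats), and the match cutoff for a tail probability $\alpha$ is
the smallest $t$ with $P(s \ge t \mid \pi) \le \alpha$. Because each column
score is rounded to the grid, a word's binned score can differ from its
true score by up to $w \cdot 10^{-3}/2$; the returned cutoff subtracts this
slack so no word of the qualifying bins is lost. Thresholds are therefore
accurate to about $w$ grid bins, which the brute-force enumeration tests
(all $4^w$ words, $w \le 8$) confirm, including identity of the induced
match sets. When even the single best word exceeds $\alpha$ (short or
degenerate motifs at stringent $\alpha$), the cutoff is placed just above
the maximal attainable score — an empty match set, not an error. Zero
probabilities at $\varepsilon = 0$ are floored at $-30$ nats, far below any
calibrated cutoff.

Tunables: $\varepsilon = 0.01$ (total pseudocount weight; the historical
scanning tools do not document theirs), natural-log scoring, default
$\alpha = 10^{-3}$, and a five-point threshold grid
$\{10^{-2}, 5\cdot10^{-3}, 10^{-3}, 5\cdot10^{-4}, 10^{-4}\}$ for
robustness screens. All are arguments, not constants.

# Peak enrichment and class association

For a motif $M$, each peak and each background sequence is classified
"present" (at least one match on either strand) or "absent", giving a
2×2 table tested by a two-sided Fisher exact test (point probabilities
$\le$ the observed table's are summed — the same convention as
`stats::fisher.test`, but implemented in-package and cross-checked in the
tests against explicit `choose()` summation on every table with total
$\le 50$). Background sequences are sampled one per peak with identical
length, uniformly over the genome (chromosomes weighted by length),
rejecting segments that overlap a peak or exceed 10% ambiguous bases; the
retry cap is 1000 per segment. Screens across a compendium report raw p and
BH-FDR q. Class-differential association replaces peak/background with a
two-class labelling of loci (e.g. the induction direction of the assigned
gene) and reports the over-represented class.

# Spacing-constraint test

Within each sequence, sites of the anchor and cofactor motifs are merged
and start-sorted; consecutive entries of *different* motifs form adjacent
heterotypic pairs. Spacing is **start-to-start**, signed so that a negative
value puts the cofactor left of the anchor. Pairs are classified by
$|d| \le 25$ bp versus $> 25$ bp. The null re-places every site's start
uniformly over the positions where its window fits (per sequence,
independently, preserving per-motif counts, widths and strands — shuffled
sites may overlap, which keeps the null exactly uniform; the paper-scale
convention of pooling 50 shuffled datasets is the default). Observed versus
pooled counts are compared by the same Fisher exact test. Zero observed
pairs return $p = 1$ with a flag rather than an error.

Design notes: shuffle streams are derived deterministically from the master
seed and shuffle index, so a result is reproducible from its metadata;
conditioning on per-sequence site counts makes the test exchangeable under
the null, which the calibration test verifies empirically (rejection at
$\alpha = 0.05$ within $[0.025, 0.075]$ over 500 uniform-placement
datasets).

# Gene-list statistics

*Expression filter*: a gene is expressed iff its count is strictly greater
than `min_reads` (default 5) in at least `min_libraries` (default 1).

*Overlap*: for lists of sizes $n$ and $K$ in a universe of size $N$ with
overlap $k$, fold enrichment is $k/(nK/N)$ and both hypergeometric tails
are reported. The universe is always explicit — the published analyses this
mirrors never state theirs, and printed fold enrichments imply different
universes across figures, so no attempt is made to reverse-engineer them;
the expression-filtered gene set is the natural default.

*Attenuation*: for genes activated by a treatment, count those with smaller
$|\log_2$ fold response$|$ under knockdown; ties are excluded but reported.
Two tests are emitted: an exact binomial against 0.5 (two-sided = twice the
smaller tail, capped at 1; the one-sided tail is also returned, since the
published figure for 27/33 attenuated genes is consistent with a one-sided
reading) and a Fisher comparison against a background gene set to exclude a
dataset-wide bias. Absolute-magnitude comparison was chosen because the
source analysis plots fold responses of activated genes.

# Intervals and differential binding

Peak unions use `GenomicRanges::reduce`. Target genes are assigned when the
edge-to-edge distance between peak and gene body is at most 10 kb,
inclusive at exactly 10 kb (whether the original rule measured from peak
edge or centre is not recoverable; edge-to-edge is the tiling-array
convention and is configurable). Differential binding per peak is a one-way
ANOVA on log2 intensities (identical to the equal-variance t-test for two
groups, an identity the tests assert to $10^{-9}$), with BH-FDR across
peaks. Binding-versus-expression correlation filters peaks at
$\ge 1.25$-fold difference and, when a gene is near several retained peaks,
uses the peak of maximal $|$fold$|$.

# Two-tissue co-expression pipeline

Both matrices are quantile normalized (columns mapped to the mean order
statistics; ties share averaged targets; the transform is idempotent and
matches limma's implementation). The pipeline then runs three nested
stages:

1. **Modules** (tissue A): unsigned adjacency $|r|^\beta$ with $\beta = 6$
   (field default; the source states no power), topological overlap
   similarity, average-linkage clustering of $1 - \mathrm{TOM}$, and a
   *static* cut (default height 0.95) — deterministic and simpler to test
   than dynamic tree cutting, which is out of scope. Clusters below 30
   genes go to an unclustered pool; constant genes are dropped with a
   warning.
2. **Tight clusters**: per module and candidate $k$, k-means is repeated on
   random 70% subsets of samples, giving a per-$k$ co-membership frequency
   matrix; maximal gene sets with all pairwise co-membership $\ge 0.7$
   (size $\ge 3$) are extracted greedily. The smallest $k$ whose sets cover
   $\ge 60\%$ of the module is kept — the coarsest *stable* sub-structure —
   and a module with no stable split stays whole ($k = 1$, where
   co-membership is trivially 1, so the consensus threshold is still
   honoured). The original tight/coherent clustering software is cited in
   the source without algorithmic detail; this is a reconstruction of its
   stated intent, and all thresholds are arguments.
3. **Coherent clusters** (tissue B): within each tight cluster, iteratively
   remove the gene with the lowest mean correlation to the others in tissue
   B until every survivor has mean correlation $\ge 0.5$ to the rest;
   survivors are "coherent", removed genes (or wholly failed clusters) are
   tissue-A-specific. The per-gene criterion was chosen over a cluster-mean
   stopping rule deliberately: a cluster-level mean crosses 0.5 while a few
   uncorrelated genes are still attached, so it does not recover planted
   half-shared structure; requiring each survivor to be coherent with the
   rest does, and reads more directly as "co-expressed with each other in
   both tissues". Coherent plus specific genes exactly partition every
   tight cluster — an invariant the tests assert as set identity.

Module enrichment for gene lists is per-module Fisher exact within an
explicit universe (enriched: raw $p < 0.05$ and odds ratio $> 1$, matching
the source's calling criterion), with BH-FDR across tests; module-level
contingencies (e.g. coherent-vs-specific × hormone-enriched) are tested by
Yates-corrected chi-square and Fisher exact.

# What the generators emulate — and what they do not

*Sequences*: Markov-0 background with one GC parameter; planted sites are
maximal-scoring words (ties resolved randomly), and planted pairs are
joint words satisfying both motifs simultaneously at an exact signed start
spacing (incompatible motif pairs are an error, not silently degraded
sites). Real genomic background is richer (repeats, composition domains,
conserved elements), so enrichment p-values here are cleaner than on real
peaks; a green recovery test establishes correctness of the machinery, not
field-realistic power. Truth tables record planted sites only — background
can by chance contain more matches, so recovery assertions use "at least
the planted" logic.

*Expression*: a single-factor model per module, $a f_m + \epsilon$ with
$f_m, \epsilon$ Gaussian; shared modules reuse the same factor realization
in both tissues, non-shared modules are pure noise in tissue B. Expected
within-module correlation is $a^2/(a^2+\sigma^2)$, which the tests use as
a closed-form oracle. Real tissue pairs have correlated noise, partial
sharing and nonlinear effects; the generator's defaults (60 samples — the
profiled cohort size — loading 1, noise 0.5) were fixed once as a
plausible desk-scale world and are not tuned per test.

*DE tables*: list sizes and pairwise overlaps are realized exactly
(overlap sets for different pairs kept disjoint; infeasible systems are
rejected), and fold changes of co-listed genes are bivariate normal with
the requested correlation. FDR values are drawn below 0.1 for listed genes
and above 0.3 otherwise, so the `fdr < 0.1` rule reconstructs the lists.

# Numerical choices and degenerate inputs

- Score grid $10^{-3}$ nats; threshold error bounded by about one bin per
  column (see above). Exact mode requires $w \le 16$.
- Fisher two-sided: sum of point probabilities $\le$ observed $\times$
  $(1 + 10^{-7})$; the tolerance guards floating-point ties.
- Zero-variance vectors in any correlation are an error, not NaN; empty
  joins and single-class inputs error with a named cause.
- All randomness flows from explicit integer seeds; child streams are
  derived as `(seed mod 1000003) * 2011 + index mod 104729`, keeping every
  derived seed below $2^{31}$.

# Known limitations

- Static tree cut and fixed $\beta$; no soft-threshold diagnostics, module
  eigengenes, or dynamic cutting.
- The spacing test conditions on the scanned site set; it does not model
  scanning uncertainty (the five-threshold screen is the robustness check).
- The exact score distribution assumes an i.i.d. background; higher-order
  composition shifts calibrated tails slightly on real genomes.
- Venn construction supports 2-3 lists; the DE-table generator realizes
  pairwise (not triple) overlap constraints.
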