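---
title: "Co-conservation and coevolution of regulatory SNP-gene pairs: methods"
author: "coevoqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-conservation and coevolution of regulatory SNP-gene pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoqtl)
```

## The scientific question

An eQTL interaction is a statistical association between the genotype at
a locus (usually a SNP) and the expression of a gene. If such
interactions are functional, the SNP's neighbourhood and the gene's
regulatory region should experience linked selective pressure: they
should be *co-conserved* (their conservation classes should be
associated) and *coevolved* (their divergence patterns across a species
panel should be correlated). coevoqtl implements the full analysis
chain for both questions, plus the practical payoff: using coevolution
scores to prioritize cis-eQTL association tests so that the
multiple-testing burden falls on the pairs most likely to interact.

Because the real inputs (a 100-vertebrate whole-genome alignment,
dbSNP, GTEx nominal p-values) are large and partly controlled-access,
the package ships a fully seeded synthetic-data generator that emulates
their statistical structure with known ground truth. All claims the
test suite makes are claims about this synthetic system; what that does
and does not imply about real data is discussed at the end.

## Conservation profiles and co-conservation

A conservation profile is the vector of per-base PhyloP-like scores at
a width-1 locus and its 1000 bases up- and downstream — 2001 values,
oriented 5'→3' in transcriptional direction for stranded loci (TSSs)
and in reference orientation for SNPs. Positive scores mean
conservation, negative mean acceleration, 0 a neutral rate; an
uncovered base is *missing* (`NA`), never 0, because 0 carries meaning.

The 2001 values are reduced to 19 by logarithmic binning: the locus
base sits alone in the centre bin, flanking bins double in size (2, 4,
..., 256) moving outward, and the outermost bin on each side absorbs
the remaining 490 bases:

```{r}
profile_bin_sizes()
sum(profile_bin_sizes())
```

This layout is the unique outward-doubling scheme with a centre bin of
1 and 9 bins per side that sums to 2001. Binning gives the positions
nearest the locus the most weight in downstream clustering. Missing
bases are excluded from their bin's mean; a bin with no observed base
is `NA` and is imputed (by the profile's own mean) only at the
clustering step.

Binned profiles are clustered with Euclidean k-means, K = 2, best of 10
seeded restarts by within-cluster sum of squares. K = 2 reflects the
two recurring shapes in this kind of data — a flat near-neutral profile
and a conserved one — and K remains configurable. The centroid with
the larger mean over its 19 bins is labelled `high_conservation`; ties
break by centre-bin value, then index (arbitrary but deterministic).

Co-conservation of eQTL pairs is then a 2×2 contingency table of
interactions (counted per pair, not per unique locus) by SNP class ×
gene class, tested with a df = 1 chi-squared. The Yates continuity
correction is on by default — on the published table of counts it is
the corrected statistic (23.651, p ≈ 1.155e-6) that reproduces the
reported result, while the uncorrected form gives ≈ 23.94:

```{r}
fit <- chi_squared_yates(contingency_from_counts(428, 7544, 1775, 40975))
c(statistic = round(fit$statistic, 3), p = signif(fit$p_value, 4))
```

Distribution comparisons use the two-sample Kolmogorov-Smirnov test.
One-sided alternatives are phrased in terms of values (`"a_less"` =
sample A stochastically smaller), which maps onto the ECDF-based
convention of `stats::ks.test` with the opposite keyword; the wrapper
hides that inversion because it is a recurring source of sign errors.

## Similarity matrices from a whole-genome alignment

For each locus a window of ±`flank` bases (a tunable, since no single
window size is canonical) is sliced out of the MAF blocks in one
serial pass — overlapping windows do not trigger re-reads. Columns
where the reference is gapped are excluded, so every subalignment has
exactly `interval length` reference-anchored columns.

The species×species similarity matrix of a window holds pairwise
*match rates*: the fraction of the window's columns where both species
are present, ungapped, and carry the identical nucleotide
(case-insensitive; ambiguity codes such as N never match anything,
including themselves — a conservative, deterministic rule). The
denominator is always the full window length, so a species with a
missing alignment scores exactly 0 against every other species, and
the diagonal stores each species' presence fraction. Identity fraction
was chosen over scoring-matrix or affine-gap alignment scores because
it is parameter-free and satisfies the two properties the downstream
score relies on: high values = high match rates, and missing data = 0.
The species panel order is fixed package-wide so matrices from
different windows are position-compatible.

## Coevolution: sparse correlation of similarity matrices

The coevolution score of two loci is the Pearson correlation of their
similarity matrices over the off-diagonal upper triangle, computed
*after discarding every entry position where both matrices are exactly
0*. Shared zeros encode shared missingness (species absent from both
windows), and under a full correlation many such pairs manufacture
spurious agreement, inflating the score toward +1; dropping them is
what makes the score robust. Exact equality to 0 is the right test —
match rates are rational counts over the window length, and true zeros
arise only from absence or total mismatch — so no epsilon is involved.
The diagonal is excluded because it encodes presence, not pairwise
divergence, and would correlate trivially.

A score is undefined (`NA` with a reason) when fewer than
`min_entries = 3` entry pairs remain (two points always correlate
perfectly) or a retained vector is constant. Undefined scores are
excluded from histograms and never enter prioritized subsets; they are
reported by count. Negative correlations are retained as-is. The
classical full correlation is kept alongside for comparison, and the
package's tests assert the separating property directly: appending
co-zero species leaves the sparse score unchanged to 1e-12 while the
full score strictly inflates.

Scoring a catalog of n SNP-gene pairs costs O(n·l²) for an l-species
panel; all-pairs mode over s SNPs and g genes costs O(s·g·l²). When a
gene has several annotated promoters, the SNP-promoter score of the
gene is the maximum over its promoters' defined scores (the working
assumption being that an eQTL acts through one promoter); backgrounds
built under this max rule are accordingly right-shifted relative to
single-window backgrounds, which the tests check as a stochastic
dominance property.

## Prioritizing eQTL tests: BH and the β/γ identity

The Benjamini-Hochberg step-up rule is implemented exactly as the
strict-inequality form: sort p-values ascending, find the largest K
with P(K) < Kα/n, reject the K smallest, and report P = Kα/n as the
significance threshold (0 if K = 0; α defaults to 0.05). A flag
switches to the conventional `≤` variant; the two differ only on exact
ties P(K) = Kα/n, which the tests exercise. Since decimal p-values and
the cutoffs Kα/n are not exactly representable in binary floating
point, both sides are compared as single products (p·n vs K·α) and
values within 1e-9 relative are treated as tied; otherwise an intended
tie resolves by rounding noise.

For a prioritization that retains a fraction γ of all hypotheses and a
fraction β of the full catalog's rejections, the prioritized threshold
satisfies P' = βKα/(γn), hence P'/P = β/γ: the threshold relaxation
*is* the enrichment of the retained set for significant interactions.
`enrichment_ratio()` reports both sides and their gap; on constructed
catalogs where BH lands exactly on the planted boundary the identity
holds to 1e-12.

Two controls isolate what score prioritization actually contributes:
uniform random downsampling (which leaves the BH threshold essentially
unchanged, because K and n shrink proportionally) and distance
matching. Distance matching keeps the largest smallest-distance prefix
whose mean distance does not exceed the target — a deterministic rule
chosen over random matching for reproducibility. Tests with undefined
scores stay in the full-catalog BH but are never retained by score
prioritization.

## The synthetic data generator

The generator is first-class, tested code; its defaults are the
package's study conditions and were fixed once, on the following
reasoning, at a desk scale that preserves the structure of the real
problem while keeping runs at minutes:

* **Panel and genome**: l = 20 species on a coalescent tree rescaled to
  0.75 substitutions/site root-to-tip (a vertebrate-like divergence
  spread), a 200 kb single-chromosome genome, 200 SNPs and 40 genes on
  alternating slots, 20 planted coevolved SNP-gene pairs. 20 species
  keeps l(l−1)/2 = 190 matrix entries per score — enough for stable
  correlations — while 200 kb × 20 species simulates in seconds.
* **Sequence evolution**: Jukes-Cantor substitution via
  `phangorn::simSeq` on per-region rescaled trees. The match-rate
  similarity needs no richer model. Each region draws an *evolutionary
  context*: per-branch rate multipliers ~ Gamma(0.35, 0.35) (mean 1,
  variance ≈ 2.9 — strong heterogeneity so regions decorrelate from
  the shared tree) and a dropout pattern deleting each non-reference
  species with probability 0.3. A planted pair's two regions share one
  context; everything else draws independently. Both channels matter:
  shared rates drive the sparse correlation up, shared dropout feeds
  exactly the co-zero entries that sparse correlation must discount.
  Background blocks evolve at baseline rate with 5% dropout. No indel
  evolution is simulated; gap handling is exercised by hand-written
  fixtures instead.
* **Conservation track**: baseline N(0, 0.5) noise (PhyloP-like
  scale). High-conservation SNPs get a Gaussian flank bump of height 2
  (half-width 200 bp) with the locus itself pulled to −1.5 — a
  conserved neighbourhood around an accelerated common variant.
  High-conservation TSSs get a sigmoid ramp rising to 2 into the gene
  body, oriented by strand. Half of each locus set is high
  conservation.
* **eQTL catalog**: every SNP×gene pair (all cis at this genome size;
  the 1 Mb cis window is enforced). A pair is a true eQTL with
  probability 0.05, elevated 5-fold for planted coevolved pairs. True
  pairs draw p ~ Beta(0.1, 1) (a standard one-parameter small-p
  model), null pairs p ~ Uniform(0, 1). The 5-fold factor makes β > γ
  at high score thresholds by construction, so the threshold curve
  rises — the direction, not the magnitude, is the tested claim.

Everything is deterministic given the seed: layout, contexts, sequences,
track, catalog. The three sub-generators use fixed small offsets of
the master seed so they can also be called independently.

What the synthetic system does *not* emulate: linkage disequilibrium
among SNPs, indels and rearrangements, realistic phyloP score
distributions, distance-dependent eQTL probability (available in the
test fixtures but off by default), promoter-gene coupled evolution, and
any calibrated effect size for how strongly real eQTL pairs coevolve —
no such estimate exists to calibrate against. Green tests therefore
demonstrate that the algorithms recover planted structure of the
stated kind and obey their contracts, not that real eQTL pairs carry a
signal of any particular strength.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based formats (WIG fixedStep) happens only in the readers/writers.
* Missing track values are `NA`, never 0.
* `bin_profile` requires exactly 2001 values; profiles at chromosome
  edges carry `NA` and remain usable.
* k-means: missing bins imputed by profile mean; fewer profiles than K
  is an error; seeded restarts make the fit reproducible.
* Sparse correlation: undefined-score reasons are ordered — too few
  retained entries is checked before zero variance.
* BH with K = 0 reports threshold 0; enrichment ratios against a K = 0
  full result are undefined (`NA`) rather than infinite.
* Distance matching errors when the target lies below the minimum pair
  distance.
* The background scorer refuses to exceed its combination budget unless
  subsampling is explicitly enabled (seeded, reproducible).

## Problem sizes used by the test suite

Unit tests run on small fixtures (≤ 6 species, ≤ 20 hypotheses,
20-60 kb genomes). The end-to-end checks use the default 200 kb / 20
species / 200 SNP genome for planted-pair recovery, a 10⁵-test catalog
for downsampling stability (median over 50 downsampling seeds), and
500 seeds for the null-catalog FDR property. These sizes were chosen to
make sampling error small relative to the margins being asserted while
keeping the whole suite in the low minutes.
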