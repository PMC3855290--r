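---
title: "Two-locus epistasis scanning, interaction networks and window annotation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-locus epistasis scanning, interaction networks and window annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinetscan)
```

# The problem

Single-locus genome-wide association scans of a quantitative trait — here the
motivating case is abdominal fat weight (AFW) in a divergently selected
broiler chicken cross — capture only the marginal effect of each marker.
Pairs of loci whose joint genotype affects the trait beyond their marginal
effects (statistical epistasis) are invisible to them.  `epinetscan`
implements the full chain of a pairwise epistasis study: quality control of a
SNP panel, an exhaustive two-locus interaction scan with a
Kempthorne-style partition of each interaction, Bonferroni control over the
enormous number of tests, contribution rates on the scale of percent
phenotypic variation, construction of the SNP–SNP interaction network with an
entropy-motivated subnet score, and annotation of the implicated genomic
windows.

# The two-locus model

For a SNP pair the phenotype is modelled as

$$y = \mu + \mathrm{SNP}_1 + \mathrm{SNP}_2 +
      \mathrm{SNP}_1{\times}\mathrm{SNP}_2 + F + e,$$

with $F$ a family effect and $e$ Gaussian error.  The single-locus genotypic
effects are carried by two contrast columns per locus:

* **additive** $a$: the minor-allele count centred by its observed mean;
* **dominance** $d$: the heterozygosity indicator orthogonalised
  (Gram–Schmidt) against the constant and additive columns *under the
  observed genotype frequencies*.

Because the orthogonalisation uses observed rather than Hardy–Weinberg
frequencies, the partition remains valid under Hardy–Weinberg disequilibrium,
and because each pair is fitted jointly, linkage disequilibrium between the
loci is absorbed by the main-effect columns rather than leaking into the
interaction.  At equal allele frequencies in HWE the codes reduce to the
classical orthogonal polynomials $(-1, 0, 1)$ and
$(-\tfrac12, +\tfrac12, -\tfrac12)$.

The two-locus interaction is spanned by the four products
$a_1a_2,\; a_1d_2,\; d_1a_2,\; d_1d_2$ — the additive×additive (AA),
additive×dominance (AD), dominance×additive (DA) and dominance×dominance
(DD) one-degree-of-freedom epistatic effects.  `test_pair()` reports

* the **overall interaction test**: the model-comparison $F$ between the full
  model and the main-effects model, with numerator degrees of freedom equal
  to the number of estimable interaction columns (4 when all nine genotype
  cells occur);
* a **per-effect 1-df $F$** on each interaction column's marginal
  (drop-one) sum of squares in the full model.

When a genotype cell is unobserved, the four product columns span fewer than
four dimensions.  Aliased columns are then removed from the working design
and reported as untestable; leaving a redundant column in place would let it
absorb the marginal sum of squares of the column actually being tested.
Similarly, a locus with only two observed genotype classes has no estimable
dominance contrast, and every effect requiring it is flagged untestable
rather than imputed.  Pairs where a locus is monomorphic among the pair's
complete cases are skipped with a logged reason; missing genotypes are
handled complete-case within each pair.

## Family effect: fixed absorption by default

The generative model treats family as a random effect.  The scan's default
(`family_mode = "fixed"`) absorbs family as fixed covariates: with a handful
of families the conditional $F$-test is the standard equivalent, it is exact
under Gaussian errors, and it is what an exhaustive scan over millions of
pairs can afford.  `family_mode = "random"` offers the literal alternative: a
one-way random intercept fitted by REML (`lme4`), with the same contrasts
tested on the family-adjusted phenotype.  The two modes select the same
effects on planted signals; their contribution rates differ by construction,
because the family-adjusted phenotype has the family variance removed from
the denominator.

## Multiple testing

With $M$ markers and four effect tests per pair the scan performs
$4\,M(M-1)/2$ tests; `bonferroni_pairs()` divides the familywise level by
that count.  At $M = 45{,}611$ and $\alpha = 0.05$ this gives
$4.16\times10^9$ tests and a threshold of $1.20\times10^{-11}$ — the
reference arithmetic for the full-size design.  Threshold comparison is
strict (`P < threshold`), and each of the four effects is thresholded
separately, which is the only reading under which the $4\times$ multiplier in
the test count is coherent.

## Contribution rate

The contribution rate of an effect is
$c = 100 \cdot SS_{\text{effect}} / \sum_i (y_i - \bar y)^2$ — the percent of
total phenotypic variation explained by that single degree of freedom.  The
total *corrected* sum of squares is used as the denominator deliberately:
it makes $c$ a variance-explained percentage and reproduces the ~1% scale of
published contribution rates for effects of this size.

# The synthetic cohort

`sim_config()`/`generate_genotypes()`/`generate_phenotypes()` emulate the
study design so every stage is testable without external data:

* **Genotypes.** Per-SNP minor allele frequencies are drawn from a
  configurable law (default uniform on $[0.05, 0.5]$, the post-QC floor);
  genotype frequencies follow $p^2+D,\; 2pq-2D,\; q^2+D$, so a Hardy–Weinberg
  departure $D$ can be planted ($D$ is feasible iff
  $-\min(p^2,q^2) \le D \le pq$; infeasible values are rejected).  Optional
  LD blocks copy a founder haplotype signal with a per-site mutation
  probability tuned to the target $r^2$ (sites in a block share a MAF and sit
  in HWE) — simple, controllable, and sufficient to exercise the
  0.2 Mb-window logic.  Missing calls are masked independently (default 1%).
* **Families.** Equal-sized, assigned at random, one Gaussian draw per
  family.  The reference design's 475 individuals come from a line cross
  whose family count and sizes are not part of the public record, so both
  are free parameters; the default of 10 families is a plausible sibship
  structure for a cohort of this size.
* **Phenotypes.** $y$ is the sum of the grand mean, optional main effects,
  planted epistatic effects, the family draw and Gaussian noise.  Planted
  effects multiply the *same* frequency-orthogonal contrast products the
  analysis side estimates, so planted and recovered effects are
  commensurable, and the realized contribution of each planted pair is
  reported.  `effect_size_for_contribution()` converts a target
  percent-of-variance into an effect size using the realized contrast-product
  variance.

What the generator does **not** emulate: realistic recombination maps (LD is
block-uniform), selection across generations, sex-chromosome dosage, related
founders, genotyping-batch artefacts, and non-Gaussian trait distributions.
Passing tests on this cohort therefore demonstrate the correctness and
calibration of the statistics under the stated model, not robustness to
every feature of real genotyping data.

# Network and subnet importance

Significant pairs form an undirected graph: one node per SNP, one edge per
distinct unordered pair (parallel records collapse to the most significant
one; self-loops are rejected).  Connected components with at least
`min_nodes` nodes are the *subnets*.  The default `min_nodes = 3` keeps
3-node subnets, matching reference reports that list them despite prose
describing "more than three nodes"; the printed table wins over the prose.
A component is a *tree graph* iff its edge count is one less than its node
count, otherwise a *loop graph*.

The importance of a subnet aggregates each edge's statistical information
weighted by its explanatory share:

$$w = \sum_{i=1}^{n} c_i \,(-\log_{10} p_i),$$

with $c_i$ the edge's contribution rate as a proportion and $p_i$ its
P-value.  $-\log_{10} p$ is the information content (in decimal digits) of
the test result, so $w$ reads as contribution-weighted evidence; it is
additive over edges, increasing in each $c_i$ and decreasing in each $p_i$.
This functional form (including the base-10 logarithm) was fixed by
validating it against all nine published subnet scores, which it reproduces
within ±0.002 — the slack induced by the 2-decimal rounding of the published
contribution rates; one reference subnet (printed 0.837) reproduces as
0.836 for exactly that reason.  Subnet letters are presentation labels; the
implementation orders components deterministically (descending node count,
then smallest member SNP id) and the regression tests match rows by the
chromosomes each subnet spans.

Exports are viewer-ready plain files: a SIF edge list plus node- and
edge-attribute tables, with nodes binned by significance
($P<10^{-13}$ red, $<10^{-12}$ blue, $<10^{-11}$ green, $<10^{-10}$ white)
and edges coloured by effect type.

# Window annotation

All coordinates are 1-based inclusive; BED input (0-based half-open) is
converted exactly at the reader boundary.  Around every mapped significant
SNP a 0.4 Mb *fragment* is centred (clipped at position 1) — the half-width
of 0.2 Mb matching the distance over which mean composite $r^2 > 0.8$
justifies transferring annotation from a marker to its neighbourhood.
Overlapping or touching fragments on a chromosome are union-merged into
*regions* (touching intervals merge because the union-set language implies
it and no published region contradicts it); each region records its member
SNP set.  Regions are therefore never narrower than 0.4 Mb, and a region is
exactly 0.4 Mb iff it holds one SNP (or coincident SNPs).

SNPs are mapped to QTL intervals by inclusive containment (many-to-many).
Genes are assigned to regions by any-overlap (≥1 bp), separating coding from
non-coding; the alternative per-SNP rule (gene within 0.2 Mb of a member
SNP, strict) is available via `genes_in_regions(by = "snp")` because merged
regions can extend farther from an individual SNP than its own window.
Pathway membership is tallied from a local gene-to-pathway mapping — counts
only, no enrichment statistic, since none is defined for this design.
Unmapped SNPs (chromosome `"UN"`) and unmapped genes are listed, never
silently dropped.

The QTL intervals, gene intervals and pathway mapping shipped under
`inst/extdata/` are **synthetic stand-ins** (the real resources are live
databases): they are constructed so that the published hub-subnet gene set
and the insulin/Jak-STAT pathway groupings are reproduced, and their
filenames say so.  Likewise the shipped SNP position table is a
reconstruction — exact where a published single-SNP region pins the marker at
its centre, exact at the extreme markers of each multi-SNP region,
interpolated or invented elsewhere — suitable for the window geometry, not
for genome annotation.

# Numerical choices

* Least squares via pivoted QR (`qr`), rank-deficiency detected from the
  pivoted rank; per-effect sums of squares by explicit column-drop refits.
* An interaction sum of squares below $10^{-12}\times$ the phenotypic SS is
  snapped to zero with $F=0,\ P=1$, so a noise-free purely additive surface
  reports $P = 1$ rather than 0/0.
* Chromosome labels are opaque strings ordered 1–28, linkage groups, Z, UN,
  then the pseudo-label 0 — the mixture that real chicken-chip tables use.
* Pair records are canonicalised so locus 1 precedes locus 2 in genome
  order; exchanging the loci swaps the AD and DA labels consistently.
* With a fixed seed every generator and the whole pipeline are
  bit-reproducible; result tables are byte-identical across reruns.

# Problem sizes used in the shipped analyses

The checked-in analysis scripts and tests run at desk scale, chosen so the
whole suite exercises every code path in well under half an hour on one
core: cohorts of 300–2,000 individuals, panels of tens to a few thousand
markers, scans over at most a few thousand pairs, 1,000 null replicates for
the type-I-error calibration and 20–50 seeds for recovery and
variance-decomposition checks.  The full-size design (45,611 markers,
$10^9$ tests) is represented by its arithmetic and by the fixture-mode
regression tests, because the original genotype data are not publicly
deposited; the headline biological result is therefore covered by the
deterministic network/annotation reproduction plus planted-signal recovery
on synthetic cohorts, not by a re-scan of the real data.

# Known limitations

* The exact internal normalisation of the original scan software under
  strong LD is not publicly specified; the regression formulation above is
  this package's documented contract, validated against the reproducible
  outputs (thresholds, network statistics, subnet scores).
* The random-family mode adjusts by a one-way REML fit before contrast
  testing; it is a fidelity option, not a full mixed-model scan.
* Higher-order (three-way and beyond) interactions, permutation thresholds
  and covariates beyond family are out of scope.
* Published marker counts contain a small internal discrepancy (45,611
  analysed vs 45,005 chromosome-assigned plus 606 unplaced); it is noted
  here and left unresolved, as it does not affect any computation.
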