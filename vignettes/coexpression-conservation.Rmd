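---
title: "Cross-species co-expression conservation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species co-expression conservation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two species — say human and mouse — are compared through their gene
co-expression maps, the question is not whether single genes are conserved
in sequence, but whether their *interactions* are conserved: does a gene
keep the same co-expression neighbourhood after ~90 My of divergence?
`coexcons` implements a pipeline around one conservation statistic, the
number of **commonly co-expressed genes (CCG)** of a homologous gene pair,
and a set of companion statistics (differential network connectivity,
duplication and non-homolog proportions) that together let tissue, pathway
and disease gene sets be ranked by cross-species conservation.

## The co-expression map

Input is a compendium of expression datasets per species (gene × condition
matrices).  Within each dataset every gene is discretized per condition to
*up* / *down* / *neutral* relative to its within-dataset median.  For a gene
pair, pooled over all conditions of all datasets,

* C = number of conditions where both genes move in the same direction,
* D = number of conditions where both are non-neutral but move oppositely,

and the co-expression score is the vote-counting frequency

$$s_{ij} = \frac{C}{C + D} \in [0, 1], \qquad s_{ij} = 0 \text{ when } C + D = 0.$$

Two normalization readings are possible for a vote count "normalized by how
often the genes were not co-regulated": the frequency C/(C+D) and the
unbounded ratio C/D.  We use C/(C+D) because it satisfies the map contract
(scores in [0, 1]) and is invariant to compendium size; C/D diverges as
soon as D = 0.  The neutrality band `neutral_epsilon` defaults to 0 (strict
sign split): with continuous expression values exact ties with the median
are rare, and a strict split is the most literal reading of "up- or
down-regulated together".  The band is exposed for integer-valued or
heavily tied data.

## CCG: conservation of co-expression connectivity

For each gene the top `p` % of its co-expression partners are selected
(`p = 5` by default), with the list length defined as `floor(p/100 × N)`
over the *full* map universe N (non-homologs included) — over a
22,766-gene universe this gives 1138 partners.  Ties at the cut are broken
by ascending gene ID so lists are byte-reproducible.

For a homolog pair (a, b), CCG counts the members of a's top list that have
at least one homolog (any relationship class) in b's top list.  A list
member with several matched homologs contributes once: CCG counts
*genes*, not homology edges.  Gene-level CCG aggregates a gene's pair
values with `max` by default — a gene is ranked by its best-conserved
relationship — with `mean` available.  For pure one-to-one homology the
statistic is symmetric under swapping species; for one-to-many homology the
A-side counting convention is kept and documented rather than symmetrized.

The association between CCG and molecular evolution rate (dN/dS) is
measured with Spearman's rho and an empirical permutation p-value: the
second vector is permuted B = 10,000 times and
$p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(B+1)$.  The add-one
convention keeps p ≥ 1/(B+1) and reproduces the conventional "< 1e-04"
bound when no permutation reaches the observed value.

## Directed networks and DiffK

A directed network is extracted at a 1 % threshold: arc i → j iff i is in
j's top-1 % list.  Every gene then owns exactly `floor(m/100)` incoming
arcs, so total arc count is fixed by construction — an identity the test
suite checks exactly.  Connectivity k(i) is the number of *other genes'*
lists containing i (row sum of the adjacency matrix); this direction-
resolved reading produces variable, hub-capable degrees consistent with the
scale-free behaviour of co-expression networks, and the log–log
least-squares slope of the degree histogram is reported as a diagnostic
(not an inferential power-law fit).

Because percentage thresholds make arc counts scale with network size, raw
degrees of species 2 are rescaled by the ratio of list lengths onto the
species-1 scale before comparison.  We rescale raw counts rather than
dividing by list size so that the +10 pseudocount of DiffK stays on a
count-like magnitude; both choices give identical within-species rankings,
and rankings are what downstream tests consume.  DiffK is

$$r = \frac{k_1 + 10}{k_2 + 10}, \qquad v = \begin{cases} r & r \ge 1 \\ -1/r & r < 1 \end{cases}, \qquad \text{folded} = \begin{cases} v - 1 & v > 0 \\ v + 1 & v < 0. \end{cases}$$

Folded DiffK is 0 iff the normalized connectivities are equal, positive
when species 1 is more connected, and exactly antisymmetric under species
swap.  For gene-set evaluation a multi-pair gene's DiffK is the mean of its
pair values (the `max` rule is reserved for CCG, where it ranks a gene by
its best-conserved relationship; for a signed quantity like DiffK the mean
preserves the sign semantics symmetrically).

## Homology classes and dN/dS

Relationship classes are decided at the level of connected components of
the bipartite pair graph: `many2many` when the component has a multiplied
gene on both sides, `one2many` when only one side is multiplied anywhere in
the component, `one2one` otherwise.  This component rule matches how
Ensembl-style labels behave — e.g. the pairs (h1,m1), (h1,m2), (h2,m1) are
all many2many even though (h2,m1) is locally unambiguous.  Pairs with
dS = 0 or missing rates are kept in homology counts but excluded from all
ratio analyses (the ratio is undefined, the homology is still real).

Class-wise dN/dS distributions are compared with a Kruskal–Wallis omnibus
test and post-hoc pairwise Mann–Whitney tests, Bonferroni-corrected by
multiply-and-cap.  Mann–Whitney uses exact enumeration when both groups
have ≤ 20 untied observations and the midrank normal approximation
otherwise (the tied-small-sample corner falls back to the approximation,
which is R's standard behaviour).

## Gene-set evaluation

Each collection (tissues, pathways, diseases as GMT files) is restricted to
the analysis universe first, then sets with fewer than 10 remaining genes
are dropped (strict "less than"; a raw-size counting mode is exposed since
published pipelines are often ambiguous here).  Four parameters per set:

1. **ccg_conservation** — two-sided Mann–Whitney of gene-level CCG, set vs
   remaining scored genes; effect = median difference.
2. **differential_connectivity** — same test on folded DiffK.
3. **duplication_ratio** — Fisher's exact test of the proportion of
   duplicated homologs (one2many/many2many), set vs remaining homologs.
4. **nonhomolog_ratio** — Fisher's exact test of the proportion of
   non-homologous genes over the full species-A universe.

The Mann–Whitney parameters are run both on all homologs and on one-to-one
orthologs only.  Benjamini–Hochberg correction is applied across sets
separately per (parameter, homology-mode) family — the natural reading of
"for each set of p-values" — and significance is flagged at FDR < 0.05.

Candidate-gene association: for a set, every non-member gene appearing in
the CCG overlaps of the set's pairs is scored by its relative frequency
(overlaps containing it / set pairs).  The null redraws pair subsets of the
same size (pairs, not genes, so one-to-many structure survives in the
null), with a one-sided empirical p (enrichment is the biological claim)
and BH correction across the set's candidates.

## The synthetic world

`generate_world()` emits everything the real-mode readers consume:
expression compendia for two species, a homology TSV, gene sets as GMT.
Its model: species-A genes are partitioned into co-expression modules plus
unstructured background; expression is module latent activity (standard
normal per condition) plus N(0, σ²) noise, with σ = 1 by default — a
signal-to-noise ratio of 1, typical of what survives microarray
normalization.  Each species-B homolog keeps its source module with
probability 1 − z(module) and is otherwise reassigned uniformly; z per
module is spread evenly over [0.05, 0.95] by default so the world contains
a full conservation gradient.  dN/dS per pair is Gamma(shape 2) with mean
0.10 + 0.15 z plus class offsets (+0.05 one2many, +0.10 many2many),
matching the observed right-skew of dN/dS distributions and the class
ordering; it is the simplest mechanism that reproduces the sign structure
(CCG negatively associated with dN/dS) without claiming realism.  The
homology mix defaults to 70 % one2one, 8 % one2many, 6 % many2many, 16 %
non-homologous, roughly the human–mouse proportions.

The standard world (2000 genes, 40 modules of 25, 50 datasets × 10
conditions) leaves half the universe as pure-noise background.  That is the
right stress test for the CCG–dN/dS sign recovery, but it is *not* usable
for planted-set recovery: a "diverged" module gene has the same
random-overlap CCG as a noise gene, so against a background-dominated
universe the Mann–Whitney has no signal — by construction, not by
implementation defect.  Real transcriptomes are predominantly
module-structured, so the planted-set recovery world puts 500 of 600 genes
into modules.  Planted sets are the union of the two lowest-z modules
(conserved), the two highest-z modules (diverged), a draw of duplicated
homologs (duplication-enriched) and 20 random null sets.

What a green recovery test establishes: the pipeline detects conservation
differences that exist by construction, at the stated world's effect sizes,
and stays calibrated on null sets.  What it does not establish: robustness
to batch effects, platform differences, non-Gaussian noise or overlapping
module membership — none of which the generator emulates.

## Numerical choices and degenerate inputs

* All tie-breaks (top lists, ranked extremes, quantile bins) are by gene ID
  so outputs are byte-reproducible; the bottom-extreme tie-break is by
  *descending* ID so that under total ties the top and bottom lists are
  disjoint.
* Quantile bins use the largest-remainder rule (n = 10, k = 4 → sizes
  3,3,2,2).
* Constant genes within a dataset discretize to all-neutral and simply
  contribute no votes; genes never co-observed score 0.
* Permutation p-values always use the add-one convention; permutations
  permute the second argument only; every random step takes an explicit
  seed.
* `shapiro.test` caps n at 5000; larger samples are tested on a
  deterministic systematic subsample and flagged.
* Degenerate Fisher margins return p = 1 with the odds ratio flagged 0/∞.

## Known limitations

* Upstream co-expression databases document their vote-counting
  normalization only loosely; per-dataset averaging variants are not
  implemented here.
* CCG for non-one2one homology is A-side counting; the symmetrized variant
  is not implemented.
* The power-law diagnostic is a least-squares slope, deliberately not a
  maximum-likelihood exponent with goodness-of-fit machinery.
* Enrichment analysis itself (DAVID/GSEA) is out of scope; the pipeline
  exports ranked extreme gene lists for external tools.
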