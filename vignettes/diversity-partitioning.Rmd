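---
title: "Partitioning taxonomic, functional, and phylogenetic diversity along a depth gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning taxonomic, functional, and phylogenetic diversity along a depth gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divpart)
```

## The question and the approach

Whether deeper, less disturbed parts of a reef system can hold — and
eventually replenish — the biodiversity of their shallow counterparts is a
community-level question: it is not enough that deep sites are rich, their
assemblages must *contain* the shallow ones taxonomically, functionally,
and phylogenetically.  `divpart` implements the analysis pipeline for this
question on site-by-species count data split into a shallow (< 30 m) and a
deep (≥ 30 m) category: coverage standardization, Hill-number diversity of
three kinds, multiplicative alpha/beta/gamma partitioning, additive
pairwise beta decomposition, trait-level contrasts, and nonparametric
group comparisons.

The 30 m boundary is the conventional upper limit of mesophotic reefs.
Reefs recorded at exactly 30 m are classified deep
(`assign_depth_category()`); when a metadata file already carries a
category column it takes precedence over the computed rule.

## Coverage standardization

Sampling effort in visual censuses is hard to equalize, so samples are
standardized by *completeness* instead of size.  `sample_coverage()`
implements the singleton/doubleton estimator

$$\hat C_n = 1 - \frac{f_1}{n}\,\frac{(n-1)f_1}{(n-1)f_1 + 2 f_2},$$

which estimates the fraction of total community abundance represented in
the sample.  Two numerical conventions matter:

* with no singletons ($f_1 = 0$) the sample is declared complete,
  $\hat C_n = 1$, including the $f_1 = f_2 = 0$ case where the formula is
  0/0;
* a sample of a single individual ($n = 1$, $f_1 = 1$) also leaves the
  bracket 0/0; it is defined as $\hat C_n = 0$ (maximally incomplete, the
  limiting behavior of the estimator as $n \to 1$) with a warning.

Reported percentages are rounded half-up to the integer, except values
above 99%, which keep one decimal — otherwise nearly complete and
complete samples become indistinguishable in reports.

## Hill numbers and the three dimensions

All diversity measures are Hill numbers, chosen because they satisfy the
replication principle and share the unit "effective number of equally
abundant elements".  The order $q$ tunes abundance sensitivity: $q = 0$
counts elements (rare species dominate), $q = 1$ weights by abundance
(typical species), $q = 2$ emphasizes dominants.  $q = 1$ is always
evaluated through the analytic Shannon limit, never by a
nearly-one approximation; $0^0$ is treated as 0, i.e. only species that
are actually present enter any sum.

*Functional* diversity builds on a Gower distance matrix over six
categorical traits (water-column position, habitat use, body-size class,
mobility, trophic category, spawning mode).  `gower_distance()` treats
`size_class` as ordinal by default — body-size classes are ordered length
intervals, so adjacent classes should be closer than distant ones — and
the other five traits as nominal 0/1 mismatches; `ordinal = character(0)`
restores the all-nominal reading, since a defensible case can be made for
treating every qualitative trait symmetrically.  Ranks are taken over the
full closed level set, not the observed levels, so distances do not change
when a level happens to be unobserved.  Missing trait values are excluded
pairwise from the Gower mean (never zero-filled), and a pair with no
shared non-missing trait is an error.

The functional Hill diversity $^qFD(Q)$ normalizes pairwise distances by
Rao's quadratic entropy $Q = \sum_{ij} d_{ij} p_i p_j$.  At $q = 0$ it is
the total functional distance among present species — note the scale:
summed over ordered pairs, it grows roughly with richness squared, so
values in the thousands are expected for species-rich pools.  A
functionally monomorphic community has $Q = 0$; its diversity is defined
as 0 with a warning rather than an error, so pipelines survive degenerate
sites.

*Phylogenetic* diversity is computed from branch lengths $L_i$ and branch
abundances $a_i$ on an ultrametric tree, as the mean-lineage form
$^q\bar D(T)$ — the effective number of maximally distinct lineages over
the root-to-tip interval $T$.  The total-branch-length variant
$T \cdot {}^q\bar D(T)$ is exposed as `mode = "total_branch"` because both
conventions circulate and published values are sometimes on the
branch-length scale; beta is identical under the two.  $T$ is fixed to
the root age of the supplied tree.  Ultrametricity is checked within a
relative tolerance (default $10^{-6}$ of root age).  Species absent from
the tree are dropped with renormalized abundances and a logged
mass-removed figure (`reconcile_tree()`); a strict mode errors instead.
A basal polytomy is accepted as a hard polytomy at the root.

## The multiplicative partition

For a region of $N$ sites, gamma is the Hill diversity of the pooled
assemblage and alpha the weighted within-site diversity; beta =
gamma/alpha is the effective number of completely distinct communities
and lies in $[1, N]$ under equal site weights.  The weighting of sites in
the pool is a genuine analytical choice: equal weights match the
"effective number of communities" reading and are the default; abundance
weights (`weighting = "by_abundance"`) make gamma the diversity of the
raw pooled counts.  Because the choice is consequential and often left
implicit in published analyses, `run_analysis()` reports both.  Gamma at
$q = 0$ is identical under either weighting (the richness of the union),
which is why the census-level gamma values are reported at $q = 0$.

The functional partition follows the attribute-diversity construction, in
which alpha aggregates species *pairs* across sites; its beta is in units
of effective numbers of distinct pairs and ranges over $[1, N^2]$, not
$[1, N]$.  The pipeline labels it accordingly to prevent conflation with
the taxonomic and phylogenetic betas.

## Pairwise beta and its components

The additive decomposition works on presence/absence (the $q = 0$
perspective): total Sørensen dissimilarity splits into a turnover
component (Simpson dissimilarity, insensitive to richness difference) and
a nestedness-resultant remainder.  The Sørensen family is used rather
than Jaccard because only there does "total beta = turnover + nestedness"
hold in the form adopted here.  Presence means count ≥ 1.

Regional summaries average the components over within-shallow,
within-deep, and shallow×deep cross pairs separately, with a seeded
percentile bootstrap over pairs (default 9,999 resamples) for 95%
intervals.  Site pairs sharing a site are not independent, so these
intervals are descriptive; that caveat is inherent to pairwise summaries
of this kind.

## Group comparisons

"Is diversity higher in deep sites?" is asked with a one-sided two-sample
rank-sum (Mann–Whitney) test.  The U statistic counts (x, y) pairs with
x > y (ties ½), so U ranges over $[0, n_1 n_2]$ — with 8 shallow and 14
deep sites, $[0, 112]$.  The null is the exact enumeration when both
samples are small ($n_1 + n_2 \le 12$) and untied, and the
tie-and-continuity-corrected normal approximation otherwise.  At the
survey's sample sizes the attained one-sided type-I error at
$\alpha = 0.05$ is within Monte-Carlo error of the nominal level (checked
by simulation in the test suite, 10,000 null replicates).

Spatial autocorrelation of composition is screened with a Mantel test
(Pearson correlation of distance matrices, seeded joint row/column
permutations); the composition dissimilarity defaults to binary Sørensen
but is configurable, since no single choice is canonical.

## The synthetic metacommunity generator

Site-level inputs (the per-reef count matrices) are typically not
publishable in full, so the package treats the generator as a first-class
module: it defines the study conditions under which the pipeline is
validated.  Defaults mirror the reference survey design — 8 shallow plus
14 deep sites whose depths follow the survey's depth list (2–62 m), 85
species, a lognormal regional abundance distribution (sdlog 1.2, strong
dominance plus a rare tail), and about 170 expected individuals per fully
suitable site, which yields realistic singleton/doubleton counts and
per-site coverages in the 0.9 range.

Three mechanisms are implemented:

* **species sorting** — Gaussian depth niches with random optima and
  sd 8 m (narrow relative to the 60 m gradient), Poisson counts; different
  depths select different species, so pairwise beta is
  turnover-dominated;
* **mass effects** — one regional pool; shallower sites retain only the
  most abundant fraction of it (linear thinning from 0.2 to 1 along
  depth) *without* renormalization, so poor sites hold fewer individuals
  and species and their composition is nested in rich sites: cross-depth
  beta is nestedness-dominated;
* **neutral** — identical expectations everywhere; regional beta
  approaches 1 as counts grow.

Poisson observation is the simplest integer-count model consistent with
max-N census data; a binomial `detection` thinning is available.  The
generator intentionally omits features of real census data — spatial
dispersal kernels, behavioral detection biases, temporal turnover — so
passing its tests demonstrates correctness of the estimators and the
direction of mechanism signatures, not field realism.  Trait simulation
can make the ovoviviparous spawning mode exclusive to deep-niche species,
mirroring the kind of depth-linked trait exclusivity seen in real reef
fish, which makes the CWM contrast detectable by design.

## Numerical choices and degenerate inputs

* $q = 1$ by analytic limit everywhere; $|q - 1| < 10^{-8}$ is treated as 1.
* $0^0 = 0$ for absent species in every power sum (a subtlety that
  matters at $q = 0$ in the weighted alpha sums).
* All-zero species columns are kept (flagged) but never enter relative
  abundances; a site with zero total abundance is invalid.
* Counts must be integers within $10^{-8}$; species names are matched
  after whitespace trimming only — no fuzzy matching.
* Ties in the thinning ranks of the mass-effects generator are broken by
  first occurrence, keeping output deterministic under a fixed seed.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed, and `run_analysis()`
writes byte-identical outputs on reruns with the same inputs and seed.
The test suite validates the estimators against independent brute-force
transcriptions of the formulas (1,000 random instances for the taxonomic
and pairwise-beta measures, several hundred for the functional and
phylogenetic ones), checks the replication principle, bounds, and
invariances, and verifies mechanism recovery over 50 seeded generator
replicates per scenario and rank-sum calibration over 10,000 null
simulations — sizes chosen so the whole suite runs in about a minute on
one core while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* Coverage is reported, not corrected for: no coverage-based rarefaction
  or extrapolation of Hill numbers is performed.
* Regional gamma at $q = 1, 2$ depends on the site-weighting choice as
  soon as site totals differ; both weightings are reported, and neither
  should be compared against published values without knowing the
  convention used there.
* Functional diversity handles categorical traits only; mixed or
  quantitative traits, dendrogram-based FD, and the FRic/FEve/FDiv family
  are out of scope.
* The Mantel screen and the pairwise bootstrap both treat pairs as
  exchangeable units; neither is a substitute for an explicit spatial
  model.
* Tree estimation and calibration are upstream concerns: the package
  consumes a ready ultrametric Newick tree.
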