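---
title: "Methods: population structure, barcode delimitation and paleoclimate hindcasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, barcode delimitation and paleoclimate hindcasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skyisland)
```

`skyisland` chains the computational stages used in phylogeographic studies
of montane ("sky island") species pairs: SNP-based population structure,
DAPC-style genetic clustering, COI barcode species delimitation, and an
ensemble paleodistribution engine driven by a benthic d18O curve. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, what the synthetic-data generators do and do not
emulate, and the known limitations.

## Allele-level AMOVA and Phi statistics

`amova()` decomposes molecular variance hierarchically (among groups, among
populations within groups, within populations) from squared pairwise
differences, with Phi statistics and permutation tests.

The units of the decomposition are **allele copies**, not individuals: each
diploid contributes two copies per locus. This choice matters. For
biallelic dosage data, an individual-level decomposition of summed dosage
differences estimates roughly `2F/(1+F)` where the allele-level
decomposition estimates the fixation index `F` itself, which is the scale
on which pairwise F_ST tables and published Phi statistics are reported.
All stratum sums of squares are phase-free: the summed pairwise allele
differences within any set of individuals depend only on per-locus allele
counts, so unphased genotypes are sufficient. For two individuals with
dosages `a` and `b` at a locus, the four between-individual allele pairs
contribute `a(2-b) + b(2-a)` differences and the within-individual pair
contributes `a(2-a)`.

Numerical choices:

* Missing data: a pair's difference count is rescaled by `L / L_shared`
  (total loci over loci genotyped in both). The behavior of the reference
  implementations is not printed in the source material, so the rescaling
  is switchable (`rescale = FALSE`).
* Negative variance components are retained as computed, which keeps the
  decomposition exactly invertible against the definitional double sums;
  `truncate_negative = TRUE` floors them at zero before forming Phi.
* Unequal sample sizes enter through the standard mean-square coefficients
  computed from allele counts per population and group.
* Permutation schemes follow the hierarchical level of each statistic:
  Phi_ST permutes individuals among populations, Phi_CT permutes whole
  populations among groups, Phi_SC permutes individuals among populations
  within groups; `p = (#{perm >= obs} + 1) / (B + 1)`. The default is
  `B = 10000` permutations; a seed is mandatory whenever `B > 0`.
* A total variance of zero makes every Phi undefined and raises an error
  rather than returning `NaN`.

`pairwise_phi_st()` runs the one-level decomposition on every population
pair. Negative pairwise estimates are reported both raw and floored at
zero (the common display convention), together with Slatkin's
linearization `F/(1-F)` and per-pair permutation p-values.

## Per-locus statistics and the exact Hardy-Weinberg test

`locus_statistics()` reports the alternate-allele frequency, observed
heterozygosity, unbiased expected heterozygosity
`He = 2p(1-p) n/(n-1)` on `n` allele copies, per-site nucleotide diversity
(equal to unbiased He at a biallelic site), and `Fis = 1 - Ho/He` (left
`NA` at monomorphic loci). The Hardy-Weinberg test is the conditional
exact test on allele counts — the p-value sums the probabilities of all
heterozygote counts no more likely than the observed one, with no mid-p
correction — because the per-population samples these analyses run on are
typically far too small for the chi-square approximation.

`filter_loci()` reproduces the completeness semantics of common RAD/GBS
locus filters: keep a locus genotyped in at least `min_presence` of the
individuals of a population, in at least `min_populations` populations.
Both knobs are exposed (defaults 0.5 and 6) and nothing is hard-coded,
since published pipelines vary in which filter produced their final
matrix.

## DAPC-style clustering

`genotype_pca()` mean-imputes missing dosages, centers, and extracts
principal axes with a deterministic sign convention (the
largest-magnitude loading on each axis is positive). `kmeans_bic_scan()`
scores k-means solutions with `BIC(k) = n log(WSS/n) + k log(n)` and picks
the minimizing `k` (ties to the smaller `k`). This spherical-cluster BIC
is well behaved when tens of axes are retained — in low dimension it is
known to overcluster, because splitting an isotropic Gaussian along one
axis removes a large share of a small total variance. The package
therefore retains 40 axes by default in the pipeline stage; the tests use
the same dimensionality.

`dapc_fit()` runs linear discriminant analysis on the retained axes.
Membership probabilities are the softmax of `-d^2/2` where `d` is the
Mahalanobis distance to each cluster centroid in discriminant space
(where the pooled within-class covariance is spherical, Euclidean
distance *is* Mahalanobis distance). The a-score — mean over clusters of
the observed reassignment rate minus the permuted-label reassignment
rate — quantifies discrimination beyond overfitting; `optimize_n_pcs()`
maximizes it over a grid of retained-axis counts.

## Barcode analyses

`k2p_distance()` implements the Kimura 2-parameter distance
`d = -log(1-2P-Q)/2 - log(1-2Q)/4` with pairwise deletion: any site where
either sequence carries a gap, `N`, `?` or an IUPAC ambiguity is excluded
before the transition proportion `P` and transversion proportion `Q` are
computed. Saturated pairs (`1-2P-Q <= 0` or `1-2Q <= 0`) raise an error
by default; `k2p_matrix(on_saturation = "na")` records them as `NA`
instead. Percent summaries are rounded to two decimals for reporting.

`barcode_gap_partition()` is an initial-partition analogue of automatic
barcode gap discovery. For each prior maximum intraspecific distance `P`
(default: ten log-spaced values, 0.001-0.1) the sorted pairwise distances
are scanned for the first gap that is wider than both
`relative_gap_width` (default 1.5) times the mean spacing of the smaller
distances and the prior itself, with the gap's upper edge beyond `P`;
the matrix is then cut by single-linkage at the gap midpoint and the
procedure recurses once inside each group. The consensus partition is the
modal partition across the prior grid. Finding no gap returns a single
group — a valid result, and the expected one when intra- and
interspecific distances overlap (as they do when the modal haplotype is
shared between species). The full iterative-prior refinement of the
original method is deliberately not reproduced.

`parsimony_connection_limit()` returns the largest number of mutational
steps for which the estimated probability of a strictly parsimonious
connection exceeds `confidence` (default 0.95). The estimator assumes
Jukes-Cantor sites with Poisson substitution counts: the per-site
intensity is solved so the expected proportion of visibly different sites
matches the observed proportion, and the parsimony probability is the
probability that every differing site was hit exactly once and every
matching site never, computed in log space (so the limit degenerates to
the sequence length as the confidence approaches zero). This is the
package's own estimator in the spirit of classical statistical parsimony;
it is deliberately conservative relative to the original software's
tables by a few steps at typical barcode lengths.

`build_parsimony_network()` builds the minimum spanning network: every
minimum-spanning-tree edge plus every tie-equal alternative (an edge of
weight `w` joins the network iff its endpoints are disconnected using
only edges of weight `< w`), restricted to edges within the parsimony
limit. This is a documented approximation of probabilistic cladogram
estimation; haplotype counts and step counts are comparable, the internal
node-placement of median networks is not attempted.

## The paleodistribution engine

`run_paleo_enm()` chains:

1. **Climate PCA** (`climate_pca()`): variables are z-scored over the
   non-masked cells of the present-day stack and reduced to `n_axes`
   (default 5) axes; anchors are projected with the *present* centers and
   scales so scores are comparable across times.
2. **Forcing interpolation** (`fit_forcing_interpolation()`): per cell and
   axis, ordinary least squares of axis score on the d18O value at the
   anchor times. With two parameters and typically four anchors,
   higher-order fits would overfit and are not offered. When anchors are
   exactly affine in the forcing the fit is exact, and hindcasts reproduce
   the anchors to machine precision — the synthetic generator constructs
   such worlds, which pins down this part of the chain numerically.
3. **Hindcasting** (`hindcast_axes()`): `axis(t) = intercept +
   slope * d18o(t)` over the default grid of 1-ky steps to 600 ky BP and
   2-ky steps from 602 to 786 ky BP — 694 time slices.
4. **Models**: five presence-only algorithms (see `fit_niche_model()`) on
   a 70/30 train/test split and a seeded uniform background sample
   (default 10000 cells, capped at the grid size; the background size is a
   package choice, flagged because the source procedure does not state
   one).
5. **Thresholding and evaluation**: per-algorithm maximum
   sensitivity+specificity thresholds (ties to the lower, more inclusive
   cutoff) against the background; evaluation with `D = TPR (1 - pi)`,
   which rewards hitting the held-out presences while penalizing
   indiscriminately large predictions.
6. **Committee**: a cell is a consensus presence when at least
   `ceiling(A/2)` of the `A` binarized maps agree (3 of 5 by default).
   `mis_aggregate()` then composites the per-slice maps into glacial and
   interglacial presence frequencies using a stage table.

Two implementation details deserve emphasis. Memory-based similarity
models score their own training points perfectly, so the domain
algorithm's training scores are computed leave-one-out before
thresholding; otherwise max-SSS drifts to the degenerate top score and
test sensitivity collapses. And the one-class SVM is fitted in the PCA
axis space *as given* (no per-feature re-standardization), with the
kernel width set from the mean axis variance: re-scaling by the training
standard deviation would turn low-variance axes into high-precision
location fingerprints and make any projected climate fall outside the
learned envelope.

The marine-isotope-stage table shipped in
`system.file("extdata", "mis_stages.csv", package = "skyisland")` holds
the 19 stage boundaries over 0-790 ky (odd stages interglacial) as
commonly tabulated from the benthic d18O stack; any table with the same
columns can be passed instead. For synthetic forcing curves,
`classify_stages()` derives stages as runs above/below the 30th
percentile of d18O — over the late Pleistocene, interglacial stages
occupy roughly the warmest third of time.

## What the synthetic generators emulate

`simulate_hierarchical_genotypes()` draws a two-level Balding-Nichols
island model: Beta-distributed group and population allele frequencies
with variances `F p (1-p)` controlled directly by `fct_target` and
`fsc_target`, then binomial genotypes. The defaults (2 groups x 3
populations x 20 individuals, 2000 loci, `fct = 0.30`, `fsc = 0.02`)
reproduce the differentiation regime of a two-species, three-mountain-
range system: interspecific pairwise F_ST near 0.3, intraspecific near
0.02. Balding-Nichols was chosen over coalescent simulation because the
acceptance question is parameter recovery, not genealogical realism;
missingness is completely at random, and the completeness filter — not
structured missingness — emulates locus-filtering pipelines.

`simulate_barcode_alignment()` emulates a barcode locus under incomplete
lineage sorting: with `shared = TRUE` a guaranteed plurality of both
species carries the identical ancestral haplotype and everyone else is at
most `max_subs = 6` substitutions away, so intra- and interspecific
distances overlap and no barcode gap exists; with `shared = FALSE` the
second species descends from an ancestor 40 substitutions away, producing
a clean gap.

`simulate_climate_history()` builds a montane world in which every
variable at every time is exactly affine in the forcing. Its structure
encodes, deliberately, the features that let a five-axis PCA and
presence-only models see the montane dynamic:

* **Terrain**: one conical massif (on a cone, the area between two
  elevation contours grows quadratically as they descend) plus four
  mid-height satellite cones that are too warm for the species today and
  become habitable under glacial cooling. Hypsometry is the mechanism of
  glacial range expansion.
* **Temperature family** (~11 of 19 variables): lapse-rate fields tied to
  elevation, cooling near-coherently with d18O at 1.7 degC per per-mil
  (~3 degC at a full glacial, the mainstream tropical estimate).
* **Precipitation family**: broad sub-regional moisture gradients with
  weak, broad forcing slopes.
* **Factor structure**: all anomaly and moisture fields are smooth
  low-frequency surfaces, Gram-Schmidt-orthogonalized against elevation
  and each other. Real bioclim stacks are low-rank (a handful of broad,
  mutually decorrelated climate gradients span them, because the PCA
  domain is continental); without this structure the trailing principal
  axes degenerate into per-variable noise fingerprints that no displaced
  range can match, and every envelope-style algorithm contracts under any
  climate shift regardless of the terrain.
* **Forcing**: a sawtooth d18O cycle (slow glaciation, rapid
  deglaciation, 100-ky pacing plus a weak 41-ky harmonic), so
  intermediate-to-cold states occupy most of each cycle, as in the
  benthic record.
* **Niche and occurrences**: a Gaussian niche centered on the present-day
  climate of an upper-flank cell (the species occupies highlands today),
  with a joint temperature tolerance of ~1.5 degC; present-day
  occurrences are sampled without replacement proportionally to true
  suitability, at most one per cell.

What passing tests on this world do **not** show about real data: the
generators have no dispersal limitation, no biotic interactions, no
spatial sampling bias beyond grid de-duplication, linkage-free loci, and
a forcing relationship that is exactly linear per cell — so the engine's
exactness results certify the numerics, and the glacial-expansion
property certifies that the chain preserves a dynamic that was *built
into* the world, not that any real species behaved this way.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run entirely on synthetic data
at desk scale: AMOVA oracle checks on 200 random instances of at most 12
individuals and 30 loci; Phi recovery on 2 x 3 x 20 individuals and 2000
loci across 20 (tests) or 5 (script) seeds; 10000 loci for the
Hardy-Weinberg size check; DAPC selection across 20 simulated species
pairs; and the paleo engine on 40 x 40 grids with 19 variables, a 6-ky
hindcast step for the glacial/interglacial contrast, and the full 694-
slice grid asserted by count. These sizes are the package's own choices
for fast, deterministic verification; all of them scale up by argument.

## Known limitations

* The AMOVA assumes biallelic SNPs coded as dosage; haplotype-based F
  statistics are out of scope.
* The barcode-gap procedure implements the initial partition only; the
  original method's recursive prior updating can split finer.
* The parsimony connection limit is an estimator of the same quantity as
  classical statistical parsimony software, not a reimplementation of its
  published table values.
* The maxent-like algorithm is a ridge-penalized presence/background
  logistic model over linear and quadratic features — a functional
  stand-in for the reference maximum-entropy implementation, adequate for
  committee membership but not feature-for-feature comparable.
* Rasters are unprojected lon/lat only; cell areas use a
  cosine-of-latitude correction and no datum transformations are
  attempted.
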