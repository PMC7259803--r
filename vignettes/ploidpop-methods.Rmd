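---
title: "Models and design decisions in ploidpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in ploidpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidpop)
```

ploidpop implements the analysis chain used to study mixed-ploidy species
complexes from targeted-capture sequencing: ploidy assignment from allele
frequencies at biallelic sites, inference of tetrasomic versus disomic
inheritance in tetraploids, locus-wise population-genetic summary
statistics on phased haplotype alignments, gene-tree-space conflict
analysis, and statistics linking habitat-suitability change to demography.
This vignette explains each model, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Ploidy from base frequencies

At a biallelic site, an individual of ploidy $p$ with alternate-allele
dosage $k$ produces alternate reads at frequency $k/p$ (plus a symmetric
error term: each read is flipped with probability $\varepsilon$, so the
expected frequency is $(k/p)(1-\varepsilon) + (1-k/p)\varepsilon$). Pooled
over many biallelic sites, the frequency histogram peaks at $\{1/2\}$
(diploid), $\{1/3, 2/3\}$ (triploid) or $\{1/4, 1/2, 3/4\}$ (tetraploid).
`extract_biallelic_frequencies()` records *both* allele frequencies per
kept site ($f$ and $1-f$), so the multiset is symmetric about 0.5; all
downstream band statistics are defined on this representation. Default
site filters (depth ≥ 10, each allele ≥ 3 reads, third-allele fraction
≤ 5%) are conservative read-count filters exposed as configuration.

`fit_ploidy()` compares, by EM, fixed-mean Gaussian mixtures (means
clamped to the ploidy's peaks; free weights; one shared variance) against
a free-means three-component mixture. Every model additionally carries a
Uniform(0,1) noise component with free weight. The noise term matters:
with per-read error $\varepsilon > 0$, homozygous sites occasionally pass
the minor-read filter and deposit a small pile of entries near
$\varepsilon$ and $1-\varepsilon$; without a noise component those
outliers cost the single-peak diploid model hundreds of log-likelihood
units while the tetraploid model absorbs them in its outer peaks, biasing
calls upward. With the noise component in *every* model the outliers load
on the uniform term symmetrically and the likelihood-ratio deltas reflect
peak structure only.

Model selection minimises $\Delta(p) = \ln L_{free} - \ln L_{fixed,p}$
(nonnegative up to numerical tolerance, since each fixed model is nested
in the free one — the implementation warm-starts the free fit from the
best fixed solution, so nesting holds by EM monotonicity). Because the
diploid peak set $\{1/2\}$ is a subset of the tetraploid peaks and weights
are free, true diploids produce near-ties between $\Delta(2)$ and
$\Delta(4)$; the caller therefore reports the *lowest* ploidy whose delta
lies within `tie_tol` (default 10) log-likelihood units of the minimum.
The default demands decisive evidence (a likelihood ratio of $e^{10}$)
before invoking a higher-ploidy model that nests a lower one; in seeded
simulations at 50× depth the margins for true triploids and tetraploids
are in the hundreds-to-thousands, so the tolerance costs no power.

EM numerics: log-space responsibilities, k-means++-style initial means,
convergence at $|\Delta \ln L| < 10^{-6}$ or 500 iterations, variance
floor $10^{-4}$. Restarts are run as short (10-iteration) pilot fits and
only the best is polished to convergence. The log-likelihood trace is
retained and asserted non-decreasing in the tests.

`denoise_frequencies()` fits the same machinery with free means (three
Gaussians + uniform) and removes entries whose signal posterior is below
0.5, averaging posteriors over mirrored pairs so the symmetric
representation survives denoising. On pure three-peak data ≥ 99% of
entries are retained; on pure uniform noise the uniform weight rises
above 0.9 (for a few thousand entries — with only hundreds, random
clumping lets the Gaussians steal more weight).

Sample QC applies two filters in order: informative fraction (non-gap
proportion of the individual's concatenated alignment rows) at least 0.2
— the threshold value itself passes — then concordance of estimated with
expected ploidy.

## Inheritance mode of tetraploids

A tetrasomic (auto-)tetraploid segregates four homologues jointly, so
genotypes at a site with allele frequency $q$ are Binomial(4, q) and
balanced AABB genotypes are no commoner than the frequency spectrum
implies. A disomic (allo-)tetraploid is two diploid subgenomes; at a fixed
inter-subgenome difference every individual is AABB, producing an excess
of intermediate (≈ 50%) allele frequencies relative to rare ones.

The expectation sets are built from diploid data by summing per-site read
counts of two individuals (`combine_diploids()`): conspecific pairs model
autotetraploids, heterospecific pairs model allotetraploids, with fixed
interspecific differences supplying the AABB excess. Summing counts is
informationally equivalent to merging read sets for frequency histograms
and keeps the package free of alignment-file dependencies.

The diagnostic statistic (`intermediate_rare_ratio()`) counts frequency
entries in the closed intermediate band [0.40, 0.60] against the open
rare band (0, 0.30). On the symmetric both-allele representation each
intermediate site contributes two entries while the rare band deliberately
counts only the low side (entries below 0.30, not their mirrors above
0.70); this is a monotone transform of the folded ratio and leaves rank
tests unchanged. Ratios are computed per individual (or per model pair)
and groups are compared with two-sided Wilcoxon rank-sum tests — exact
enumeration when both groups have ≤ 10 untied values, otherwise the
tie-corrected normal approximation — with Benjamini–Hochberg adjustment
across the declared family (observed-vs-auto, observed-vs-allo,
auto-vs-allo).

The decision rule in `classify_inheritance()` is directional:
*tetrasomic* when the observed group is significantly below the
allotetraploid models and not significantly above the autotetraploid
models; *disomic* in the mirror case; *mixed* when the observed group
sits between the model sets with both comparisons significant, or when
neither is. An observed group lying *beyond* the matching model set
(e.g. even more intermediate-heavy than the allo models) is not "mixed":
direction is part of the rule.

Design choices in the recovery experiment
(`inheritance_mode_recovery()`), all of which matter for calibration:

- **Disjoint model pairs.** All-pairs expectation sets reuse each diploid
  in many pairs; the resulting ratios are strongly correlated, and a rank
  test that treats them as independent rejects a true null far too often
  (we measured ≈ 35% at nominal 5%). The experiment therefore pairs each
  diploid once (`build_expectation_sets(..., pairs = "disjoint")`). The
  all-pairs construction remains available and is appropriate for
  visualising expectation bands, as opposed to testing.
- **Depth matching.** Combined counts double the depth of their sources,
  and band leakage across the 0.30 boundary is depth-dependent, so
  diploids are sequenced at half the tetraploid depth (default 25× vs
  50×).
- **No heterozygosity conditioning.** Observed tetraploids are simulated
  over raw sites (≈ 19,000, yielding ≈ 5,000 biallelic sites) rather than
  conditioning each site on being heterozygous, because conditioning
  removes the error-driven rare-band leakage of homozygous sites that the
  combined-diploid models retain — a ≈ 2% systematic offset otherwise.
- **Population structure.** Diploids of the two species share per-site
  allele frequencies except at a `fixed_diff_prob` fraction of fixed
  differences (default 0.05), the same divergence used for the disomic
  tetraploids' subgenomes; each diploid population uses 50,000 sites so
  the shared site realisation contributes little between-replicate
  variance.

At these defaults the classifier labels tetrasomic truth correctly in
≈ 98% and disomic truth in ≈ 92% of 100 seeded replicates, and
null-vs-null comparisons reject ≈ 3% at $\alpha = 0.05$.

## Locus-wise summary statistics

Site filters: sites containing any gap or N are dropped (complete
deletion; pairwise deletion is available as a switch, complete is the
default for determinism), sites with more than two nucleotide alleles are
dropped, and a locus is analysed only if *strictly more than* 100 sites
survive. Filtering is idempotent.

On the kept sites, with $n$ haplotypes (tetraploids contribute their four
phased haplotypes as four rows — all statistics are haplotype-based):
$\pi$ is the mean pairwise difference per site over all
$\binom{n}{2}$ pairs; $\theta_W = S/(a_1 L)$ with
$a_1 = \sum_{i=1}^{n-1} 1/i$; Tajima's
$D = (\Pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$ with the standard
constants in $n$, undefined (flagged NA) at $S = 0$. Between species,
Hudson's $F_{st} = 1 - H_w/H_b$ with $H_w$ the average of the two
species' mean pairwise differences and $H_b$ the mean between-species
difference, undefined when $H_b = 0$; $d_{xy} = H_b/L$. Note the pairwise
estimator's finite-sample algebra: identical balanced pools of size $n$
per species give exactly $-1/(n-1)$, not 0 (between-species pairs include
cross-copies of the same haplotype); under panmixia its *expectation*
across loci is 0, which is what the tests assert. Per-locus $F_{st}$
aggregates across loci by the median, $d_{xy}$ by the mean; species
matrices are clustered with average linkage (UPGMA) via `hclust`.

## Gene-tree space

Robinson–Foulds distances are computed from canonical bipartition sets
(trees handled unrooted throughout; splits keyed on the side not
containing the alphabetically first leaf). Classical (Torgerson) MDS via
`cmdscale` embeds the distance matrix; axes with non-positive eigenvalues
are dropped with a warning, and each axis is sign-fixed so its first
nonzero coordinate is positive.

Cluster count is selected with PAM plus the gap statistic against B = 50
uniform reference draws over the coordinate bounding box, choosing the
smallest $k$ with $Gap(k) \ge Gap(k+1) - s_{k+1}$. Two choices here are
deliberate and were calibrated on synthetic two-topology tree sets:

- **Distinct topologies only.** Gene-tree sets contain many exact
  duplicates, which collapse to zero-width point masses in the embedding.
  Left in place, splitting any tight satellite group off a zero-width core
  always pays, and the gap curve increases monotonically to `k_max` for
  essentially every seed. Model selection therefore runs on distinct
  points, and every tree inherits its representative's cluster.
- **Three embedding axes, squared-distance dispersion.** With two planted
  topologies (200 trees, one random NNI applied with probability 0.2),
  recovery of $k = 2$ across 100 seeds was 77% with 2-D axes and linear
  dispersion, 89% with 3-D/linear, 93% with 2-D/squared and 99% with
  3-D/squared; the defaults use three axes and squared distances (the
  original gap-statistic formulation).

Gene concordance factors: for each internal species-tree branch, the
percentage of *decisive* gene trees (those carrying at least one leaf
from each of the four subtrees adjacent to the branch) whose topology
contains the branch's bipartition restricted to their leaf set.

The within-locus consistency test asks whether gene-tree conflict lives
between loci (expected after rapid speciation) or already within loci
(expected under incomplete lineage sorting or gene flow). Per locus it
draws `n_replicates` (default 6; the number is a free parameter) random
one-individual-per-species subsamples, builds a neighbor-joining tree
from JC69 distances for each (complete-deletion overlap; saturated pairs
capped with a warning), and scores the mean pairwise RF among replicate
trees; each locus is summarised by its majority-rule (50%) consensus, and
the between-locus score is the mean pairwise RF among consensus trees.
The verdict threshold defaults to 0 (strict topological identity within
loci), matching the qualitative claim it operationalises, and is exposed
as configuration.

## Niche statistics

Suitability rasters hold presence probabilities on the cloglog (0–1)
scale; the ESRI ASCII grid is the supported on-disk format. Suitable area
is the count of cells at or above the threshold (inclusive ≥ 0.8 by
default), optionally weighted by a per-cell area grid — by default areas
are cell counts, and the latitude-weighted mode exists because past-climate
grids can cover a different landmass. Relative change is
(current − past)/current, undefined at zero current area. Correlated
bioclimatic variables are pruned greedily: repeatedly take the worst pair
above $r_{max} = 0.85$ and drop the member with the higher mean absolute
correlation to the remaining variables (ties to the earlier column).
The demography correlation is Pearson's $r$ between per-species relative
change and median Tajima's D, with the two-sided t-test
$t = r\sqrt{(n-2)/(1-r^2)}$; permutation checks at $n = 6$ put the
5%-level rejection rate within [0.03, 0.07].

## Synthetic-data generators

All generators are deterministic given a seed.

- **Genotypes and reads.** Allele frequencies come from a symmetric
  Beta(0.2, 0.2) prior — a unimodal-at-extremes spectrum mimicking the
  neutral excess of rare variants; dosages are Binomial(ploidy, q) for one
  pool, or two Binomial(2, q) subgenomes with a fixed-difference fraction
  for disomic tetraploids. Depth is Poisson truncated to ≥ 1 (zero-depth
  sites carry no information); errors are symmetric biallelic flips.
- **Coalescent loci.** Standard single-population coalescent with
  exponential waiting times at rate $\binom{j}{2}$, optional exponential
  growth (hazard inflated by $e^{gt}$, inverted analytically), and
  infinite-sites mutations (Poisson with mean $\theta T_{total}/2$,
  placed uniformly on branches, one alignment column each; a locus too
  short for the realised mutation count is an error, not a resample). The
  closed-form checks this enables: $E[S] = \theta a_1$ and
  $E[\pi] = \theta$. A finite-sites JC69 companion simulates on a fixed
  tree for distance-based tree building fixtures.
- **Gene trees.** Draws from weighted base topologies with one random NNI
  applied with probability `nni_prob`, truth labels retained.
- **Raster pairs.** Exact planted counts of suitable (probability in
  [0.8, 1)) cells.

What the generators do *not* emulate: linked sites and recombination
within loci, mapping and base-quality error structure, reference bias,
allele-specific expression of capture efficiency, and spatial
autocorrelation in rasters. Passing recovery tests on these simulations
shows the estimators and decision rules are correct and calibrated under
their stated models, not that real AHE data meet those models; the
empirical depth distribution of any given capture experiment, in
particular, is a free parameter the defaults do not claim to match.

## Problem sizes in the shipped experiments

The test suite and `scripts/acceptance.R` run the recovery studies at:
100 replicates for inheritance-mode recovery (8 + 8 tetraploids, 2 × 8
diploids each); 300 individuals for ploidy recovery (100 per ploidy,
5,000 sites at 50×); 1,000 neutral loci (n = 20, θ = 5) for Tajima's D
calibration and 2,000 replicates (n = 10, θ = 2) for the Watterson check;
100 random 8-leaf trees for RF oracle agreement and 100 seeded runs for
cluster-count recovery; 50 loci for the discordance sign test; and 1,000
permutations for the correlation calibration. These sizes give stable
rates while keeping a full run in the minutes range on one core.
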