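# ploidpop

Population-genetic analysis of polyploid species complexes from targeted
sequencing data: ploidy calling, inheritance-mode inference, locus-wise
summary statistics, gene-tree-space conflict analysis, and
habitat-suitability change statistics — with seeded synthetic-data
generators so the whole pipeline is testable end to end without external
data.

The package is aimed at researchers working on mixed-ploidy groups (e.g.
diploid–tetraploid amphibian or plant complexes) sequenced with targeted
capture of conserved nuclear loci, where phased haplotype alignments and
per-site read counts are available but whole genomes are not.

## What it computes

**Ploidy from allele frequencies.** At a biallelic site in an individual of
ploidy *p* with alternate-allele dosage *k*, reads support the alternate
allele with frequency *k/p*. The distribution of allele frequencies over
thousands of biallelic sites therefore peaks at {1/2} for diploids,
{1/3, 2/3} for triploids and {1/4, 1/2, 3/4} for tetraploids. `fit_ploidy()`
maximises, by EM, Gaussian mixtures with means clamped to each ploidy's
peaks (free weights, one shared variance, plus a Uniform(0,1) noise
component) and a free-means reference mixture, and reports the ploidy
minimising Δ(p) = ln L(free) − ln L(fixed, p), with parsimony tie-breaking
toward lower ploidy.

**Inheritance mode of tetraploids.** An autotetraploid (tetrasomic
inheritance, one pool of four homologues) has genotype frequencies
Binomial(4, q); an allotetraploid (disomic, two diploid subgenomes) adds
fixed inter-subgenome differences that force balanced AABB genotypes at
exactly 50% read frequency. `combine_diploids()` builds expected
autotetraploids (conspecific diploid pairs) and allotetraploids
(heterospecific pairs) by summing per-site read counts;
`intermediate_rare_ratio()` computes the diagnostic ratio of
intermediate-band (40–60%) to rare-band (<30%) allele-frequency entries;
`classify_inheritance()` compares observed tetraploids against both model
sets with two-sided Wilcoxon rank-sum tests (Benjamini–Hochberg adjusted)
and labels each species tetrasomic, disomic or mixed.

**Locus summary statistics.** On phased haplotype alignments (2 rows per
diploid, 4 per tetraploid), per locus and species: segregating sites S,
nucleotide diversity π, Watterson's θ_W = S/(a₁L), Tajima's
D = (Π − S/a₁)/√(e₁S + e₂S(S−1)), Hudson's F_st = 1 − H_w/H_b, and d_xy;
plus median-F_st aggregation into species matrices and UPGMA clustering.

**Gene-tree space.** Robinson–Foulds distances, classical MDS embedding,
PAM clustering with gap-statistic selection of the cluster count, gene
concordance factors (per species-tree branch, the percentage of decisive
gene trees containing the branch's bipartition), and a within-locus
consistency test that distinguishes rapid speciation (conflict only
*between* loci) from incomplete lineage sorting or gene flow (conflict
already *within* loci).

**Range change vs demography.** Thresholded suitable areas (≥ 0.8 presence
probability) from presence-probability rasters, the relative change
(current − past)/current, correlated-variable pruning (|r| > 0.85), and the
Pearson correlation of range change with per-species median Tajima's D.

## Worked example

```r
library(ploidpop)

# simulate a tetrasomic tetraploid sequenced at 50x and call its ploidy
cfg <- sim_config(seed = 7, n_sites = 5000, ploidy = 4,
                  inheritance_mode = "tetrasomic",
                  mean_depth = 50, error_rate = 0.005)
counts <- simulate_read_counts(simulate_genotypes(cfg), cfg)
freqs  <- extract_biallelic_frequencies(counts)
fit    <- fit_ploidy(freqs)
fit
#> <ploidy_fit> best ploidy 4 (n = 2668 entries)
#>   delta(ll_free - ll_fixed): 2n 587.954 | 3n 334.785 | 4n 0.782
```

The deltas say the free mixture beats the diploid and triploid fixed-peak
models by hundreds of log-likelihood units but the tetraploid model by only
~0.8 — the frequency histogram is explained by peaks at {1/4, 1/2, 3/4}, so
the individual is called tetraploid.

```r
# inheritance mode: observed tetraploids vs in-silico expectation sets
dip <- simulate_diploid_species_pair(n_per_species = 8, n_sites = 50000,
                                     fixed_diff_prob = 0.05,
                                     mean_depth = 25, seed = 42)
models <- build_expectation_sets(dip, pairs = "disjoint")
auto <- do.call(rbind, lapply(models$auto, function(m)
  intermediate_rare_ratio(extract_biallelic_frequencies(m), group = "model_auto")))
allo <- do.call(rbind, lapply(models$allo, function(m)
  intermediate_rare_ratio(extract_biallelic_frequencies(m), group = "model_allo")))
obs <- do.call(rbind, lapply(1:8, function(i) {
  cfg <- sim_config(seed = 4200 + i, n_sites = 19000, ploidy = 4,
                    inheritance_mode = "tetrasomic")
  intermediate_rare_ratio(
    extract_biallelic_frequencies(simulate_read_counts(simulate_genotypes(cfg), cfg)),
    group = "observed_4n")
}))
classify_inheritance(obs, auto, allo, species = "sim_tetrasomic")
#> <inheritance_call> sim_tetrasomic: tetrasomic
#>   adj. p vs auto 0.7984 | vs allo 0.0002331 (alpha = 0.05)
#>   median ratio observed 0.906 | auto 0.907 | allo 1.55
```

The observed group's intermediate/rare ratios are indistinguishable from
the autotetraploid models (p ≈ 0.8) and far below the allotetraploid
models (p ≈ 2e-4), so the allopolyploid origin is rejected: inheritance is
called tetrasomic.

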