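---
title: "Methods: mixed-ploidy species separation from SNP allele depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-ploidy species separation from SNP allele depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `ploidypop`, the choices made
where the design was genuinely open, and the limits of what the synthetic
benchmarks can show about real data.

## The problem

Interfertile shrub birches with different ploidy levels (diploid dwarf
birch, tetraploid bog birch, hybrid river-birch derivatives, dwarf arctic
birch) co-occur across the subarctic and are hard to separate
morphologically. The workflow combines four semi-independent criteria —
ploidy inferred from sequencing reads, nuclear genetic clustering,
chloroplast haplotypes and leaf morphology — into per-sample species
records. Ploidy and cluster membership decide; morphology corroborates;
the chlorotype is recorded but never decides, because haplotype sharing
across species (chloroplast capture through hybridization) strips it of
discriminatory power.

## Ploidy from allelic ratios

At a heterozygous site with alternate-allele dosage d in a sample of ploidy
c, reads carry the alternate allele with probability near d/c, so the
allelic ratio r = alt/(ref + alt) concentrates near d/c. Across many
heterozygous sites the ratio density shows c − 1 modes: {0.5} for diploids,
{1/3, 2/3} for triploids, {0.25, 0.5, 0.75} for tetraploids, {0.2, 0.4,
0.6, 0.8} for pentaploids.

**Reference SNPs.** Ratios from fewer than 15 reads are treated as missing.
A clear-diploid panel is bootstrapped: all samples are classified on all
sites, samples called diploid form the panel, and sites are retained iff
(a) panel mean depth ≥ 24, (b) after discarding ratios outside
(0.05, 0.95) the histogram mode (bin width 0.02, ties toward 0.5) lies in
[0.45, 0.55], and (c) at least two-thirds of the remaining ratios fall in
[0.4, 0.6]. The central-mass rule is computed as an empirical fraction, not
a smoothed integral, so it is bandwidth-free and deterministic. One
refinement pass re-derives the panel on the reference sites.

**Density estimation and classification.** Per sample, ratios in the
extreme tails (≤ 0.05, ≥ 0.95; mostly homozygous sites) are discarded and a
Gaussian kernel density with boundary reflection at 0 and 1 is estimated on
a 512-point grid, weighting observations by read depth (deeper ratios are
less noisy). Local maxima with topographic prominence of at least 10% (or
5%) of the curve maximum are matched to the ploidy templates: every
detected peak must lie within 0.07 of a distinct template position and
every template position must be hit. The 0.07 tolerance is the largest
value that still separates the diploid and tetraploid templates through
their 0.25/0.75 flank peaks.

A single fixed bandwidth cannot serve all ploidies: data-driven rules of
Silverman type oversmooth multimodal profiles so severely that tetraploid
flanks vanish, while a bandwidth below the depth lattice spacing (1/24 at
24×) invents spurious peaks. Classification therefore scans a
coarse-to-fine bandwidth ladder (0.045–0.02) at both prominence levels and
keeps the richest template matched anywhere on the ladder: oversmoothing
can only delete peaks, never produce extra template-consistent ones, so a
richer match is stronger evidence. Four-peak (pentaploid) matches must
appear at three or more ladder rungs, suppressing noise-driven matches.
Reported peak positions are ensemble means over the matching rungs, refined
to the local density mode at bandwidth 0.035 — this damps the
one-lattice-atom wobble a single bandwidth suffers at realistic site
counts. Samples matching no template are "unknown"; groups of unknowns can
be pooled (their ratios concatenated) and classified jointly, which mirrors
how unresolved individuals are rescued per putative species in practice.

**Calibration and resolution limits.** With binomial reads at 24×, the
flank components of a tetraploid (sd ≈ 0.09) are separated well enough that
classification accuracy exceeds 95% at 2000 heterozygous sites; accuracy
for diploids and triploids is essentially 100%. The generator's default
beta-binomial concentration of 500 adds mild allele-balance
overdispersion while keeping this structure resolvable — at strong
overdispersion (concentration below ~100) the tetraploid profile becomes
effectively unimodal and no peak-based classifier can recover it.
Pentaploids at 24× are at the method's intrinsic limit: in the *true*
mixture density the 0.4/0.6 components merge (their dip falls below any
usable prominence threshold), so pentaploid calls at 24× split between
pentaploid, tetraploid and unknown; the lowest mode near 0.2 is still
recovered. This matches field experience, where pentaploids are rare,
called visually, and many profiles remain unknown. Deeper coverage (30×)
and more sites make the pentaploid pattern mostly recoverable.

## Dataset assembly

Two nuclear datasets are built. The *initial diploid* dataset codes every
individual as diploid; `code_diploid()` models what a diploid genotype
caller reports from polyploid reads — any mixed dosage reads as
heterozygous — which is why diploid-coded tetraploids show elevated
heterozygosity. The *diploid-tetraploid* dataset keeps inferred diploids at
ploidy 2 and codes every other call (tetraploid, triploid, pentaploid,
unknown) as tetraploid. Filters: per-sample missingness caps of 40%
(initial) and 50% (mixed), then loci with MAF ≥ 0.01 (ploidy-aware
frequencies: summed dosages over summed ploidies) and < 30% missingness,
with frequencies recomputed after sample removal for internal consistency.

Clones are detected on the Manhattan dosage distance
d(i, j) = Σ |g_i − g_j| over loci observed in both samples, with
single-linkage grouping at an absolute threshold and the least-missing
member kept as genet. The published thresholds (350 for the initial
dataset, 300 for the mixed one) are absolute counts calibrated on a
~5000-locus panel; at other panel sizes they scale proportionally (70/60 at
the 1000-locus default used in `analysis/`). Distances are deliberately not
rescaled by pairwise overlap — that is what makes the absolute thresholds
meaningful — and pairs sharing fewer than 50 loci are flagged.

## Genetic structure

**DAPC.** Missing dosages are imputed to locus means, PCA scores feed a
k-means scan (10 restarts per k) scored by BIC_k = n ln(WSS_k/n) + k ln(n);
the minimum selects k, with an explicit `force_k` override because a flat
BIC valley is legitimately resolved by external evidence (geography,
morphology) — the study situation this package mirrors retained k = 5
against a 4–6 plateau. The number of retained PCs optimises the a-score
(observed minus permutation-expected reassignment). Linear discriminants
come from `MASS::lda`; group memberships are a softmax of negative halved
squared distances to group centroids in discriminant space, which
reproduces standard DAPC behaviour at the contract level.

**Admixture.** Instead of a Bayesian MCMC program, a binomial EM estimator
fits the same admixture likelihood: dosage g_il ~ Binomial(c_i, Σ_k Q_ik
F_kl) with per-sample coded ploidy c_i (diploids contribute two allele
copies, tetraploid-coded samples four — the EM analogue of the four-row
STRUCTURE coding with −9 padding, which `write_structure_file()` emits for
external runs). E-steps allocate allele copies to clusters; M-steps are
closed-form; the log-likelihood is non-decreasing and multiple restarts
guard against local optima. Replicate runs (independent restarts) feed the
Evanno statistic ΔK = mean over replicates of |L(K+1) − 2L(K) + L(K−1)|
divided by sd(L(K)), defined only at interior K with positive replicate
spread. Lineages are assigned where max_k Q_ik ≥ 0.75, and a cluster
containing both "Alaska" and "Europe" samples is split by region, because
a single genetic cluster can span disjunct ranges that should be managed
separately.

**Diversity.** Per population and locus with n genotyped diploids:
Ho = observed heterozygote fraction, Hs = n/(n−1) (1 − Σ p_a² − Ho/(2n)),
FIS = 1 − Ho/Hs. Pairwise FST is the Weir–Cockerham (1984) θ with
ratio-of-sums combination over loci (the standard recommendation; means of
ratios are biased), negative estimates reported as computed. Per-individual
heterozygosity follows the usual VCF summary: observed versus expected
homozygote counts under sample frequencies, F = (O − E)/(N − E). FST and
individual heterozygosity run on the diploid-coded initial dataset; a
ploidy-aware FST is out of scope.

## Chloroplast haplotypes

Organellar SNPs are haploid. Sites that are invariant among genotyped
samples or exceed 10% missingness are dropped; among the rest, sites
inducing the same sample partition (identical columns up to a global 0/1
swap, compared on shared non-missing samples) are redundant and only the
least-missing representative is kept — "uniquely informative" is read as
partition-level information. Haplotypes are the concatenated alleles over
retained sites in genomic order; a sample missing any retained site has no
haplotype (no imputation — dropped individuals are the honest outcome).
Letters rank haplotypes by global frequency. The sharing report flags
chlorotypes carried by more than one nuclear cluster; on synthetic data
with known carriers the report is exact.

## The synthetic generator

`simulate_dataset()` emulates the study's statistical structure: ancestral
allele frequencies uniform on (0.05, 0.95); cluster frequencies from the
Balding–Nichols beta with per-cluster divergence F_k; individual dosages
binomial in the ploidy at admixture-weighted frequencies; depths
negative-binomial (mean 24, size 10); alternate reads beta-binomial
(concentration 500) with a 0.5% error pulling homozygote ratios off the
boundaries; MCAR nuclear missingness (3%); clonal copies with independent
per-locus error; hybrids and trihybrids with explicit admixture vectors.
Chloroplast haplotypes live on a random genealogy under infinite sites —
sites mutating on the same branch are exactly the redundant sites the
informative-SNP collapse removes — with cross-cluster sharing probability
0.3 (chloroplast capture) and per-sample dropout (failed organellar
amplicons) rather than per-cell noise. Populations nest within clusters;
40% of the 29 teams sample two clusters, reproducing the situation where
collection teams unknowingly mix species. Defaults mirror the study
cohort: cluster sizes 198/109/10/127/25 with the fourth cluster
tetraploid, plus 24 hybrids and 10 clones, at 1000 nuclear and 85
chloroplast SNPs (1000 loci keep the workflow comfortably interactive
while leaving every estimator deeply in its working range; the full-panel
scale only changes the clone thresholds, which scale proportionally).

What the generator does *not* emulate — linkage disequilibrium, selection,
paralogous mis-alignment (the main real-world source of off-0.5 ratio
artefacts the reference-SNP filter exists for), spatial population
structure within clusters, and batch effects between sequencing runs — is
exactly what passing tests cannot vouch for on real data. The
reference-SNP filter is exercised against its stated criteria, not against
realistic paralogy.

## Numerical choices and degenerate inputs

Kernel densities integrate to 1 within 1e-3 on the grid; samples with
fewer than 30 usable ratios are unknown by construction. K-means uses 10
restarts under a caller-provided seed; EM initialises Q from a symmetric
Dirichlet and F from perturbed pooled frequencies, clamps probabilities to
[1e-6, 1 − 1e-6], and stops on log-likelihood gains below tol. ΔK is NA at
endpoint K and wherever replicate sd is zero. Monomorphic loci are removed
by the MAF filter; loci with fewer than two genotyped individuals per
population are skipped in diversity sums. All simulation and analysis
entry points take integer seeds and restore the caller's RNG state.

## Known limitations

- Pentaploid recovery at 24× is intrinsically partial (see above).
- The EM admixture estimator fits the independent-loci admixture model
  without the correlated-allele-frequency prior; with closely related
  clusters and modest marker numbers it merges clusters more readily than
  long MCMC runs, and ΔK computed from restart replicates reflects restart
  variance, not posterior variance.
- The multicriteria concordance rule (ploidy and cluster necessary,
  morphology corroborating, chlorotype never deciding) is one defensible
  operationalisation of qualitative field practice, not a unique one.
- Absolute clone thresholds assume comparable per-locus information across
  datasets; panels differing strongly in locus number or missingness need
  rescaled thresholds.
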