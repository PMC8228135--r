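---
title: "Models and conventions behind canid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind canid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canid)
```

`canid` analyses SNP-array genotypes of dog breeds and wild canids through
five lenses: autozygosity (runs of homozygosity and F_ROH),
allele-frequency divergence (Weir–Cockerham F_ST, Nei distances),
supervised clustering (DAPC), model-based ancestry (admixture with Evanno
ΔK) and fine-scale relatedness (IBS k-nearest-neighbour networks), plus
candidate-gene-panel stratification. This vignette describes each model,
its tunable parameters and their defaults, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## The genotype container

All stages operate on a `genotype_dataset`: a samples × markers matrix of
counted-allele dosages (0/1/2, `NA` for missing) with a marker map and a
sample/group table. Positions are 1-based base pairs, as in PLINK MAP/BIM
files; every interval in the package (runs, gene intervals) is closed,
`[start, end]`. Markers are kept sorted by (chromosome, position);
chromosome labels are strings, and the autosome filter keeps `"1"`–`"38"`
(the dog autosomes) by default.

PED/MAP carries no allele columns, so the reader assigns the counted allele
A1 as the *minor* allele, with ties and monomorphic markers broken
lexicographically. This is deterministic and makes read → write → read the
identity; BIM's explicit allele columns are taken as-is. When merging
datasets, markers are restricted to the common set and the other datasets'
dosages are complemented (d → 2 − d) wherever their A1/A2 order is
reversed relative to the first dataset; pairs that cannot be reconciled —
including strand-ambiguous A/T and C/G markers whose codes differ — are
dropped and counted, since without frequency information a strand flip
cannot be distinguished from an allele swap.

Missingness QC removes samples first, then markers, each in a single pass,
mirroring the one-shot pruning reported for the data this package is
designed around and keeping the accounting trivial to reconcile; the order
is configurable. A unit is removed when its missing fraction is *strictly
greater* than the threshold (default 0.10 for both axes), the PLINK
`--mind`/`--geno` convention.

## Runs of homozygosity and F_ROH

ROH are detected by the consecutive-runs criterion rather than a sliding
window: within a sample and chromosome, a candidate run is a maximal
stretch of consecutive homozygous calls, broken by *any* heterozygous or
missing genotype and by any inter-SNP gap larger than `max_gap_bp`
(default 1000 kb). A candidate is reported when

* its length (first to last SNP, closed) is ≥ `min_length_bp` (500 kb),
* it contains at least `min_snps` SNPs, and
* its average spacing `length / n_snps` is at most one SNP per
  `min_density_bp_per_snp` (5000 kb).

`min_snps` defaults to the false-positive bound
\(l = \ln(\alpha/(n_s n_i)) / \ln(1-\bar h)\) evaluated on the dataset at
hand (α = 0.05), floored; a fixed value such as 65 can be supplied when
reproducing a published setting, because the heterozygosity that produced a
published count is usually not reported. Segment boundaries are the first
and last homozygous SNP positions, not midpoints of flanking gaps, so
reported lengths are conservative.

F_ROH divides the summed ROH length by the SNP-covered autosome length
(`genome_span`: per-chromosome max − min position, summed). Two
conventions are provided. The default is *threshold-cumulative*,
F_ROH(≥X) = length of all runs at least X Mbp long / genome length, for
X ∈ {0.5, 2, 4, 8, 16}; the literal *per-class* mode sums only runs whose
length falls inside one class. Cumulative is the default because a
published per-breed table of counts, mean lengths and F_ROH values that we
use as an arithmetic cross-check is internally consistent only under the
cumulative reading — reconstructing its F_ROH column from its own counts ×
mean lengths reproduces all five values within 0.1 percentage points only
when classes accumulate from each threshold upward. Group summaries use
the arithmetic mean and n−1 SD over all animals of the group by default; a
carriers-only denominator (only animals with a qualifying run) is
available, since class-wise averages in published tables sometimes behave
that way.

One genome-length caveat: the reconstruction above treats a published
total of "21,995.34 Mbp" as 2,199.534 Mbp. The former exceeds the dog
autosome roughly ten-fold, and the arithmetic closes only at the smaller
value, so the package takes it as a unit slip.

## Divergence statistics

Per-group allele frequencies exclude missing genotypes. Nei's 1972
standard distance pools loci before the ratio:
\(D = -\ln \left[ J_{xy} / \sqrt{J_x J_y} \right]\) with
\(J_{xy} = \sum_l (x_l y_l + (1-x_l)(1-y_l))\) etc.; the 1983 distance is
\(D_A = 1 - \tfrac1L \sum_l (\sqrt{x_l y_l} + \sqrt{(1-x_l)(1-y_l)})\).
Loci with a missing frequency on either side are skipped with L adjusted.
The default method is 1972, matching what the widely used StAMPP
implementation computes for group-level distances; both are exposed and
every output names its method. Individual-level matrices treat each animal
as a population of one (frequencies in {0, ½, 1}), which is how
heat-map-style intrapopulation similarity figures are built.

F_ST uses the Weir & Cockerham (1984) θ in its two-population biallelic
form: per locus, variance components a (among populations), b (among
individuals within) and c (within individuals) are computed from the two
sample sizes, allele frequencies and *observed* heterozygosities, and
θ = Σa / Σ(a+b+c) over loci. Loci monomorphic across the pair, or with
fewer than two informative samples, are skipped. Slightly negative θ
estimates — expected under no differentiation — are preserved in
`$extra$unclipped` and clipped to 0 in the headline matrix, the common
reporting convention. An optional bootstrap over loci gives percentile
CIs. θ is invariant to swapping allele labels at any locus, which the test
suite asserts.

## DAPC

`pca()` mean-imputes missing dosages (the convention of the reference
DAPC implementation), centres columns, optionally scales (unit variance or
√(p(1−p))), and eigendecomposes via SVD with a deterministic sign
convention (largest-magnitude loading positive). The initial PCA retains
components covering 95% of the variance; `a_score()` then balances
discrimination against overfitting: for each candidate number of PCs it
computes the observed correct-reassignment proportion minus its mean over
label permutations (default 25 permutations, fixed seed), averaged over
groups, and recommends the maximizer. The discriminant step whitens the
pooled within-group covariance (ridge 1e−8 on singularity, logged in the
result) and eigendecomposes the between-group covariance in the whitened
space, giving at most groups − 1 discriminant functions. Posteriors use a
Gaussian model with shared identity covariance in the whitened DF space and
uniform priors. With five predefined origin groups this yields exactly
four discriminant functions.

## Admixture and ΔK

The K-cluster admixture model treats genotype \(g_{ij}\) as
Binomial(2, \(\pi_{ij}\)) with \(\pi_{ij} = \sum_k q_{ik} f_{kj}\),
uncorrelated cluster frequencies. Rather than MCMC sampling of the
posterior, `fit_admixture()` maximizes this likelihood by EM from a seeded
random start: the E step computes expected ancestry-specific allele
counts, the M step updates P and Q in closed form; the log-likelihood
trace is non-decreasing (asserted every iteration) and convergence is a
gain below `tol` (1e−6) or `max_iter` (2000). This is a deliberate
divergence from the Bayesian clustering software used in the tradition
this package follows: the model is identical, but point estimation is
deterministic given a seed and desk-scale fast, which is what a tested
package needs. The correlated-allele-frequencies prior of that software is
not implemented. K = 1 has the closed-form solution (pooled frequencies),
which doubles as a unit test anchor.

`admixture_scan()` runs replicates (default 10, matching common practice)
over K = 1..10, and `evanno_delta_k()` applies
ΔK = |mean L(K+1) − 2 mean L(K) + mean L(K−1)| / SD(L(K)), selecting the K
that maximizes it. Replicate log-likelihoods stand in for the mean
posterior log-probability used with MCMC output. ΔK needs at least three
consecutive K values and two replicates; a zero SD flags ΔK infinite.
Label switching is handled by greedy overlap matching (`align_clusters`)
before any comparison with truth.

## Relatedness networks

The default pairwise distance is 1 − IBS, with IBS similarity the mean of
(2 − |g_a − g_b|)/2 over loci genotyped in both samples — frequency-free
and robust across mixed populations. Because published pipelines often
feed "IBD" distances from PLINK into network clustering, a PI_HAT mode is
provided: method-of-moments P(IBD = 0/1/2) from the pairwise IBS 0/1/2
counts and the sample allele frequencies under Hardy–Weinberg
expectations, without the finite-sample correction factors of the original
implementation (at array scale they are negligible); PI_HAT = P(1)/2 +
P(2), distance 1 − PI_HAT. Both modes are labelled in the output.

The mutual k-NN graph keeps edge (a,b) iff each sample is among the
other's k nearest (default k = 15, the value typically chosen from a k-NN
selection plot; the union rule is also available). Ties at the k-th
distance break by sample-id order, so graphs are bit-identical across
runs. Community detection on the graph is out of scope — the package
delivers the graph that network-clustering tools consume.

## Gene panels

Candidate genes for four phenotype categories — aerobic trainability
(ATO), behaviour/motivation (BM), coat colour (CC), strength/endurance
(SE) — are supplied as a BED-like TSV. A SNP maps to a gene iff the
chromosome matches and start ≤ position ≤ end; SNPs in overlapping genes
go to all of them, flagged. The packaged
`inst/extdata/gene_panel_synthetic.tsv` carries the field's usual
candidate-gene symbols for these categories on *synthetic placeholder
coordinates* laid out on the generator's 38 × 60 Mbp genome: real-genome
coordinates come from an annotation database lookup, which is an external
resource outside this package's scope, so analyses of real data must
supply their own panel file.

Panel-wise PCA delegates to `pca()` on the subset columns (asserted never
to touch markers outside the panel). Factor analysis is iterated
principal-axis factoring on the correlation matrix (communalities
initialized at squared multiple correlations, convergence when the largest
communality change drops below 1e−3, cap 100 iterations — the looser
tolerance is deliberate, as near-Heywood cases otherwise creep toward the
0.995 communality cap indefinitely), with optional varimax rotation and
regression-method scores. "Each gene as a separate factor" is implemented
as the `aggregate = "gene"` mode (gene-mean dosages, one variable per
gene, n_factors defaulting to the gene count); marker-level FA is also
available. Dosages rather than group allele frequencies enter these
analyses — the per-animal view is what the stratification figures need.

## The synthetic-data generator

`simulate_balding_nichols()` draws ancestral frequencies from U(0.05,
0.95), per-population frequencies from Beta(p(1−F)/F, (1−p)(1−F)/F) — the
Balding–Nichols model, chosen because Weir–Cockerham θ has a computable
Monte-Carlo expectation under it — and genotypes Binomial(2, f). The
geometry defaults to a dog-like 38 autosomes; tests and the acceptance
script use 2–5 chromosomes of 50–60 Mbp with a few thousand SNPs, sizes at
which every stage completes in seconds to a couple of minutes on one CPU
while leaving the statistics of interest (θ, Q, class labels) well
resolved. `simulate_admixed()` mixes two frequency profiles with known q.
`implant_roh()` places non-overlapping exponential-length tracts
(placement rejects overlaps rather than merging, keeping the truth
intervals disjoint for clean recovery scoring) until a target F_ROH is
reached, forcing every SNP inside homozygous for an allele drawn by
frequency. All generators are bit-reproducible given their mandatory seed.

What the generator does *not* emulate: linkage disequilibrium and
recombination (loci are exchangeable), mutation, pedigree structure,
ascertainment bias of array content, and genuine IBD sharing between
"unrelated" samples. Passing recovery tests therefore demonstrate that the
estimators are implemented correctly under their own model assumptions —
they do not certify behaviour on real array data, where LD inflates
chance homozygous runs (the Lencz bound exists precisely to absorb that)
and where admixture and drift are confounded by shared history.

## Degenerate inputs and tie-breaks

Monomorphic marker pairs give flagged `NA` θ; opposite fixation under Nei
1972 would be infinite and is returned as the flagged value 1e6; sample
pairs sharing no genotyped locus get `NA` IBS distance with a warning;
empty gene-panel categories are dropped with a warning; a single group is
an error for DAPC; `evanno_delta_k` refuses non-consecutive K or single
replicates. Every stochastic function takes an explicit seed, and the
pipeline (`run_pipeline`) threads one seed through all stages, records it
in a provenance JSON with the input checksum and all parameters used, and
never mutates its input dataset.
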