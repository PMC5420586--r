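---
title: "Bin-marker maps and QTL scans for low-coverage F2 populations: models and methods"
author: "binQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-marker maps and QTL scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binQTL)
```

## The problem

Genotyping-by-sequencing (GBS) of a biparental F2 population produces tens of
thousands of SNP calls per individual at a fraction of one-fold coverage.  At
that depth a heterozygote is frequently sampled on only one allele and called
homozygous, genotypes are sometimes simply wrong, and many calls are missing.
Raw calls are therefore unusable as individual mapping markers.  The standard
remedy, which this package implements end to end, is:

1. keep only markers with the informative `aa x bb` parental configuration and
   Mendelian 1:2:1 segregation;
2. replace per-SNP calls by sliding-window consensus genotypes, merge
   identical windows into blocks, and collapse the genome into
   *recombination bins* — segments in which no individual of the population
   recombines, so every SNP inside segregates identically;
3. estimate a genetic map over the bins (recombination fractions by maximum
   likelihood, Kosambi map function);
4. scan the bins for quantitative trait loci (QTL) by composite interval
   mapping (CIM) with permutation thresholds, and by a LASSO over the joint
   additive/dominance design with post-selection tests.

Because the raw data of the motivating maize experiment (an SG5 x SG7 F2 of
199 individuals) are not publicly deposited, the package carries a first-class
synthetic population generator that emulates its structure; every stage is
tested against that generator's ground truth, and the published per-chromosome
map summaries ship as a numeric fixture for arithmetic checks.

## The F2 meiosis and noise model

`simulateGamete()` draws a Poisson number of crossovers with mean equal to the
chromosome's genetic length in Morgans, places them uniformly on the physical
span, and alternates parental origin across them — a no-interference
(Haldane) process.  An F2 individual is two independent gametes; at any locus
the genotype frequencies are the Mendelian 1/4, 1/2, 1/4.  We deliberately
simulate *without* crossover interference although the map is later reported
in Kosambi units: the generator is the test harness, and the map-construction
stage is judged on internal consistency (recovering the generator's lengths),
not on matching the generator's map function.  Genetic positions vary linearly
with physical position within a chromosome; real genomes have recombination
deserts and jets, which this generator does not emulate — passing tests shows
correctness of the machinery, not robustness to strongly non-uniform
recombination landscapes.

`gbsObserve()` perturbs true calls in three ordered steps, each an independent
Bernoulli event per call:

* *heterozygote undercall* (`hetUndercallRate`, default 0.30): a true `AB`
  becomes `AA` or `BB` with equal probability — the dominant error mode of
  allele sampling at ~0.36-fold coverage, and symmetric for that reason;
* *genotype error* (`errorRate`, default 0.01): any call is replaced by one of
  the two other categories;
* *missingness* (`missingRate`, default 0.10): the call is masked.

The defaults are stated regimes, not estimates of the motivating study's
(unpublished) error rates; the 0.10 missingness mirrors the 25% missing-data
filter bound being comfortably clear of typical markers, and tests vary all
three rates.  One consequence worth knowing: with a 0.30 undercall rate the
*expected* 1:2:1 chi-square statistic at a clean marker is about 18, which
sits just above the df-2 cut-off for p < 0.001 (13.8).  A hard Mendelian
filter then removes the majority of markers — consistent with the motivating
experiment retaining 29,927 of 68,882 `aa x bb` SNPs — and, because linked
markers share the same 199 individuals, retention fluctuates in a correlated
way along chromosomes.  Recovery simulations in the test suite therefore use
a 0.10 undercall rate so that filtered marker density stays adequate at desk
scale; the robustness suite uses the full 0.30 with no filtering, which is the
regime the sliding window exists to absorb.

Phenotypes follow the standard F2 additive/dominance model
`y = mu + sum_k (a_k x_k + d_k z_k) + e`, with `x` coded +1/0/−1 for the
P1-homozygote/heterozygote/P2-homozygote and `z = 1` for the heterozygote.
One QTL contributes variance `a^2/2 + d^2/4` at F2 frequencies; the residual
variance is set from the *theoretical* genetic variance (QTL treated as
unlinked) so that the trait heritability equals `h2`.  Trait–trait
correlation arises only through shared QTL.

## Marker filtering

`filterMarkers()` applies, in fixed priority order: abnormal call tokens
(anything outside `AA/AB/BB/NA`), missingness (> 25% removed; exactly 25% is
retained — the boundary is unstated in the motivating description, and this
reading removes strictly more than the bound), and 1:2:1 segregation
distortion (chi-square p < 0.001 on the non-missing counts, df = 2, for which
the p-value is exactly `exp(-chisq/2)`).  The order does not change the
retained set, only which reason a doubly-failing marker reports.  Heterozygous
calls count once toward the middle class; missing calls are excluded from the
test total.

## The sliding-window caller and bin construction

Windows of 15 SNPs advance one SNP at a time.  Within a window each `AA` call
scores 1 for P1, `BB` scores 1 for P2, and `AB` splits 0.5/0.5 (the
allele-ratio reading; `hetSplit = FALSE` switches to call counting for
sensitivity analysis).  A parent reaching 11/15 of the non-missing weight is
called homozygous, otherwise the window is heterozygous; a score of exactly
11 is homozygous ("11 or more"), and windows with missing data scale the
threshold proportionally.  Each SNP takes the call of the window centred on
it (ends reuse the nearest complete window; chromosomes shorter than one
window are governed by a single truncated window); windows with no data
inherit from their upstream neighbour.  Runs of identical per-SNP calls merge
into blocks, and the breakpoint between two blocks is placed midway between
the flanking SNPs.

Two systematic consequences of the supermajority rule are worth stating
because tests account for them.  First, at a homozygote–heterozygote junction
the first SNP of the new block still satisfies the homozygote threshold
(7 + 8·0.5 = 11), so block boundaries shift by one SNP toward the
heterozygous side; bin genotypes are therefore *nearly* (not bit-for-bit)
exact against truth even in noiseless data.  Second, two crossovers closer
than roughly one window span collapse, which biases estimated map lengths
mildly downward at desk-scale marker density — noiseless simulations recover
generator lengths within about 10% on average.

`buildBins()` partitions each chromosome into a fixed 100-kb grid anchored at
coordinate zero (half-open intervals — the anchoring convention is ours, the
motivating description being silent).  An interval holding at least one
breakpoint midpoint anywhere in the population is *hot*; each hot interval
starts a new bin (we assign the breakpoint interval to the downstream bin — a
documented convention, not an inference), and cold intervals extend it.  Bin
coordinates are trimmed to the first/last constituent SNP, which is how bins
shorter than one grid interval arise.  A bin's genotype for an individual is
its block genotype over the bin, read at the last constituent SNP so that a
recombinant individual (whose breakpoint sits in the bin's opening interval)
contributes the genotype right of its breakpoint; constancy over the rest of
the bin is asserted at construction time.  "Skeleton-bin" collapsing is
treated as identical to this construction.

## Genetic map estimation

Marker order is taken from the genome; bins are anchored to the reference
assembly and never re-ordered.  `estimateRF()` maximizes the two-locus F2
multinomial likelihood over the nine genotype-pair cells, in which the
double-heterozygote cell mixes the two phases with probability
`((1-r)^2 + r^2)/2`.  We use direct bounded one-dimensional optimization
(tolerance 1e-9) with the endpoints checked explicitly; tests verify
equivalence with an exhaustive grid search to 1e-3 on random instances.
Adjacent pairs with `r >= 0.49` are flagged as gaps but the chromosome is not
split — assignment to linkage groups is physical.  Before the Kosambi
transform (`d = 25 ln((1+2r)/(1-2r))`, exact inverse `r = tanh(d/50)/2`)
`r` is capped at 0.495, since the transform diverges at 0.5.  Map positions
are cumulative distances; `mapSummary()` reproduces the conventional
per-linkage-group table (bins, size, average gap = size/(bins−1), max gap)
and accepts either an estimated map or a published per-chromosome table,
which is how the shipped summary of the maize SG5 x SG7 map (3,305 bins,
2,236.7 cM, overall average gap 0.68 cM) is checked arithmetically.

## Composite interval mapping

At a tested position the unobserved QTL genotype has prior probabilities
conditional on the flanking bin genotypes under the two-locus,
no-interference F2 transition model (`qtlGenotypeProbs()`, computed by exact
enumeration over gamete haplotype configurations; cM distances convert to
recombination fractions via the inverse Kosambi).  `fitQtlMixture()` fits the
three-component mixture regression by EM — posterior weighting then weighted
least squares — with tolerance 1e-8, at most 100 iterations, and a
non-decreasing observed-data log-likelihood asserted in tests.  The LOD score
compares against the same covariate model without the QTL term.  At a fully
observed bin the prior is degenerate, EM converges immediately, and the LOD
equals the single-marker ANOVA LOD `n/2·log10(SS0/SS1)` to numerical
precision — an identity the tests check at 1e-8.

Cofactors come from forward–backward stepwise selection on single-bin
additive+dominance pairs (partial F, df 2, enter/stay at 0.05, capped at 5)
and are excluded within a 10-cM window of the tested position.  Note that
with hundreds of correlated candidate bins an unadjusted 0.05 entry level
virtually always admits some cofactor even for a pure-noise trait; the cap,
the exclusion window and the permutation threshold are what keep the scan
calibrated, and the calibration suite verifies a genome-wide type-I error
near 5%.

Permutation thresholds shuffle the trait across individuals with the cofactor
set frozen (re-selection per permutation would multiply cost by the marker
count and the reference behaviour is undocumented).  Permuted scans use
Haley–Knott regression on the expected QTL genotype codes, vectorized over
all permutations; at fully observed bin markers — where bin genotypes are
complete by construction — this is *exactly* the mixture LOD, so threshold
and scan are on the same statistic on the default marker grid.  The
`-log10(p)` track uses the chi-square df-2 approximation of `2 ln(10) LOD`;
the mixture's non-regularity makes this approximate, and declaration is by
the permutation threshold, not this p-value.  QTL are called as peaks at or
above the threshold, merged within 20 cM, with 1.5-LOD support intervals
reported through flanking bins and their physical span — the merge radius and
the 1.5-LOD rule are conventional defaults, the motivating analysis not
stating its interval rule.  Additive effects are half the homozygote-mean
difference (positive when the P1 allele increases the trait); dominance is
the heterozygote deviation from the homozygote midpoint; R² is the residual
variance reduction from adding the QTL term, over total phenotypic variance.

## LASSO scan

`lassoScan()` builds the 2M-column design (additive +1/0/−1 and dominance
0/1 codes per bin), standardizes internally, and fits one joint L1-penalized
least-squares model via `glmnet`, with the penalty chosen by 10-fold
cross-validation at the minimum CV error — the liberal choice, matching the
multi-QTL character of the reference analyses; fold assignment is
seed-controlled.  Selected columns are refitted by ordinary least squares and
reported with Wald `-log10(p)` values (unselected columns get p = 1), as
separate additive and dominance tracks against the nominal threshold
`-log10(0.05) = 1.3` — no multiplicity adjustment, on the argument that
severe shrinkage in a joint multiple-marker model already controls false
positives.  Post-selection OLS inference is one defensible reading of the
reference procedure and is kept separate from the penalized fit so it can be
swapped.  KKT subgradient conditions of the penalized solution are asserted
in tests.

## Reports

`traitSummary()` and `pearsonMatrix()` produce the descriptive-statistics and
correlation tables in their conventional layouts (pairwise-complete Pearson,
two-sided t flags at 0.05, unadjusted).  `annotateInterval()` intersects a
QTL physical interval with gene models (GFF3 via `rtracklayer`) using
closed-interval, strand-agnostic overlap — a gene abutting the interval end
counts — with an optional biotype filter, since published gene counts for
QTL intervals typically mean protein-coding models.

## Problem sizes used by the test and acceptance suites

All simulations are sized for a single desktop CPU, as package choices:

* *recovery study*: the 10-chromosome maize-like genome at 1/10 physical and
  1/4 genetic scale, 10 SNPs/Mb (about 2,500 raw SNPs, 800–900 bins after
  filtering), 199 individuals, three QTL at 8/12/18% explained variance
  (d = a/2, h² = 0.38), 200 permutations, 50 replicates;
* *robustness*: two 30-Mb/60-cM chromosomes, 15 SNPs/Mb, 199 individuals,
  2% genotype error, 30% heterozygote undercall, 10% missing, 50 replicates;
* *calibration*: three 20-Mb/80-cM chromosomes, 200 null traits, 200
  permutations each;
* *map-length recovery*: two 20-Mb chromosomes (100/80 cM), 25 SNPs/Mb,
  noiseless, 20 replicates.

The genetic-length rescaling in the recovery study keeps the ratio of window
span to crossover spacing near the motivating experiment's regime, where
roughly fourteen SNPs fall per centimorgan; without it, a desk-scale marker
count against full maize map lengths makes the 15-SNP window span tens of
centimorgans and the caller's double-crossover absorption dominates.

## Known limitations

* No crossover interference in the generator, uniform recombination in
  physical coordinates, and independent trait residuals.
* The sliding window is not a hidden-Markov caller; breakpoints resolve to
  about one window span, and very short double-crossover segments are
  absorbed (map lengths mildly underestimated at low SNP density).
* The chi-square p-value track for CIM is approximate (mixture
  non-regularity); use the permutation threshold for declaration.
* Imputation of the rare missing bin genotype at scan time is by flanking
  conditional probabilities inside the mixture, not a separate imputation
  pass.
* Physical support intervals (1.5-LOD) and the 20-cM merge radius are
  conventions; comparisons with analyses using other rules should expect
  interval-width differences.

## A minimal worked example

```{r example, eval = FALSE}
gen <- maizeGenome(scaleBp = 0.1, scaleCM = 0.25, snpsPerMb = 10)
qtl <- data.frame(trait = "KW", chrom = "6", pos = 6e6, a = 0.5, d = 0.25)
cfg <- simConfig(nIndividuals = 199, hetUndercallRate = 0.1, qtl = qtl,
                 h2 = 0.3, seed = 1)
sim  <- simulateF2(gen, cfg)
obs  <- gbsObserve(sim$genotypes, cfg)
flt  <- filterMarkers(obs)
bins <- buildBins(callBlocks(flt$genotypes))
map  <- buildMap(bins)
ph   <- simulatePhenotypes(sim$truth, cfg)
cof  <- selectCofactors(bins, ph, "KW")
thr  <- permutationThreshold(bins, map, ph, "KW", cofactors = cof,
                             nPerm = 1000, alpha = 0.05, seed = 2)
scan <- cimScan(bins, map, ph, "KW", cofactors = cof, threshold = thr)
callQtl(scan, bins, map)
```
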