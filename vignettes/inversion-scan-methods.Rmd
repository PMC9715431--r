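---
title: "Detecting and analysing inversion polymorphisms with invscan"
author: "invscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing inversion polymorphisms with invscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscan)
```

## The problem

Megabase-scale chromosomal inversions segregating within a species suppress
recombination in heterozygotes and partition genetic variation into large
haploblocks. In population resequencing data they leave a characteristic
signature: genomic windows where sample structure departs from the rest of
the genome, with individuals falling into three PC1 clusters (the two
homozygous arrangements and heterozygotes), elevated heterozygosity in the
middle cluster, block-wise linkage disequilibrium that vanishes within
homozygotes, near-zero crossover rates in heterozygous parents, and a
block of elevated differentiation between the homozygous classes.

`invscan` implements that entire analysis chain — detection, genotyping,
validation, mutational-load assessment, and the downstream evolutionary
analyses (divergent-selection simulation, geographic cline fitting,
genotype–phenotype association) — together with synthetic-data generators
that reproduce the statistical structure each stage assumes, so the whole
pipeline is testable end to end without any external data.

## The scan

Windows of 100 kb (size and step configurable) are summarized by a local
PCA of the sample covariance of mean-imputed, mean-centred dosages. The
top k = 2 eigenvalues are divided by the covariance trace so windows with
different SNP counts are comparable; windows with fewer than 10
polymorphic SNPs are excluded. The distance between two windows is the
Frobenius distance between their trace-normalized rank-2 covariance
reconstructions,

d^2 = sum(lambda_a^2) + sum(lambda_b^2)
      - 2 sum_{a,b} lambda_a lambda_b (u_a . u_b)^2,

which is embedded by classical (Torgerson) MDS. Windows are clustered in
(MDS1, MDS2) by k-means for k = 2..10 with the mean silhouette choosing k
(ties to the smaller k), and MDS1 is z-scored genome-wide over included
windows.

A candidate region is a maximal run of consecutive same-cluster windows
containing at least 10 consecutive windows with z > 1.5, reported from the
run's first to last above-threshold window. We deliberately treat the
z-threshold as a property the run must contain rather than one every
member window must satisfy: per-window z-scores fluctuate (in simulations,
a 50-window inversion almost always has at least one interior window dip
below 1.5), and requiring every window to exceed the threshold fragments
true regions. Trimming to the outermost above-threshold windows keeps the
reported boundaries tight.

Sign indeterminacy of eigenvectors and MDS axes is resolved by making the
largest-magnitude coordinate positive, so results are reproducible across
platforms; the scan is invariant to sample ordering.

## Genotyping a region

For each candidate region, a PCA over all SNPs in the region (no MAF
filter or thinning) is computed with Patterson scaling — centre by 2p and
divide by sqrt(p(1-p)) — with missing dosages imputed to the SNP mean and
10 components retained. Samples are clustered on PC1 by k-means with
k = 3, starting centres at the minimum, midpoint and maximum (so unequal
cluster sizes cannot drag the starts), falling back to k = 2 when three
clusters degenerate. The middle cluster is called heterozygous; a post-hoc
check requires it to have the maximal mean heterozygosity, otherwise the
call set is flagged ambiguous rather than silently reassigned. Which PC1
extreme is the derived (inverted) arrangement cannot be determined from
the genotype data and is an input label (for deer mice it comes
from outgroup genome alignment).

New samples are projected onto the stored loadings after scaling with the
training allele frequencies, and genotyped by the nearest PC1 cluster
centre. A call is made only when the distance to the nearest centre is
less than half the gap to the adjacent centre (margin configurable);
otherwise the genotype is missing. For low-coverage data a set of
diagnostic SNPs fixed between arrangements supports a per-sample
maximum-likelihood call under binomial read sampling with error rate
epsilon (default 0.01).

Hardy–Weinberg equilibrium of the resulting genotype counts is tested with
the asymptotic Pearson chi-square on 1 degree of freedom, without
continuity correction; monomorphic count vectors are flagged undefined.

## Validation statistics

**LD.** SNPs are filtered to MAF strictly greater than 5% and thinned to
one per kb, then mean squared dosage correlation (geno-r2, pairwise
complete, at least 4 complete pairs) is computed between all SNP pairs
spanning 500 kb window pairs. Inside an inversion this matrix is uniformly
elevated when all genotypes are included and collapses within a homozygous
class. The small-sample expectation of r2 between independent SNPs is
1/(n-1), which sets the noise floor for the contrast.

**F_ST.** The Hudson estimator with sample-size correction is windowed as
a ratio of sums (sum of per-SNP numerators over sum of denominators), with
allele counts as n. Negative window values are reported as computed.
Identical groups give a small negative value of about -1/(n-1) — the
correction's finite-sample signature, not a bug. Within-inversion
haplotype differentiation uses 10 kb windows; genome-wide population
comparisons use 100 kb.

**Recombination.** Crossovers in F2 intercross panels are counted as
ancestry state changes along ordered markers; AA to BB directly counts as
two. Single-marker runs are removed as genotyping errors, and so are runs
of up to 2 markers flanked by the same state on both sides: paired
miscalls otherwise masquerade as double crossovers, and at 100 kb marker
spacing with sub-cM/Mb rates a genuine double crossover inside one or two
intervals has probability of order 1e-3 per gamete, so the induced
downward bias is about 2% — far less than the upward bias errors would
cause. Map length is 100 x crossovers / (2 n_F2) cM (two meioses per F2);
a crossover belongs to a region iff its midpoint (between flanking
markers) falls inside. Double crossovers between adjacent markers are
invisible, an acknowledged downward bias at sparse markers.

## Mutational load and breakpoint statistics

Coding SNPs are classified by swapping the alternate allele into its
reference codon (strand-aware); codons carrying more than one variant are
conservatively excluded. Per-site diversity is the unbiased pairwise
heterozygosity 2p(1-p)n/(n-1). pN/pS and piN/piS are computed in 500 kb
windows restricted to sites segregating within the supplied (single
homozygote class) sample set, with ratios flagged undefined when the
denominator is zero. Contrasts use Welch t-tests (two-sided between
haplotype classes, one-sided against genome-wide windows).

Breakpoint statistics: unsigned distance to the nearest annotated TSS and
a gene-disruption flag; an exact two-sided binomial test (minimum
likelihood rule) of in-gene breakpoints against the gene density computed
from the supplied annotation as union(gene spans)/genome length (the
original annotation gives 0.39, but the density is always recomputed);
and a two-sample Kolmogorov–Smirnov test of segmental-duplication density
in +/-500 kb breakpoint flanks against random genome-wide sites, with
flanks truncated at chromosome edges (realized flank length as the
denominator) and breakpoints at chromosome ends excluded. SD interval
tables are filtered declaratively with the standard thresholds (length
at least 1 kb, identity at least 70%, less than 70% repeat-masked).

## Divergent selection, clines, associations

**Two-deme Wright–Fisher.** Discrete generations with the fixed life
cycle selection -> migration -> binomial drift (the order matters at large
scaled s, so it is part of the contract). Fitnesses are 1+s, 1+hs, 1 with
h = 0.5 by default. Parameter rescaling by lambda divides N and times and
multiplies m and s, keeping Nm and Ns invariant; the introduction "as a
single copy" is materialized as the frequency 1/(2N) of the pre-scaling
deme, since frequencies are scale-invariant. The rescaling is a diffusion
approximation: it is exact in distribution only in the limit, and the
scaled run lives on a 1/(2N/lambda) frequency grid, so equivalence checks
must compare regimes where the dispersion of the statistic is much larger
than that grid. Demographic defaults (N = 10,000 per deme, m = 1e-3
symmetric) are placeholders rather than fitted forest–prairie estimates;
the split time default (2.2e6 generations) is the reported estimate for
those ecotypes. The summary statistic is the fraction of replicates
with |p_forest - p_prairie| above a threshold (default 50%).

**Clines.** Allele frequency along a gradient follows
p(x) = pMin + (pMax - pMin)(1 + tanh(2(x - c)/w))/2, optionally with
exponential tails beyond delta km from the centre that match the sigmoid's
value at the junction and decay with tau times its slope there (a
Szymura–Barton-style form, the standard hybrid-zone convention; the
curve is continuous by construction and slope-continuous at tau = 1). Ten families (scaling
fixed/free x tails none/left/right/mirror/both) are fit by bounded
maximum likelihood (binomial log-likelihood, L-BFGS-B, 20 random restarts
plus warm starts of tailed families from the same-scaling untailed
optimum) and ranked by AICc; families with n_sites <= k + 1 are skipped.
"Fixed" scaling pins pMin/pMax to the terminal-site frequencies — pinning
to the min/max over all sites chases single-site sampling noise and lets
tail parameters act as surrogate free asymptotes, which inverts model
choice on null data. A caveat users should know: at typical hybrid-zone
designs (tens of sites, tens of diploids per site) tail parameters are
weakly identified, and AICc correctly prefers the untailed family unless
tails are strong and sampling is deep; centre and width, by contrast, are
recovered within a few percent.

**Associations.** Trait ~ (covariate +) genotype by least squares with
genotype coded 0/1/2; the genotype p-value comes from the ANOVA
decomposition with the covariate entered first, PVE is the genotype sum of
squares over the total, and Bonferroni correction defaults to 13 tests
(the number of ecotype-differentiating inversions a deer-mouse screen
tests).

## The synthetic world

The generators state a world; they are first-class, tested code:

- `simulate_population_vcf`: haplotypes carry independent per-SNP draws
  from a background MAF law (uniform on 0.05–0.5 by default, 1 SNP/kb);
  inside the inversion, haplotypes belong to one of two arrangement
  classes, a `divergence` fraction of region SNPs differ between classes
  by `delta_p` (default 0.9), and diploids pair classes in Hardy–Weinberg
  proportions unless an F-style deviation is set. Background LD is zero by
  construction so the inversion's block signal is unambiguous — real
  genomes have background LD, so a green detection test establishes
  signal recovery, not false-positive behaviour under linked structure.
- `simulate_f2_cross`: per-gamete Poisson crossovers (no interference,
  as in standard map-length models), zero crossovers inside inversions
  whose F1 parents are heterozygous, uniform positions, and symmetric
  per-marker genotyping error.
- `simulate_transect_counts`: binomial allele counts at each site under a
  true cline.
- `simulate_coding_region`: genes of random sense codons on both strands,
  at most one planted variant per codon, synonymous/nonsynonymous at
  class-specific rates with an exact truth table (and the reference
  sequence, which codon-context classification requires).
- `simulate_phenotypes`: y = a g + b body_length + noise; defaults a =
  2.7 mm, noise 4.8 mm give ~12.5% variance explained at F2 genotype
  variance 0.5, matching the largest per-inversion tail-length effects
reported in deer mice.

All generators are deterministic given a seed and do not disturb the
caller's RNG state.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; VCF positions convert at
  the I/O boundary. Variants on a window's end coordinate belong to the
  next window; final partial windows are retained.
- Missing genotypes are a distinct state everywhere; imputation happens
  only inside PCA scaling, never at I/O.
- `pca_map_distance` is a sqrt of a cancellation-prone sum: identical
  windows give ~1e-8, not exact zero.
- MAF exactly at the threshold is removed (strict inequality);
  monomorphic SNP pairs and pairs with fewer than 4 complete samples are
  skipped in LD; windows with pS = 0 are flagged, not divided.
- k-means uses fixed seeds derived from the run seed; silhouette ties go
  to the smaller k; empty-cluster failures fall back to smaller k.
- HWE, load, and KS tests flag undefined inputs (monomorphic counts,
  zero-variance groups, empty density sets) instead of erroring.

## Known limitations

- Divergence between arrangement classes is modelled as per-SNP frequency
  contrasts, not coalescent history; LD decay, gene conversion and
  recombination within classes are absent.
- The scan is a single-population (or pre-pooled pair) scan; no
  multi-population joint model.
- Crossover interference, sex-specific maps and pedigree errors are out
  of scope; double crossovers between adjacent markers are invisible.
- Ancestral/derived orientation is an input label, not inferred.
- The Wright–Fisher model has no linked selection or genomic background.
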