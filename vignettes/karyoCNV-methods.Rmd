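---
title: "Methods: chromosomal anomaly detection and CNV burden analysis"
author: "karyoCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosomal anomaly detection and CNV burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoCNV)
```

# Scope

karyoCNV re-implements, as a tested and reusable pipeline, the analysis arc
of a SNP-array case--control copy-number study of recurrent depressive
disorder: chromosomal-anomaly screening from B-allele-frequency (BAF) and
log-R-ratio (LRR) summaries, multi-algorithm CNV consensus building with
tiered filters, and the case--control statistical layer (exact 2x2 tests,
permutation burden grid, phenotype regression with effective-test
correction, power calculations). The original cohort is not distributable,
so the package pairs every detector with a synthetic-array generator that
renders known karyotypes into realistic signal; all recovery claims in the
test suite are claims about that generator's signal model, made precise
below.

# The signal model

At a marker genotyped with `b` B alleles out of `c` chromosomal copies, the
generator centres BAF on `b/c` and LRR on `mu(c)`, a configurable
copy-number response with `mu(2) = 0`. For a mosaic in which a fraction `f`
of cells carries `(b2, c2)` against a constitutional `(b1, c1)`:

$$\mathrm{BAF} = \frac{(1-f)\,b_1 + f\,b_2}{(1-f)\,c_1 + f\,c_2},
\qquad
\mathrm{LRR} = \mu\big((1-f)\,c_1 + f\,c_2\big)$$

with `mu` linearly interpolated between integer copy numbers. Two
consequences drive all of the detection logic:

* a heterozygous diploid site (`b1 = 1, c1 = 2`) under monosomy mosaicism
  splits into bands at `1/(2-f)` and `(1-f)/(2-f)`, i.e. displaced from
  0.5 by `d = f / (2(2-f))`;
* under trisomy (and diploid/triploid) mosaicism the displacement is
  `d = f / (2(2+f))`, reaching the familiar 1/3 and 2/3 bands at `f = 1`.

Both displacement maps are strictly increasing in `f`, so the observed
displacement inverts to a fraction estimate: `f = 4d/(1+2d)` (monosomy) and
`f = 4d/(1-2d)` capped at 1 (trisomy); `estimateMosaicFraction()` is that
inverse and the tests exercise it across the grid `f = 0.2..0.8`.

Uniparental isodisomy (UPD) is modelled as two identical copies: copy
number 2 throughout, all sites homozygous, except an optional distal
fraction of markers that reverts to population heterozygosity (the
partial-recombination signature at the telomeric end of a chromosome arm).

Noise is Gaussian per marker: `lrrSd` (default 0.20, log2 units) and
`bafSd` (default 0.03) at heterozygous bands, with homozygous-band BAF
noise halved and clipped at the 0/1 boundary so that hom clusters never
bleed into the heterozygous window. The LRR response defaults to
`mu = (-3.5, -0.66, 0, 0.40, 0.68)` for copies 0--4 -- canonical
Illumina-array expectations; no source values exist for these and they are
fully configurable through `NoiseModel()`. The defaults describe
blood-derived DNA of good quality; degraded (e.g. buccal) DNA corresponds
to larger `lrrSd`, and the QC layer is calibrated to fail such samples.
Sex chromosomes follow dosage: XY males carry X at copy 1 (no heterozygous
band) and Y at copy 1; samples without a Y emit copy-0 background on Y
markers (LRR centred on `mu(0)`, uniform BAF), which is exactly the signal
the Y-based sex check keys on.

Marker maps place markers uniformly across the 22 autosomes (each autosome
equally likely) with positions uniform over hg19-like chromosome lengths,
plus X and Y panels, and attach a fixed per-marker population B-allele
frequency drawn once from Uniform(0.05, 0.95). The default test map holds
~100 markers per autosome -- about 250x sparser than a production 610k
array. Every threshold below is calibrated at that density, and the two
places where density genuinely matters (the distal-recovery run length and
the tier marker floors) are discussed explicitly.

# Anomaly detection

`summarizeChromosomes()` computes, per sample and chromosome, the LRR mean
and the BAF heterozygosity rate (fraction of markers with BAF in the
heterozygous window, default [0.25, 0.75] -- the field-standard
operationalization, configurable). Each statistic is converted to a
z-score against the mean and SD of that statistic across all *other*
autosomes of the same sample. The leave-one-out reference prevents a large
anomaly from inflating its own reference SD; sex chromosomes are scored
against the full autosomal reference. With ~20 reference autosomes the
z is t-like rather than normal, so raw 3-SD excursions occur at a rate of
roughly 1% of chromosome statistics; this is why flags alone are never
calls.

The screening rule (flag anything deviating by more than 3 SD) is resolved
by an explicit decision table in `classifyAnomaly()` rather than by visual
inspection, for reproducibility:

1. **gain**: `z_lrr > 3` *and* `lrr_mean >= 0.1` -- full trisomy when the
   band displacement implies `f >= 0.95`, otherwise mosaic trisomy with
   the inverted `f`;
2. **loss**: `z_lrr < -3` *and* `lrr_mean <= -0.1` -- full monosomy when no
   interior band remains, otherwise mosaic monosomy by inversion;
3. **isodisomy**: copy-neutral LRR (|z| <= 2.5 *or* |mean| <= 0.1) with a
   heterozygosity z below -3 and a heterozygosity rate under 0.2 --
   complete UPD when the rate is under 0.02, partial-recovery UPD when a
   distal run of at least 10 markers regains heterozygosity (rate >= 0.12
   in the run, < 0.02 before it);
4. **genome-wide diploid/triploid mosaicism**: a split heterozygous band
   (displacement >= 0.05) on at least 10 autosomes that are individually
   unflagged -- a genome-wide shift cancels in the within-sample
   leave-one-out reference, so this class is only visible genome-wide.

Contradictory evidence (an LRR flag without the corroborating band
structure, typically a large segmental CNV dragging a whole-chromosome
mean) is reported as the LRR-driven class with a warning flag, never
silently dropped; whole-sample karyotype classification ignores
warning-flagged calls.

Three deliberate departures from a bare 3-SD rule deserve note. First, the
absolute-magnitude gates (`lrr_mean` beyond +/-0.1 for aneuploidy) exist
because 21 autosomes x 2 statistics x cohort-scale sample counts make
chance 3-SD excursions certain; the gates cost nothing at chromosome scale
(a true trisomy sits ~20 SE from zero at default noise) and take the
false-call rate on clean diploid cohorts to zero, which the acceptance
suite asserts on 200 samples. Second, the copy-neutral criterion for UPD
accepts either the relative (z) or the absolute test, because on a
chromosome whose true LRR mean is exactly zero the leave-one-out z still
has unit variance and a pure `|z| <= 1.5` rule would reject ~13% of true
isodisomies for no reason. Third, the distal-recovery run floor is 10
markers rather than a larger value: at ~100 markers per chromosome a 20%
distal recovery segment holds only ~20 markers, and the feasibility search
(any suffix between the floor and half the chromosome, heterozygosity
< 0.02 before the boundary) makes a false partial-recovery call on a truly
homozygous chromosome essentially impossible, since stray heterozygous
noise cannot reach the window.

Band displacement `d` is estimated from interior BAF values (window
(0.05, 0.95), at least 10 markers) as the solution of
`E|X - 0.5| = m` for `X ~ N(0.5 +/- d, sigma)` -- a folded-normal mean
inversion using the configured `bafSd` as `sigma`. The naive mean absolute
displacement is biased upward by noise when `d` is comparable to `sigma`
(a mosaic fraction of 0.2 gives `d = 0.056` against `sigma = 0.03`); the
folded inversion removes that bias, and the acceptance suite checks a mean
absolute fraction error of at most 0.05 over the `f` grid at >= 500
markers per chromosome (observed: under 0.01).

Sex is predicted twice, independently: from the X heterozygosity rate
(below 0.05 implies a single X) and from the Y LRR mean (above -1.0
implies a Y is present), with double-X samples promoted to 47,XXX
candidates when the X dosage z against the autosomes exceeds 3 -- the
heterozygosity rate cannot separate XX from XXX, but the LRR dosage can.
Discordance with a reported sex is flagged, never auto-corrected.

# Consensus, tiers, rarity

Per-sample QC passes a sample when the autosomal LRR SD is at most 0.30,
BAF drift (fraction of values in (0.2, 0.25) or (0.75, 0.8)) at most 0.01,
and no single algorithm contributes more than 30 calls. The metrics are
autosomal because sex-chromosome dosage is karyotype, not assay quality.
Thresholds are recorded with each result.

`mergeCallsets()` groups same-sample, same-state calls from different
algorithms by transitive >= 1 bp overlap (deletions and duplications never
merge) and keeps groups supported by at least `minSupport` distinct
algorithms. The consensus interval is the intersection of the group --
conservative against boundary over-call -- with the union available as
`boundaryRule = "outer"`. A transitive group can lack a common core (A
overlaps B, B overlaps C, A misses C); the strict rule then falls back to
the union and marks `core_empty`, rather than inventing an interval or
splitting the group. Marker counts are recomputed from the map over the
final interval, and the operation is idempotent and order-invariant
(asserted by test).

Two filter tiers mirror the two analysis layers of the study design:
*large* keeps length strictly over 1 Mb with strictly more than 100
markers and deliberately does not require multi-algorithm support (the
large-CNV analysis pooled all calls); *phenotype* keeps length over
100 kb, at least 10 markers, and support from all three algorithms. The
inequalities are applied exactly as printed (strict vs inclusive), and the
function defaults carry the full-density values; the demo pipeline's
config scales the marker floors down (to 2) because at ~0.8 markers/Mb a
literal 100-marker floor would describe a 130 Mb event.

Rarity classes cluster CNVs cohort-wide by same state and >= 50%
reciprocal overlap (transitive closure, union-find): singleton clusters of
size one, common clusters spanning over 1% of samples, rare otherwise.
The reciprocal-overlap and frequency defaults are the field-standard
values. Transitive clustering is simple and order-invariant but can chain
distinct events bridged by one long call; the brute-force pairwise oracle
in the test suite checks the closure, not a stronger claim.

# The statistical layer

`fisherExact()` is implemented in-package: with all margins fixed the
case-carrier count is hypergeometric, the two-sided p sums the
probabilities of all tables at most as probable as the observed one (the
minimum-likelihood convention of standard exact-test implementations), the
one-sided p is the enrichment tail, the conditional-MLE odds ratio
maximizes the noncentral hypergeometric likelihood (solved by unirooting
the mean function on the log-odds scale), and the 95% CI inverts the exact
tails at 0.025 per side, with an infinite upper bound when the carrier
count sits at its margin maximum. The implementation is cross-checked in
the tests against both the reference implementation in `stats` and an
independent log-binomial-coefficient enumeration over every 2x2 table with
total at most 40. The cross-product (sample) odds ratio is reported
alongside because the printed tables of the motivating study reproduce
under the cross-product at 2 decimal places for every pinned contrast;
one printed value (3.46, duplications vs screened controls) matches
neither estimator (both give 3.50) and is displayed but never asserted.
Printed confidence intervals match no standard method and are not pinned
either.

Burden testing follows the permutation design: 3 contrasts (cases vs all
controls, vs screened controls, vs population controls) x 3 CNV classes
(all, deletions, duplications) x 7 per-sample statistics -- carrier
indicator, CNV count, total kb, mean length, genes covered, mean genes per
CNV, genic-CNV count -- for 63 tests, with the Bonferroni threshold
.05/63 = .00079. The identity of the 7 statistics is this package's
declared reconstruction (the original list is not public); the count and
the grid structure are fixed and asserted. The observed statistic is the
difference in arm means, one-sided (case > control) by default; labels are
permuted preserving arm sizes and the empirical p uses the add-one
correction, so p is never zero and its null distribution is super-uniform.
CNV-free samples contribute zeros to counts and totals but are excluded
from per-CNV means; a permuted arm that ends up all-missing counts as a
non-exceedance. Type-I error at the 5% level is asserted to lie in
[0.03, 0.07] over 500 null cohorts.

Phenotype association is ordinary least squares of each clinical phenotype
(age of onset in years, duration of worst episode in weeks, and the three
Eysenck personality scores) on per-sample burden, with listwise deletion
and the complete-case n reported -- no covariates by default, matching the
unconditional design, with hooks for covariates. Multiple-testing
correction uses the spectral decomposition of the phenotype correlation
matrix: both the eigenvalue-dispersion effective-test count
`1 + (M-1)(1 - Var(lambda)/M)` and the integer/fractional partition
`sum(1{lambda>=1} + frac(lambda))` are reported, with `alpha/v_eff` and
the Sidak variant. The motivating study's corrected level (.0073 from 5
traits) implies ~6.8 effective tests, which no `v_eff <= M` method can
produce from 5 phenotypes -- most plausibly additional tests were folded
in; the value is therefore displayed in documentation but never asserted,
and the package computes its corrections from the data at hand.

Power: the linear-model figure uses the noncentral F distribution,
`P(F'(1, n-2; ncp = f2 n) > F_{1-alpha}(1, n-2))`, which reproduces the
printed 88% at `f2 = .005, n = 1940, alpha = .05` and is cross-checked in
the tests against the normal approximation `Phi(sqrt(ncp) - z_{1-alpha/2})`.
The two-proportion design offers the pooled-null z approximation and an
exact simulation (binomial draws through `fisherExact`, rejection rate
with a Monte Carlo SE). The calculator settings behind the printed 99% and
75% two-proportion figures are not recoverable (sidedness and
exact-vs-approximate are unstated), so only the linear-model figure is
pinned.

# The pipeline and reproducibility

`runPipeline()` chains simulate -> callsets -> detection -> QC ->
consensus -> tiers -> burden -> association from a single serializable
config; the config (including the master seed) is written next to the
outputs, every stochastic stage derives a child seed deterministically,
and identical configs produce byte-identical statistical outputs
(asserted). The run report recomputes its own 2x2 tables through
`fisherExact`, so the printed frequencies and the printed statistics can
never drift apart. `reproducePublishedTables()` re-derives every printed
contrast statistic from the transcribed carrier counts shipped in
`extdata/published_counts.tsv` at run time -- nothing in that path is
simulated, looked up, or cached.

Problem sizes in the default test and acceptance runs were chosen to keep
a full check of the package in the low minutes on one core: ~2,400-marker
maps, 400-sample classification cohorts, 25 replicates per mosaic
fraction on an ~11,600-marker map, 500 null cohorts for the type-I check,
1,000 cohorts for regression coverage, and 99--499 permutations per grid
test in the demo pipeline (10,000 is the analysis default).

# What passing tests do and do not show

The generator produces Gaussian per-marker noise around exact band
positions, with no GC waviness, no plate or batch structure, no
probe-level (X/Y channel) effects, and markers placed uniformly rather
than with real array spacing. Detection and recovery results on this
signal therefore demonstrate the correctness of the estimators and
decision logic, not their operating characteristics on real arrays --
thresholds that separate classes by tens of SE here will separate less
cleanly under wave artefacts, and the QC layer (LRR SD, BAF drift, call
count) is exactly the part of a real pipeline that absorbs that gap.
Segmental (sub-chromosomal) mosaicism detection, somatic-vs-constitutional
attribution, and re-implementation of the underlying HMM callers are out
of scope; the caller layer is emulated with jittered truth plus
false-positive/negative noise so that consensus logic is testable without
the callers themselves.
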