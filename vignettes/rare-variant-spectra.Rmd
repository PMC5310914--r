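---
title: "Methods: analysing population differences in the rare-variant mutational spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant mutational spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `mutspect`, the
assumptions behind them, the parameters that matter, and the design choices
made where the methodology left room for judgement.

## The 96-class spectrum

A single-nucleotide mutation is classified by its ancestral base, its
derived base, and the two flanking reference bases, giving
6 substitution types x 16 flank pairs = 96 classes once reverse-complement
pairs are merged. We store classes pyrimidine-centred: a `G>A` change is
read through the reverse complement of its full context, so `CGT` with
`G>A` is the class `ACG>T`. Contexts are read 5'→3' on the reference
strand. Because reverse-complement collapsing merges each class with its
mirror, the resulting 96-part partition is identical whichever strand
convention the input uses; the choice only matters for strand-bias
analyses, where classes are deliberately *not* collapsed.

Counting rules for a sample: a homozygous-derived genotype contributes 2
copies, a heterozygote 1. The allele-count stratum (e.g. doubletons, `f2`)
is defined on the total derived count over *all* samples jointly,
population labels ignored. Records are excluded when they are
multi-allelic, when the ancestral annotation is not confidently assigned
(lowercase `AA`), when the ancestral allele matches neither REF nor ALT
(a triallelic history), or when the site lacks flanking context.

Two normalizations of the count matrix `C` (96 x samples) are supported:
division by each sample's `ATA>C` count — the most common class and a
stable baseline across populations — or by each sample's total. Ratios
between classes within a sample are identical under both, so downstream
inferences that depend only on relative intensities are
normalization-invariant.

## Signature inference

Intensities `X` are factorized as `X ≈ W H` with `W >= 0` (96 x k class
weights) and `H >= 0` (k x samples loadings), using multiplicative updates
for the Euclidean (Frobenius) objective. The Euclidean divergence was
chosen because the residual sum of squares is the fit diagnostic we report;
each update step provably does not increase the objective, which the test
suite asserts to 1e-10 relative tolerance.

**Initialization.** The default initializer runs a fixed-point ICA
(whitening by SVD, tanh contrast, symmetric decorrelation, tolerance 1e-4,
up to 3 restarts of 200 iterations) on `X`, orients each component so its
sum is positive, and clamps negative entries. Multiplicative updates
rescale entries by ratios, so an entry clamped to a negligible value stays
frozen near zero; we therefore floor clamped entries at 1% of the
component's mean absolute value rather than at machine epsilon. With a
bare-epsilon floor the ICA-initialized fit converges measurably more
slowly and to slightly worse optima than random initialization; with the
relative floor the two reach equivalent optima, and the suite asserts
near-equality rather than superiority of either (random initialization can
reach exactly-zero residual on exact low-rank input, a difference with no
scientific content). If the ICA iteration fails to converge the fit falls
back to a random start, with a warning.

**Determinism.** Factor order is arbitrary in NMF, so factors are reordered
by descending total loading; diagnostics and fits are reproducible under a
seed.

**Rank selection** is reported, never decided automatically: for each
candidate rank we run `n_starts` random starts (default 50; 200 is a
config away) and report (i) the consensus-matrix dispersion, the mean of
`4 (C - 1/2)^2` over the average co-clustering matrix of
sample-to-dominant-factor assignments — 1 when cluster structure is
perfectly reproducible across runs; (ii) the best rss; (iii) the mean
silhouette of the dominant-factor assignment with distance
`1 - Pearson correlation` of loading profiles (the silhouette metric is not
prescribed anywhere; correlation distance matches how loading profiles are
compared elsewhere in the package). To make best-rss exactly non-increasing
in rank — the property a reader expects of nested models — each rank also
receives one warm start: the previous rank's best factorization padded with
one small extra factor, which multiplicative updates can only improve.

**Presentation aids.** For plotting and catalog comparison, class weights
are rescaled by the genome frequencies of their 32 contexts; the scale is
then not directly interpretable and no inference uses it. Catalog
comparison is plain Pearson correlation in the 96-dimensional class space,
ranked descending; COSMIC-style labels (`A[C>A]A`) are accepted and
mapped. The CpG-floor correction subtracts, per CpG class, the
across-signature minimum weight: when NMF is run from random starts every
factor tends to absorb a constant amount of the dominant CpG classes, and
removing the shared floor (an idempotent operation that leaves non-CpG
classes untouched) recovers the interpretable structure.

## Genomic strata

Strand bias: each base is labelled `+`, `-`, `both` or `none` by the union
of transcribed intervals; `both`/`none` positions are ignored. A mutation
whose pyrimidine representation lies on the same strand the region is
transcribed on counts as *untranscribed* (the annotation names the strand
carrying the transcript's sense sequence; the template strand is the
transcribed one). The log-ratio uses the natural log (configurable). When
either count is zero we add 0.5 to both (Haldane), flagging the sample —
chosen over dropping samples because extreme-but-finite values carry
information in small panels.

Methylation: the rate ratio divides per-site rates, not raw counts, because
high- and low-methylation site lists differ in size by design. The exact
2x2 test sums hypergeometric probabilities no larger than the observed
table's (the classic two-sided convention, with the standard `1 + 1e-7`
tolerance for floating-point ties); degenerate margins give p = 1.

Decile stratification assigns each variant the decile label of its
covering interval (deciles computed over fixed-size bins, then applied per
base) and reports per-group, per-decile class-set proportions, keeping
empty cells as zeros rather than dropping them.

## Coalescent simulation of single and repeat mutations

Genealogies for `n` haplotypes follow the standard coalescent: with `k`
lineages the waiting time is exponential with rate `k(k-1)/2`, and a
uniform pair merges. Mutations fall on branches as a Poisson process with
mean `theta/2` per unit branch length; a mutation's derived allele count is
the number of leaves below its branch. `theta` defaults to 2 — the spectra
we use are shape-only, so the value only sets Monte-Carlo resolution.

Exponential growth is simulated by rescaling node times with the exact map
`t' = (1/g)(e^{gt} - 1)` for `t <= s` and `t' = (1/g)(e^{gs} - 1) + (t-s)`
beyond the onset `s`, `g = log(N)/s` for `N`-fold growth. The map is
continuous, strictly increasing, and the identity at `N = 1`; with
human-like parameters (Ne = 15,000, 30-year generations) the default onset
`s = 0.01` corresponds to about 9,000 years.

A repeat (recurrent) mutation is the OR of two independent length-weighted
placements on the same genealogy. In a tree, two clades are either nested
or disjoint, so the union's allele count is the larger clade or the sum —
no genotype vectors are needed for spectra, though carrier sets are
available. Events whose union covers all leaves are excluded from
segregating spectra as fixed (the excluded count is reported). The two
placements are drawn on the same tree — both mutation events happen at one
site in one population, so they share a genealogy. Single and repeat
spectra are normalized separately; their relative weight enters only
through the mixture model below.

The CpG mixture model assumes a fraction `frac_cpg = 0.15` of mutations
occur at CpG sites and `frac_repeat = 0.10` of those are repeat events.
The modelled CpG proportion at allele count `i` is then
`frac_cpg ((1-frac_repeat) S_i + frac_repeat R_i)` over that quantity plus
`(1-frac_cpg) S_i`, with `S` and `R` the unit-normalized single and repeat
spectra. Two exact identities pin the implementation: `R = S` gives
`frac_cpg` at every count, and an empty repeat spectrum at the defaults
gives `0.135/0.985 ≈ 0.1371` everywhere.

## The damage-robust M statistic

Ancient DNA carries post-mortem cytosine deamination, inflating C>T calls
and mimicking signature 1. The corrected log-ratio pairs each signature-1
context `XC{C,T}` with the control context `XCA`, all as C>T classes:
`M = log2[(X_TCC X_ACC X_TCT X_CCC) / (X_TCA X_ACA X_TCA X_CCA)]`, with
`TCA` appearing twice to balance four numerator contexts against three
distinct controls. A uniform multiplicative excess of C>T calls multiplies
numerator and denominator by the same factor and cancels exactly (asserted
to 1e-12); per-sample normalization cancels likewise, so raw counts can be
used directly. M values are standardized so a designated reference panel
(African samples in the motivating analysis) has mean 0, SD 1. When any of
the eight classes is zero we add 0.5 to all eight before forming the ratio
(logged); uncertainty comes from multinomially resampling the sample's
class counts with the observed total preserved (Poisson resampling is
available), reporting 5% and 95% quantiles. Ancient samples are scored
only on heterozygous sites that are singletons in the modern panel, which
ascertains recent variation while avoiding genotype-quality artifacts.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. It
emulates: a reference with controllable base composition and CpG density
(first-order Markov chain; `cpg_boost = 0` deletes CG dinucleotides
entirely); multi-population diploid panels in which each variant originates
in one population, draws its class from context availability times planted
per-class multipliers, lands uniformly on an unused admissible site, and
assigns derived copies within the origin population (doubletons: one
homozygote with probability 0.1, else two heterozygotes); allele counts
either fixed or drawn from coalescent spectra simulated per population
(respecting growth models, 200 trees by default); planted repeat CpG
doubletons whose two carriers are drawn panel-wide and can straddle
splits; lowercase ancestral annotations at a configurable rate; and
strand, methylation and decile annotation tracks.

What it does *not* emulate — and hence what passing tests cannot show
about real data: linkage disequilibrium (variants are independent),
back-mutation and reference error (the ancestral allele always matches the
reference), sequencing and genotyping error, cell-line artifacts beyond a
metadata label, and realistic genome composition (contexts are near-
uniform unless configured otherwise). Planted effects are recovered up to
a known renormalization: boosting some classes of one population deflates
its other classes by the normalizing constant, which cancels in intensity
ratios but compresses raw class-fraction ratios.

## Numerical choices and problem sizes

Convergence: NMF stops at a relative objective change below 1e-6 or 2,000
iterations; denominators carry a 1e-9 guard. Zero-count cells: Haldane 0.5
for strand bias, pseudocount 0.5 for M, per-sample errors (never silent
NaNs) for zero normalization denominators. Degenerate inputs error with
the offending samples or classes named.

Monte-Carlo checks compare estimates to analytic expectations within
3 batch standard errors (batching over independent tree replicates, since
mutations within a genealogy are correlated and a naive multinomial SE
would be anti-conservative). The shipped validation suite uses 10^5 trees
of 50 haplotypes for constant-size calibration, 2 x 10^4 trees for growth
contrasts, a 96 x 100 rank-3 recovery problem at 5% noise, and panels of
up to 80,000 variants over 50 samples — sizes chosen so every planted
effect is detected at >5 standard errors while the whole suite stays
comfortably reproducible on a laptop.

## Known limitations

The coalescent module has no recombination, migration or multiple
mergers; the repeat-mutation model draws exactly two events per site; the
pipeline assumes a single reference contig per analysis; and NMF rank
choice remains the user's judgement on the reported diagnostics, as it
should.
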