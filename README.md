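# mutspect

Populations differ in the *spectrum* of their rare genetic variants — the
relative rates of the 96 trinucleotide substitution classes — even when
their total mutation rates are nearly identical. Two well-known examples in
humans: an enrichment of `TCC>T` / `ACC>T` / `CCC>T` / `TCT>T` mutations
("signature 1") in West Eurasians, and an enrichment of CpG transitions
(`NCG>T`, "signature 2") in some Native American populations that is driven
not by mutation rate but by recurrent mutation at hypermutable CpG sites
interacting with recent population growth.

`mutspect` is an R package for analysing such differences, aimed at
population geneticists working with polarized variant panels (VCF with an
ancestral-allele `AA` tag plus a reference FASTA). It provides:

- **Spectrum construction** — classification of polarized SNPs into the 96
  canonical pyrimidine-centred classes; per-sample count matrices
  `C_ij` for chosen derived-allele-count strata (doubletons `f2`,
  singletons `f1`, per-genome, arbitrary ranges), counting 2 copies for a
  homozygote and 1 for a heterozygote; intensities
  `X_ij = C_ij / C_{ATA>C, j}` or total-normalized columns.
- **Signature inference** — non-negative matrix factorization
  `X ≈ W H` by Lee–Seung multiplicative updates (Frobenius objective),
  initialized from the non-negative components of a fixed-point ICA;
  rank-selection diagnostics (consensus dispersion, rss, silhouette);
  catalog comparison by Pearson correlation; trinucleotide-frequency
  rescaling; a PCA alternative; and the CpG-floor correction for the
  CpG-absorption fitting artifact.
- **Genomic strata** — transcriptional strand bias log-ratios (mutations
  not collapsed with reverse complements), methylation-state rate ratios,
  exact 2x2 Fisher tests, and B-statistic / recombination-decile
  stratification.
- **Coalescent simulation** — standard-coalescent genealogies; exponential
  growth via the exact time rescaling
  `t' = (1/g)(e^{gt} - 1)` for `t <= s`, `t' = (1/g)(e^{gs} - 1) + (t - s)`
  otherwise, with `g = log(N)/s`; Poisson mutation placement; repeat
  (recurrent) mutations as the OR of two independent placements; pooled
  site frequency spectra; and the mixture model for the CpG proportion of
  variants by allele count.
- **Ancient-genome scoring** — the damage-robust corrected signature-1
  log-ratio
  `M = log2[(X_TCC X_ACC X_TCT X_CCC) / (X_TCA X_ACA X_TCA X_CCA)]`
  (all C>T classes; a uniform deamination excess cancels exactly),
  reference-panel standardization, and multinomial bootstrap quantiles.
- **Rate arithmetic** — the closed form `ΔN/M = (q - p)/(1 - q)` linking a
  signature-proportion shift to a total-rate change, repeat-fraction
  estimates from cross-population sharing, and coalescent-unit/year
  conversion.
- **A synthetic-data generator** — reference sequences with controllable
  CpG content, multi-population panels with *planted* per-class intensity
  multipliers, planted repeat CpG doubletons, coalescent-drawn allele
  frequencies, and annotation tracks — so every stage can be validated
  against known ground truth.

## Worked example

The numbered scripts in `analysis/` run the whole study on synthetic data
(`Rscript analysis/01_simulate_panel.R`, then `02`…`07`; outputs land in
`results/`). The core loop, condensed:

```r
library(mutspect)

ref <- generate_reference(genome_spec(150000, seed = 1))
sig1 <- signature1_definition()   # TCT>T, TCC>T, CCC>T, ACC>T
pops <- list(
  population_spec("WESTERN", "west_eurasia", 25,
                  class_multipliers = setNames(rep(1.5, 4), sig1$classes)),
  population_spec("AFRICAN", "africa", 25))
panel <- generate_panel(ref, pops, n_variants = 80000, seed = 1,
                        cpg_repeat_frac = 0.1)

counts <- count_spectrum(panel, ref, stratum = "f2")
props <- signature_proportion(counts, sig1)
west <- panel$samples$sample[panel$samples$population == "WESTERN"]
afr  <- panel$samples$sample[panel$samples$population == "AFRICAN"]
group_z(props, west, afr)
```

On this panel the analysis scripts print:

```
Mean signature-1 f2 proportion: 0.0629 (WESTERN) vs 0.042 (AFRICAN)
Group Z for the difference: 19.4
f2 sharing across the split: 0.052 (signature 2) vs 0.002 (all)
Singleton fraction: 0.222 (constant; analytic 0.223) -> 0.525 (growth)
Repeat/single doubleton enrichment: 0.52 (constant) -> 2.28 (growth)
Modelled CpG proportion under growth: 0.137 at count 1 vs 0.166 at count 2
Ancient (WESTERN): normalized M = 2.27 [5-95%: 1.31, 3.32]
Ancient (AFRICAN, 5x C>T damage): normalized M = -0.34 [5-95%: -0.81, 0.17]
Implied genome-wide rate increase: 1.1% (q = 8.8%) to 3.7% (q = 11.1%)
```

Reading these: the planted 1.5x boost is recovered as a cleanly separated
per-individual signature-1 proportion (Z = 19.4); planted repeat CpG
doubletons inflate cross-population sharing of signature-2 variants far
above the all-class background; exponential growth more than doubles the
repeat-mutation doubleton enrichment, which is what concentrates CpG
variants at allele count 2; the M statistic flags the boosted "ancient"
genome while ignoring one with heavy simulated deamination damage; and a
shift of the signature-1 doubleton proportion from 7.8% to 8.8–11.1%
implies at most a 1.1–3.7% change in the genome-wide mutation rate.

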