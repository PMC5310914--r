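#!/usr/bin/env Rscript
# Build the synthetic study panel: a 150 kb reference, two populations of 25
# diploid samples, and 80,000 doubleton variants. The "WESTERN" population
# carries a planted 1.5x intensity boost of the four signature-1 classes
# (TCT>T, TCC>T, CCC>T, ACC>T); "AFRICAN" is the neutral control. A tenth of
# CpG (NCG>T) doubletons are planted as repeat mutations, whose two carriers
# are drawn panel-wide and can therefore straddle the population split.

library(mutspect)

dir.create("results", showWarnings = FALSE)
seed <- 1

ref <- generate_reference(genome_spec(150000, seed = seed))
sig1 <- signature1_definition()

pops <- list(
  population_spec("WESTERN", "west_eurasia", 25,
                  class_multipliers = setNames(rep(1.5, 4), sig1$classes)),
  population_spec("AFRICAN", "africa", 25))

panel <- generate_panel(ref, pops, n_variants = 80000, seed = seed,
                        cpg_repeat_frac = 0.1)

write_reference_fasta(ref, "results/reference.fasta")
write_panel_vcf(panel, "results/panel.vcf")
write_sample_metadata(panel$samples, "results/samples.tsv")
write_truth_json(panel$truth[c("multipliers", "freq_source", "seed")],
                 "results/truth.json")

cat("Panel:", nrow(panel$variants), "variants x", nrow(panel$samples),
    "samples\n")
cat("Planted repeat CpG doubletons:", sum(panel$truth$is_repeat), "\n")
cat("Signature-1 class fraction (truth):",
    round(mean(panel$truth$class %in% sig1$classes), 4), "\n")
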