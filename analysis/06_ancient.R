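#!/usr/bin/env Rscript
# Damage-robust scoring of "ancient" samples. Modern samples are scored on
# the doubleton panel; two synthetic ancient genomes are scored on
# singleton-overlap sites of a coalescent-frequency panel: one from the
# boosted-signature population (WESTERN-like) and one from the control
# population with heavy uniform C>T deamination damage added. The M
# statistic should flag the former and ignore the latter.

library(mutspect)

ref <- read_reference_fasta("results/reference.fasta")
panel <- read_panel_vcf("results/panel.vcf", metadata = "results/samples.tsv")

counts <- count_spectrum(panel, ref, stratum = "f2")
m_raw <- apply(counts$counts, 2, function(x) as.numeric(m_statistic(x)))
afr <- counts$samples$sample[counts$samples$population == "AFRICAN"]
norm <- normalize_m(m_raw, afr)
mu <- attr(norm, "reference_mean")
sdev <- attr(norm, "reference_sd")
norm$population <- counts$samples$population[match(norm$sample,
                                                   counts$samples$sample)]
write.table(norm, "results/m_statistics_modern.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Mean normalized M: WESTERN",
    round(mean(norm$normalized[norm$population == "WESTERN"]), 2),
    "| AFRICAN", round(mean(norm$normalized[norm$population == "AFRICAN"]), 2),
    "\n")

# a coalescent-frequency panel supplies singleton sites for the ancient
# site ascertainment (the doubleton panel has none by construction)
sig1 <- signature1_definition()
pops <- list(
  population_spec("WESTERN", "west_eurasia", 25,
                  class_multipliers = setNames(rep(1.5, 4), sig1$classes)),
  population_spec("AFRICAN", "africa", 25))
panel_c <- generate_panel(ref, pops, n_variants = 60000,
                          freq_source = "coalescent", seed = 4,
                          sfs_trees = 300)

# synthetic ancient het-site list: the pooled singleton sites of the
# population the ancient genome derives from (a single real ancient genome
# contributes thousands of such sites genome-wide; one 150 kb sample-slice
# would give too few for a stable ratio)
het_singletons <- function(population) {
  in_pop <- panel_c$samples$population == population
  f1 <- which(colSums(panel_c$geno) == 1 &
                colSums(panel_c$geno[in_pop, , drop = FALSE]) == 1)
  data.frame(chrom = panel_c$variants$chrom[f1],
             pos = panel_c$variants$pos[f1])
}

for (pop in c("WESTERN", "AFRICAN")) {
  anc_counts <- ancient_site_filter(het_singletons(pop), panel_c, ref,
                                    stratum = "f1")
  # heavy uniform deamination damage on the AFRICAN-derived sample
  if (pop == "AFRICAN") {
    ct <- substr(names(anc_counts), 2, 2) == "C" &
      substr(names(anc_counts), 5, 5) == "T"
    anc_counts[ct] <- round(anc_counts[ct] * 5)
  }
  b <- bootstrap_m(anc_counts, n_boot = 1000, seed = 3,
                   reference_mean = mu, reference_sd = sdev)
  cat(sprintf("Ancient (%s%s): normalized M = %.2f [5-95%%: %.2f, %.2f] over %d sites\n",
              pop, if (pop == "AFRICAN") ", 5x C>T damage" else "",
              b$point, b$q05, b$q95, sum(anc_counts)))
}
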