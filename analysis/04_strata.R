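#!/usr/bin/env Rscript
# Genomic-feature stratification of the synthetic panel. The generator
# plants no strand asymmetry, methylation dependence or decile dependence,
# so these analyses are null calibrations: strand-bias log-ratios near 0,
# a methylation rate ratio near 1, and per-decile proportions flat and
# equal between populations.

library(mutspect)

ref <- read_reference_fasta("results/reference.fasta")
panel <- read_panel_vcf("results/panel.vcf", metadata = "results/samples.tsv")
L <- nchar(as.character(ref$sequence[[1]]))

# alternating +/- "transcripts" over the first two thirds of the genome
step <- 10000
starts <- seq(0, 2 * L / 3 - step, by = step)
strand_track <- generate_tracks(ref, track_spec("strand", data.frame(
  chrom = "chr1", start = starts, end = starts + step,
  label = rep(c("+", "-"), length.out = length(starts)))))

sig1 <- signature1_definition()
sb <- strand_bias(panel, ref, strand_track, sig1, stratum = "f2")
write.table(sb, "results/strand_bias_sig1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Signature-1 strand bias: mean log-ratio %.3f (null expectation 0)\n",
            mean(sb$log_ratio, na.rm = TRUE)))

# methylation: label the first half of the genome 'high', the rest 'low'
meth_track <- generate_tracks(ref, track_spec("methylation", data.frame(
  chrom = "chr1", start = c(0, L / 2), end = c(L / 2, L),
  label = c("high", "low"))))
sites <- methylation_site_lists(ref, meth_track)
mr <- methylation_ratio(panel, ref, sites$high, sites$low,
                        signature2_definition(), stratum = "f2")
cat(sprintf("CpG mutation rate ratio high/low methylation: %.2f (%d vs %d mutations; null 1)\n",
            mr$ratio, mr$n_high, mr$n_low))
fis <- fisher_2x2(matrix(c(mr$n_high, mr$sites_high - mr$n_high,
                           mr$n_low, mr$sites_low - mr$n_low), 2))
cat("Fisher exact P for a rate difference:", signif(fis, 2), "\n")

# decile track from a smooth synthetic conservation-like score
set.seed(1)
score <- as.numeric(stats::filter(rnorm(L / 1000), rep(1, 5),
                                  circular = TRUE))
dec_track <- generate_tracks(ref, track_spec("decile", score = score,
                                             bin_size = 1000))
groups <- list(WESTERN = panel$samples$sample[panel$samples$population == "WESTERN"],
               AFRICAN = panel$samples$sample[panel$samples$population == "AFRICAN"])
st <- decile_stratify(panel, ref, dec_track, sig1, groups, stratum = "f2")
write.table(st$counts, "results/decile_stratification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
wide <- reshape(st$counts[, c("group", "decile", "proportion")],
                direction = "wide", idvar = "decile", timevar = "group")
cat("Max |per-decile signature-1 proportion difference| between groups:",
    round(max(abs(wide[[2]] - wide[[3]])), 4), "\n")
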