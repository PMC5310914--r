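#!/usr/bin/env Rscript
# Signature extraction from the doubleton intensity matrix: rank-selection
# diagnostics, the rank-2 NMF fit with ICA initialization, comparison with
# the shipped synthetic catalog, trinucleotide-frequency rescaling for
# plotting, the CpG-floor correction, and the PCA alternative.

library(mutspect)

ref <- read_reference_fasta("results/reference.fasta")
X <- normalize_spectrum(read_spectrum_tsv("results/spectrum_f2.tsv"), "ata_c")

diag <- rank_diagnostics(X, ranks = 2:4, n_starts = 10, seed = 1,
                         max_iter = 400)
write.table(diag, "results/rank_diagnostics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Rank diagnostics (dispersion / rss / silhouette):\n")
print(diag)

fit <- nmf_fit(X, rank = 2, init = "ica", seed = 1)
print(fit)
write_spectrum_tsv(fit$weights, "results/signatures.tsv")
write.table(data.frame(factor = rownames(fit$loadings), fit$loadings,
                       check.names = FALSE),
            "results/loadings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

catalog <- read_catalog(system.file("extdata",
                                    "synthetic_signature_catalog.tsv",
                                    package = "mutspect"))
for (k in seq_len(fit$rank)) {
  m <- compare_catalog(fit$weights[, k], catalog)
  cat(sprintf("Factor S%d best catalog match: %s (rho = %.2f)\n",
              k, m$name[1], m$rho[1]))
}

# genome-scaled weights for plotting (scale not directly interpretable)
scaled <- rescale_signature(fit$weights, ref$trinuc_freqs)
write_spectrum_tsv(scaled, "results/signatures_rescaled.tsv")

# CpG-floor corrected signatures
corrected <- subtract_cpg_floor(fit)
write_spectrum_tsv(corrected$weights, "results/signatures_cpg_corrected.tsv")

pca <- pca_spectrum(X)
write.table(data.frame(sample = rownames(pca$scores), pca$scores[, 1:4]),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("PCA variance explained (first 4 PCs):",
    round(pca$sdev[1:4]^2 / sum(pca$sdev^2), 3), "\n")
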