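# Shared builders for small synthetic fixtures. Everything is generated in
# code at test time; no stored data.

test_reference <- function(length = 20000, seed = 11, cpg_boost = 1) {
  generate_reference(genome_spec(length, cpg_boost = cpg_boost, seed = seed))
}

two_pop_panel <- function(ref, n_variants = 6000, mult = NULL, seed = 7,
                          n_samples = 10, ...) {
  pops <- list(
    population_spec("POPA", "regionA", n_samples, class_multipliers = mult),
    population_spec("POPB", "regionB", n_samples))
  generate_panel(ref, pops, n_variants, seed = seed, ...)
}

.h_comp <- function(x) chartr("ACGT", "TGCA", x)

# Variant rows of a given canonical class at admissible reference sites.
# orient restricts to sites where the pyrimidine representation sits on the
# given strand; offset skips the first sites (so two classes sharing a
# context never collide).
place_class_variants <- function(ref, class_label, n, orient = NULL,
                                 offset = 0) {
  ct <- mutation_class_table()
  row <- ct[ct$label == class_label, ]
  idx <- context_site_index(ref)
  sel <- idx[idx$context == row$context, ]
  if (!is.null(orient)) sel <- sel[sel$orient == orient, ]
  if (nrow(sel) < n + offset) stop("not enough admissible sites")
  sel <- sel[seq_len(n) + offset, ]
  anc <- ifelse(sel$orient == "+", row$ancestral, .h_comp(row$ancestral))
  der <- ifelse(sel$orient == "+", row$derived, .h_comp(row$derived))
  data.frame(chrom = "chr1", pos = sel$pos, ref = anc, alt = der, aa = anc,
             orient = sel$orient, stringsAsFactors = FALSE)
}

simple_samples <- function(n, population = "POPA") {
  data.frame(sample = paste0(population, "-", seq_len(n)),
             population = population, region = "regionA", source = "tissue",
             stringsAsFactors = FALSE)
}

# Signature matched to planted truth: greedy cosine matching of recovered
# columns to planted columns.
cosine_match <- function(recovered, planted) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- ncol(planted)
  sim <- outer(seq_len(ncol(recovered)), seq_len(k),
               Vectorize(function(i, j) cs(recovered[, i], planted[, j])))
  best <- numeric(k)
  taken <- integer(0)
  for (j in order(-apply(sim, 2, max))) {
    i <- setdiff(order(-sim[, j]), taken)[1]
    best[j] <- sim[i, j]
    taken <- c(taken, i)
  }
  best
}
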