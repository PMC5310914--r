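test_that("reference generation is deterministic and matches multinomial context expectations", {
  spec <- genome_spec(1e6, seed = 5)
  ref <- generate_reference(spec)
  ref2 <- generate_reference(spec)
  expect_identical(as.character(ref$sequence), as.character(ref2$sequence))
  expect_equal(sum(ref$trinuc_freqs), 1, tolerance = 1e-12)
  expect_length(ref$trinuc_freqs, 32)
  # uniform weights, no CpG boost: each canonical context at 1/32
  n_ctx <- 1e6 - 2
  se <- sqrt((1 / 32) * (1 - 1 / 32) / n_ctx)
  expect_true(all(abs(ref$trinuc_freqs - 1 / 32) < 3.5 * se))
})

test_that("cpg_boost = 0 removes every CG dinucleotide", {
  ref <- generate_reference(genome_spec(50000, cpg_boost = 0, seed = 2))
  expect_false(grepl("CG", as.character(ref$sequence[[1]])))
  # and CpG contexts are absent from the site index
  idx <- context_site_index(ref)
  expect_false(any(substr(idx$context, 2, 3) == "CG"))
})

test_that("spec validation rejects degenerate genomes", {
  expect_error(genome_spec(2), "length")
  expect_error(genome_spec(100, base_weights = c(A = 1, C = 1, G = 0, T = 0)),
               "sum to 1")
})

test_that("a single neutral population yields context-uniform class counts", {
  ref <- test_reference(300000, seed = 8)
  pop <- list(population_spec("P", "r", 20))
  panel <- generate_panel(ref, pop, 48000, seed = 3)
  cs <- count_spectrum(panel, ref, "f2")
  class_counts <- rowSums(cs$counts) / 2  # doubletons carry 2 copies
  idx <- context_site_index(ref)
  avail <- table(factor(idx$context, levels = canonical_contexts()))
  ct <- mutation_class_table()
  p0 <- as.numeric(avail[ct$context]) / 3
  p0 <- p0 / sum(p0)
  gof <- suppressWarnings(chisq.test(class_counts, p = p0))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted class multipliers are recovered from normalized intensities", {
  ref <- test_reference(200000, seed = 12)
  panel <- two_pop_panel(ref, n_variants = 40000,
                         mult = c("TCC>T" = 1.5), seed = 9, n_samples = 10)
  cs <- count_spectrum(panel, ref, "f2")
  a <- panel$samples$population == "POPA"
  tcc_a <- sum(cs$counts["TCC>T", a]); tcc_b <- sum(cs$counts["TCC>T", !a])
  ata_a <- sum(cs$counts["ATA>C", a]); ata_b <- sum(cs$counts["ATA>C", !a])
  ratio <- (tcc_a / ata_a) / (tcc_b / ata_b)
  se <- ratio * sqrt(1 / tcc_a + 1 / tcc_b + 1 / ata_a + 1 / ata_b)
  expect_lt(abs(ratio - 1.5), 3 * se)
})

test_that("empty panels propagate to empty spectra", {
  ref <- test_reference(5000, seed = 3)
  panel <- two_pop_panel(ref, n_variants = 0, n_samples = 3)
  expect_equal(ncol(panel$geno), 0)
  cs <- count_spectrum(panel, ref, "f2")
  expect_equal(sum(cs$counts), 0)
})

test_that("the doubleton homozygote rule follows hom_prob", {
  ref <- test_reference(50000, seed = 4)
  p_hom <- generate_panel(ref, list(population_spec("P", "r", 6)), 500,
                          seed = 2, hom_prob = 1)
  expect_true(all(colSums(p_hom$geno == 2L) == 1))
  expect_true(all(colSums(p_hom$geno) == 2L))
  p_het <- generate_panel(ref, list(population_spec("P", "r", 6)), 500,
                          seed = 2, hom_prob = 0)
  expect_true(all(colSums(p_het$geno == 1L) == 2))
  expect_true(all(p_het$geno <= 1L))
})

test_that("low-confidence (lowercase) ancestral alleles are excluded downstream", {
  ref <- test_reference(50000, seed = 6)
  panel <- generate_panel(ref, list(population_spec("P", "r", 5)), 400,
                          seed = 8, lowercase_aa_frac = 1)
  expect_true(all(panel$variants$aa == tolower(panel$variants$aa)))
  cs <- count_spectrum(panel, ref, "f2")
  expect_equal(sum(cs$counts), 0)
  expect_equal(as.numeric(cs$skipped["low_confidence_aa"]), 400)
})

test_that("panel generation and VCF writing are byte-deterministic under a seed", {
  ref <- test_reference(30000, seed = 10)
  p1 <- two_pop_panel(ref, n_variants = 800, seed = 42, n_samples = 4)
  p2 <- two_pop_panel(ref, n_variants = 800, seed = 42, n_samples = 4)
  expect_identical(p1$variants, p2$variants)
  expect_identical(p1$geno, p2$geno)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_panel_vcf(p1, f1); write_panel_vcf(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("panels survive a VCF round trip", {
  ref <- test_reference(30000, seed = 14)
  panel <- two_pop_panel(ref, n_variants = 600, seed = 5, n_samples = 4,
                         hom_prob = 0.3)
  vcf <- tempfile(fileext = ".vcf")
  meta <- tempfile(fileext = ".tsv")
  write_panel_vcf(panel, vcf)
  write_sample_metadata(panel$samples, meta)
  back <- read_panel_vcf(vcf, metadata = meta)
  expect_equal(back$variants$pos, panel$variants$pos)
  expect_equal(back$variants$aa, panel$variants$aa)
  expect_equal(unname(back$geno), unname(panel$geno))
  expect_equal(back$samples$population, panel$samples$population)
  cs1 <- count_spectrum(panel, ref, "f2")
  cs2 <- count_spectrum(back, ref, "f2")
  expect_equal(cs1$counts, cs2$counts)
})

test_that("coalescent frequencies under growth enrich panel singletons", {
  ref <- test_reference(120000, seed = 20)
  mk <- function(growth) {
    pop <- list(population_spec("P", "r", 8, growth = growth))
    panel <- generate_panel(ref, pop, 6000, freq_source = "coalescent",
                            seed = 33, sfs_trees = 300)
    mean(panel$truth$allele_count == 1)
  }
  f_const <- mk(NULL)
  f_growth <- mk(growth_model(100, 0.01))
  expect_gt(f_growth, f_const)
})

test_that("strand tracks merge contradictory overlaps to 'both'", {
  ref <- test_reference(5000, seed = 2)
  sp <- track_spec("strand", data.frame(
    chrom = "chr1", start = c(100, 300), end = c(500, 700),
    label = c("+", "-")))
  tr <- generate_tracks(ref, sp)
  lab_at <- function(pos) strand_classify(data.frame(chrom = "chr1",
                                                     pos = pos), tr)
  expect_equal(lab_at(150), "+")
  expect_equal(lab_at(400), "both")
  expect_equal(lab_at(600), "-")
  expect_equal(lab_at(900), "none")
})

test_that("an empty strand spec yields an empty track and strand_bias refuses it", {
  ref <- test_reference(20000, seed = 2)
  tr <- generate_tracks(ref, track_spec("strand"))
  expect_length(tr, 0)
  panel <- two_pop_panel(ref, n_variants = 200, seed = 1, n_samples = 3)
  expect_error(strand_bias(panel, ref, tr, signature1_definition()),
               "covers nothing")
})

test_that("decile tracks from a smooth score cover 10% of bins each", {
  ref <- test_reference(100000, seed = 7)
  set.seed(1)
  score <- as.numeric(stats::filter(rnorm(100), rep(1, 5), circular = TRUE))
  tr <- generate_tracks(ref, track_spec("decile", score = score,
                                        bin_size = 1000))
  tab <- table(tr$label)
  expect_length(tab, 10)
  expect_true(all(abs(as.numeric(tab) - 10) <= 1))
})

test_that("tracks survive a BED round trip", {
  ref <- test_reference(5000, seed = 2)
  sp <- track_spec("strand", data.frame(
    chrom = "chr1", start = c(0, 200, 1000), end = c(300, 600, 1500),
    label = c("+", "-", "+")))
  tr <- generate_tracks(ref, sp)
  bed <- tempfile(fileext = ".bed")
  write_track_bed(tr, bed)
  back <- read_track_bed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(tr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(tr))
  expect_equal(back$label, tr$label)
})

test_that("track specs validate labels and bounds", {
  ref <- test_reference(1000, seed = 2)
  expect_error(track_spec("strand", data.frame(chrom = "chr1", start = 0,
                                               end = 10, label = "x")),
               "invalid strand label")
  expect_error(track_spec("decile", data.frame(chrom = "chr1", start = 0,
                                               end = 10, label = "11")),
               "invalid decile label")
  sp <- track_spec("strand", data.frame(chrom = "chr1", start = 0,
                                        end = 5000, label = "+"))
  expect_error(generate_tracks(ref, sp), "beyond reference")
})

test_that("methylation site lists split CpG cytosines by track label", {
  ref <- test_reference(20000, seed = 9)
  half <- 10000
  tr <- generate_tracks(ref, track_spec("methylation", data.frame(
    chrom = "chr1", start = c(0, half), end = c(half, 20000),
    label = c("high", "low"))))
  sl <- methylation_site_lists(ref, tr)
  s <- as.character(ref$sequence[[1]])
  expect_true(all(substring(s, sl$high$pos, sl$high$pos + 1) == "CG"))
  expect_true(all(sl$high$pos <= half))
  expect_true(all(sl$low$pos > half))
})
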