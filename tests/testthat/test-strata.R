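strand_track_for <- function(ref, plus = c(0, 10000), minus = NULL) {
  iv <- data.frame(chrom = "chr1", start = plus[1], end = plus[2],
                   label = "+")
  if (!is.null(minus)) {
    iv <- rbind(iv, data.frame(chrom = "chr1", start = minus[1],
                               end = minus[2], label = "-"))
  }
  generate_tracks(ref, track_spec("strand", iv))
}

test_that("strand bias counts pyrimidine-on-coding-strand mutations as untranscribed", {
  ref <- test_reference(30000, seed = 25)
  track <- strand_track_for(ref, plus = c(0, 30000))
  # 8 TCC>T events with the pyrimidine on + (coding) = untranscribed,
  # 4 with the pyrimidine on - = transcribed
  v_un <- place_class_variants(ref, "TCC>T", 8, orient = "+")
  v_tx <- place_class_variants(ref, "TCC>T", 4, orient = "-")
  variants <- rbind(v_un[, 1:5], v_tx[, 1:5])
  samples <- simple_samples(2)
  geno <- matrix(0L, 2, 12)
  geno[1, ] <- 1L
  panel <- build_panel(variants, geno, samples)
  sb <- strand_bias(panel, ref, track, signature1_definition(),
                    stratum = "f1")
  expect_equal(sb$untranscribed[1], 8)
  expect_equal(sb$transcribed[1], 4)
  expect_equal(sb$log_ratio[1], log(2), tolerance = 1e-12)
  # equal counts give zero
  geno2 <- matrix(0L, 2, 12); geno2[1, c(1:4, 9:12)] <- 1L
  sb0 <- strand_bias(build_panel(variants, geno2, samples), ref, track,
                     signature1_definition(), stratum = "f1")
  expect_equal(sb0$log_ratio[1], 0)
})

test_that("inverting the strand track negates every log ratio exactly", {
  ref <- test_reference(60000, seed = 26)
  panel <- two_pop_panel(ref, n_variants = 4000, seed = 3, n_samples = 5)
  iv <- data.frame(chrom = "chr1",
                   start = seq(0, 50000, by = 10000),
                   end = seq(5000, 55000, by = 10000),
                   label = rep(c("+", "-"), 3))
  track <- generate_tracks(ref, track_spec("strand", iv))
  iv_flip <- iv
  iv_flip$label <- ifelse(iv$label == "+", "-", "+")
  track_flip <- generate_tracks(ref, track_spec("strand", iv_flip))
  sig <- signature_definition("all_ct", c("NCA>T", "NCC>T", "NCG>T", "NCT>T"))
  sb <- strand_bias(panel, ref, track, sig)
  sb_f <- strand_bias(panel, ref, track_flip, sig)
  expect_equal(sb_f$untranscribed, sb$transcribed)
  expect_equal(sb_f$log_ratio, -sb$log_ratio)
})

test_that("a planted 2:1 strand asymmetry is recovered as log 2", {
  ref <- test_reference(120000, seed = 27)
  track <- strand_track_for(ref, plus = c(0, 120000))
  set.seed(4)
  n <- 600
  untx <- runif(n) < 2 / 3
  v_u <- place_class_variants(ref, "TCC>T", sum(untx), orient = "+")
  v_t <- place_class_variants(ref, "TCC>T", sum(!untx), orient = "-")
  variants <- rbind(v_u[, 1:5], v_t[, 1:5])
  samples <- simple_samples(2)
  geno <- matrix(0L, 2, n); geno[1, ] <- 1L
  panel <- build_panel(variants, geno, samples)
  sb <- strand_bias(panel, ref, track, signature1_definition(),
                    stratum = "f1")
  se <- sqrt(1 / sb$untranscribed[1] + 1 / sb$transcribed[1])
  expect_lt(abs(sb$log_ratio[1] - log(2)), 3 * se)
})

test_that("the Haldane correction handles zero cells and both-zero samples are NA", {
  ref <- test_reference(30000, seed = 25)
  track <- strand_track_for(ref, plus = c(0, 30000))
  v <- place_class_variants(ref, "TCC>T", 3, orient = "+")
  samples <- simple_samples(2)
  geno <- matrix(0L, 2, 3); geno[1, ] <- 1L
  panel <- build_panel(v[, 1:5], geno, samples)
  sb <- strand_bias(panel, ref, track, signature1_definition(),
                    stratum = "f1")
  expect_true(sb$corrected[1])
  expect_equal(sb$log_ratio[1], log(3.5 / 0.5), tolerance = 1e-12)
  expect_true(is.na(sb$log_ratio[2]))
})

test_that("methylation rate ratio normalizes by site-list sizes", {
  ref <- test_reference(60000, seed = 28)
  sig2 <- signature2_definition()
  # plant CpG variants: 100 at 'high' sites out of 1000, 20 at 'low' of 2000
  idx <- context_site_index(ref)
  cpg_sites <- idx$pos[substr(idx$context, 2, 3) == "CG" & idx$orient == "+"]
  expect_gt(length(cpg_sites), 3000)
  high <- data.frame(chrom = "chr1", pos = cpg_sites[1:1000])
  low <- data.frame(chrom = "chr1", pos = cpg_sites[1001:3000])
  ct <- mutation_class_table()
  mk_var <- function(pos) {
    left <- substring(as.character(ref$sequence[[1]]), pos - 1, pos - 1)
    data.frame(chrom = "chr1", pos = pos, ref = "C", alt = "T", aa = "C",
               stringsAsFactors = FALSE)
  }
  variants <- mk_var(c(high$pos[1:100], low$pos[1:20]))
  samples <- simple_samples(2)
  geno <- matrix(0L, 2, 120); geno[1, ] <- 1L
  panel <- build_panel(variants, geno, samples)
  mr <- methylation_ratio(panel, ref, high, low, sig2)
  expect_equal(mr$ratio, (100 / 1000) / (20 / 2000))
  # equal rates give 1
  variants2 <- mk_var(c(high$pos[1:50], low$pos[1:100]))
  geno2 <- matrix(0L, 2, 150); geno2[1, ] <- 1L
  mr2 <- methylation_ratio(build_panel(variants2, geno2, samples), ref,
                           high, low, sig2)
  expect_equal(mr2$ratio, 1)
  expect_error(methylation_ratio(panel, ref, high, high, sig2), "disjoint")
  # zero low-site mutations flag an infinite ratio
  variants3 <- mk_var(high$pos[1:10])
  geno3 <- matrix(0L, 2, 10); geno3[1, ] <- 1L
  expect_warning(
    mr3 <- methylation_ratio(build_panel(variants3, geno3, samples), ref,
                             high, low, sig2), "infinite")
  expect_equal(mr3$ratio, Inf)
})

test_that("a planted 8.5x methylation rate ratio is recovered", {
  ref <- test_reference(120000, seed = 29)
  idx <- context_site_index(ref)
  cpg_sites <- idx$pos[substr(idx$context, 2, 3) == "CG" & idx$orient == "+"]
  high <- data.frame(chrom = "chr1", pos = cpg_sites[1:1500])
  low <- data.frame(chrom = "chr1", pos = cpg_sites[1501:6000])
  set.seed(6)
  # per-site mutation probability 8.5x higher at high sites
  hit_h <- high$pos[runif(1500) < 0.17]
  hit_l <- low$pos[runif(4500) < 0.02]
  pos <- c(hit_h, hit_l)
  variants <- data.frame(chrom = "chr1", pos = pos, ref = "C", alt = "T",
                         aa = "C", stringsAsFactors = FALSE)
  samples <- simple_samples(2)
  geno <- matrix(0L, 2, length(pos)); geno[1, ] <- 1L
  panel <- build_panel(variants, geno, samples)
  mr <- methylation_ratio(panel, ref, high, low, signature2_definition())
  se <- mr$ratio * sqrt(1 / mr$n_high + 1 / mr$n_low)
  expect_lt(abs(mr$ratio - 8.5), 3 * se)
})

test_that("the exact 2x2 test matches stats::fisher.test on random tables", {
  expect_equal(fisher_2x2(matrix(0, 2, 2)), 1)
  expect_equal(fisher_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_2x2(matrix(c(2, 3, 4, 6), 2)), 1)
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  set.seed(7)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, sample(1:10, 1)), 2)
    p_mine <- fisher_2x2(tab)
    p_ref <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      stats::fisher.test(tab)$p.value
    } else 1
    expect_equal(p_mine, p_ref, tolerance = 1e-12)
  }
})

test_that("decile stratification is uniform under uniform placement and group-equivariant", {
  ref <- test_reference(100000, seed = 30)
  set.seed(2)
  score <- as.numeric(stats::filter(rnorm(100), rep(1, 3), circular = TRUE))
  track <- generate_tracks(ref, track_spec("decile", score = score,
                                           bin_size = 1000))
  panel <- two_pop_panel(ref, n_variants = 8000, seed = 5, n_samples = 5)
  groups <- list(A = panel$samples$sample[panel$samples$population == "POPA"],
                 B = panel$samples$sample[panel$samples$population == "POPB"])
  st <- decile_stratify(panel, ref, track, signature2_definition(), groups)
  totals <- tapply(st$counts$total, st$counts$group, sum)
  for (g in names(groups)) {
    sub <- st$counts[st$counts$group == g, ]
    p_hat <- sub$total / totals[g]
    # doubleton copies land pairwise in the same decile: effective n is half
    se <- sqrt(0.1 * 0.9 / (totals[g] / 2))
    expect_true(all(abs(p_hat - 0.1) < 4 * se))
  }
  # permuting group labels permutes the output identically
  st_perm <- decile_stratify(panel, ref, track, signature2_definition(),
                             rev(groups))
  a1 <- st$counts[st$counts$group == "A", -1]
  a2 <- st_perm$counts[st_perm$counts$group == "A", -1]
  expect_equal(a1, a2, ignore_attr = TRUE)
})

test_that("decile proportions are null-calibrated when both groups share intensities", {
  ref <- test_reference(60000, seed = 31)
  set.seed(3)
  score <- as.numeric(stats::filter(rnorm(60), rep(1, 3), circular = TRUE))
  track <- generate_tracks(ref, track_spec("decile", score = score,
                                           bin_size = 1000))
  sig2 <- signature2_definition()
  n_cells <- 0; n_ok <- 0
  for (rep_i in 1:12) {
    panel <- two_pop_panel(ref, n_variants = 4000, seed = 100 + rep_i,
                           n_samples = 5)
    groups <- list(
      A = panel$samples$sample[panel$samples$population == "POPA"],
      B = panel$samples$sample[panel$samples$population == "POPB"])
    st <- decile_stratify(panel, ref, track, sig2, groups)
    a <- st$counts[st$counts$group == "A", ]
    b <- st$counts[st$counts$group == "B", ]
    pool <- (a$class_set + b$class_set) / pmax(a$total + b$total, 1)
    se <- sqrt(pool * (1 - pool) * (1 / pmax(a$total, 1) +
                                      1 / pmax(b$total, 1)))
    ok <- abs(a$proportion - b$proportion) <= 3 * pmax(se, 1e-9)
    use <- (a$total + b$total) > 0
    n_cells <- n_cells + sum(use)
    n_ok <- n_ok + sum(ok[use])
  }
  expect_gte(n_ok / n_cells, 0.95)
})

test_that("positions outside the reference are rejected in strand classification", {
  ref <- test_reference(1000, seed = 2)
  track <- strand_track_for(ref, plus = c(0, 1000))
  expect_error(strand_classify(data.frame(chrom = "chr1", pos = 2000),
                               track, reference = ref), "outside")
})
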