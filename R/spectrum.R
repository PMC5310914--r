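# Per-variant classification with the filtering rules applied.
# Returns a data.frame aligned with panel$variants: keep (logical), reason
# for exclusion, canonical class, the derived allele on the reference
# strand, whether ALT is the derived allele, and the orientation of the
# pyrimidine-centred representation.
.panel_variant_classes <- function(panel, reference) {
  stopifnot(inherits(panel, "mut_panel"))
  r <- .ref_seqstring(reference)
  v <- panel$variants
  n <- nrow(v)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    hit <- keep & cond
    reason[hit] <<- why
    keep[hit] <<- FALSE
  }
  aa_up <- toupper(v$aa)
  flag(nchar(v$ref) != 1 | nchar(v$alt) != 1 | grepl(",", v$alt),
       "multiallelic")
  flag(v$aa != aa_up, "low_confidence_aa")
  flag(!(aa_up %in% .BASES), "invalid_aa")
  flag(!(aa_up == v$ref | aa_up == v$alt), "triallelic_history")
  flag(v$pos < 2 | v$pos > r$length - 1, "edge")
  cls <- rep(NA_character_, n)
  derived <- rep(NA_character_, n)
  if (any(keep)) {
    i <- which(keep)
    left <- substring(r$seq, v$pos[i] - 1, v$pos[i] - 1)
    right <- substring(r$seq, v$pos[i] + 1, v$pos[i] + 1)
    bad_ctx <- !(left %in% .BASES) | !(right %in% .BASES)
    if (any(bad_ctx)) {
      reason[i[bad_ctx]] <- "ambiguous_context"
      keep[i[bad_ctx]] <- FALSE
      i <- i[!bad_ctx]; left <- left[!bad_ctx]; right <- right[!bad_ctx]
    }
    derived[i] <- ifelse(aa_up[i] == v$ref[i], v$alt[i], v$ref[i])
    cls[i] <- classify_variant(left, aa_up[i], right, derived[i])
  }
  data.frame(chrom = v$chrom, pos = v$pos, keep = keep, reason = reason,
             class = cls, derived = derived,
             derived_is_alt = aa_up == v$ref,
             orient = ifelse(aa_up %in% .PYRIMIDINES, "+", "-"),
             stringsAsFactors = FALSE)
}

# Derived-allele dosage matrix (samples x variants); ALT dosage flipped
# where the ancestral allele is ALT.
.derived_dosage <- function(panel, info) {
  dd <- panel$geno
  fl <- which(!info$derived_is_alt)
  if (length(fl) > 0) dd[, fl] <- 2L - dd[, fl, drop = FALSE]
  dd
}

# Logical selector over variants for an allele-count stratum.
# stratum: "f1", "f2", "f3", "per_genome", or c(lo, hi).
.stratum_select <- function(info, panel, stratum, dd = NULL) {
  if (is.null(dd)) dd <- .derived_dosage(panel, info)
  total <- colSums(dd)
  nh <- 2L * nrow(panel$samples)
  rng <- if (is.numeric(stratum)) {
    if (length(stratum) == 1) c(stratum, stratum) else stratum[1:2]
  } else if (identical(stratum, "per_genome")) {
    c(1L, nh - 1L)
  } else if (grepl("^f[0-9]+$", stratum)) {
    k <- as.integer(sub("^f", "", stratum))
    c(k, k)
  } else {
    stop("unknown stratum: ", stratum)
  }
  info$keep & total >= rng[1] & total <= rng[2]
}

#' Count the 96-class mutation spectrum per sample
#'
#' Classifies each panel variant into its canonical trinucleotide class
#' (context from the reference flanks, middle base = ancestral allele) and
#' tallies derived-allele copies per sample: two for a homozygous derived
#' genotype, one for a heterozygote. Only variants whose total derived count
#' over all samples (population labels ignored) falls in the requested
#' stratum are tallied. Records that are multi-allelic, lack a confident
#' (uppercase) ancestral annotation, have an ancestral allele matching
#' neither REF nor ALT (triallelic history), or sit at a sequence edge are
#' skipped; the skip tally is attached to the result.
#'
#' @param panel a [build_panel()] object (e.g. from [generate_panel()] or
#'   [read_panel_vcf()]).
#' @param reference the reference sequence supplying flanking context.
#' @param stratum `"f1"`, `"f2"`, `"f3"`, `"per_genome"` (all segregating
#'   frequencies), or a numeric allele-count range `c(lo, hi)`.
#' @return object of class `spectrum_counts`: list with `counts` (96 x
#'   n_samples integer matrix, rows in [enumerate_classes()] order),
#'   `stratum`, `samples` (metadata) and `skipped` (named skip counts).
#' @export
count_spectrum <- function(panel, reference, stratum = "f2") {
  info <- .panel_variant_classes(panel, reference)
  dd <- .derived_dosage(panel, info)
  sel <- .stratum_select(info, panel, stratum, dd = dd)
  labs <- enumerate_classes()
  counts <- matrix(0L, nrow = 96, ncol = nrow(panel$samples),
                   dimnames = list(labs, panel$samples$sample))
  if (any(sel)) {
    cls <- factor(info$class[sel], levels = labs)
    agg <- rowsum(t(dd[, sel, drop = FALSE]), cls)
    counts[rownames(agg), ] <- agg
  }
  skipped <- table(info$reason[!info$keep])
  structure(list(counts = counts, stratum = stratum,
                 samples = panel$samples,
                 skipped = skipped),
            class = "spectrum_counts")
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat("spectrum_counts: 96 x", ncol(x$counts), "samples, stratum",
      paste(x$stratum, collapse = "-"), "; total mutations",
      sum(x$counts), "\n")
  invisible(x)
}

#' Normalize a count spectrum into intensities
#'
#' Under `"ata_c"` each sample's counts are divided by its ATA>C count (the
#' most common class and a stable baseline), so the ATA>C row is identically
#' 1. Under `"total"` each column is divided by its total, so columns sum
#' to 1.
#'
#' @param counts a [count_spectrum()] result (or 96 x n matrix).
#' @param mode `"ata_c"` or `"total"`.
#' @return object of class `intensity_matrix`: list with `values` (96 x n),
#'   `normalization`.
#' @export
normalize_spectrum <- function(counts, mode = c("ata_c", "total")) {
  mode <- match.arg(mode)
  m <- if (inherits(counts, "spectrum_counts")) counts$counts else counts
  denom <- if (mode == "ata_c") m["ATA>C", ] else colSums(m)
  zero <- denom == 0
  if (any(zero)) {
    stop("zero ", if (mode == "ata_c") "ATA>C count" else "total count",
         " for sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  }
  structure(list(values = sweep(m, 2, denom, "/"), normalization = mode),
            class = "intensity_matrix")
}

#' Per-sample proportion of mutations in a signature
#'
#' @param counts a [count_spectrum()] result.
#' @param sig a [signature_definition()].
#' @return named numeric vector of proportions in `[0, 1]`; samples with no
#'   mutations get NA with a warning.
#' @export
signature_proportion <- function(counts, sig) {
  stopifnot(inherits(sig, "signature_definition"))
  m <- if (inherits(counts, "spectrum_counts")) counts$counts else counts
  tot <- colSums(m)
  p <- colSums(m[sig$classes, , drop = FALSE]) / tot
  if (any(tot == 0)) {
    warning("sample(s) with zero total mutations flagged NA: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
    p[tot == 0] <- NA_real_
  }
  p
}

#' Two-sample Z statistic on per-individual proportions
#'
#' `Z = (mean_a - mean_b) / sqrt(var_a/n_a + var_b/n_b)` with unpooled
#' (Welch-style) variances.
#'
#' @param proportions named numeric vector of per-sample values.
#' @param group_a,group_b sample names (each of size >= 2).
#' @return the Z statistic.
#' @export
group_z <- function(proportions, group_a, group_b) {
  miss <- setdiff(c(group_a, group_b), names(proportions))
  if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  a <- proportions[group_a]
  b <- proportions[group_b]
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 samples")
  if (anyNA(a) || anyNA(b)) stop("missing proportions in groups")
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(0)
    stop("zero variance in both groups with unequal means: Z undefined")
  }
  (mean(a) - mean(b)) / sqrt(se2)
}

#' Cross-split sharing proportions of stratum variants
#'
#' For variants in the given allele-count stratum, computes the fraction
#' carrying at least one derived copy on each side of a sample split, both
#' for the signature's classes (`p_sig`) and for all classes (`p_all`). An
#' elevated `p_sig` relative to `p_all` indicates recurrent mutation in the
#' signature classes, since a single mutation of count 2 rarely straddles a
#' deep population split.
#'
#' @param panel a variant panel.
#' @param reference reference sequence for classification.
#' @param split list with elements `a` and `b`: sample name vectors
#'   partitioning the panel samples.
#' @param sig a [signature_definition()].
#' @param stratum allele-count stratum (default `"f2"`).
#' @return list with `p_sig`, `p_all`, `n_sig`, `n_all`.
#' @export
sharing_proportion <- function(panel, reference, split, sig, stratum = "f2") {
  stopifnot(inherits(sig, "signature_definition"))
  all_s <- panel$samples$sample
  if (length(split$a) == 0 || length(split$b) == 0) {
    stop("both sides of the split must be non-empty")
  }
  if (!setequal(c(split$a, split$b), all_s) ||
      length(intersect(split$a, split$b)) > 0) {
    stop("split must partition the panel samples")
  }
  info <- .panel_variant_classes(panel, reference)
  dd <- .derived_dosage(panel, info)
  sel <- which(.stratum_select(info, panel, stratum, dd = dd))
  if (length(sel) == 0) return(list(p_sig = NA_real_, p_all = NA_real_,
                                    n_sig = 0L, n_all = 0L))
  ia <- match(split$a, all_s)
  ib <- match(split$b, all_s)
  on_a <- colSums(dd[ia, sel, drop = FALSE]) > 0
  on_b <- colSums(dd[ib, sel, drop = FALSE]) > 0
  shared <- on_a & on_b
  in_sig <- info$class[sel] %in% sig$classes
  list(p_sig = if (any(in_sig)) mean(shared[in_sig]) else NA_real_,
       p_all = mean(shared),
       n_sig = sum(in_sig), n_all = length(sel))
}
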