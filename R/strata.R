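#' Classify positions by transcriptional strand
#'
#' Labels each position by the union-of-transcripts rule: `"+"` or `"-"`
#' when covered by transcripts on that strand only, `"both"` when covered on
#' both strands, `"none"` when intergenic.
#'
#' @param positions data.frame with `chrom`, `pos` (1-based) or a `GRanges`.
#' @param strand_track labelled strand `GRanges` from [generate_tracks()].
#' @param reference optional reference for bounds checking.
#' @return character vector of labels.
#' @export
strand_classify <- function(positions, strand_track, reference = NULL) {
  gr <- if (inherits(positions, "GRanges")) positions
  else GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos, width = 1))
  if (!is.null(reference)) {
    r <- .ref_seqstring(reference)
    p <- GenomicRanges::start(gr)
    if (any(p < 1 | p > r$length)) stop("position outside the reference")
  }
  lab <- rep("none", length(gr))
  hits <- GenomicRanges::findOverlaps(gr, strand_track)
  if (length(hits) > 0) {
    got <- tapply(strand_track$label[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), function(ls) {
      u <- unique(ls)
      if ("both" %in% u || all(c("+", "-") %in% u)) "both" else u[1]
    })
    lab[as.integer(names(got))] <- as.character(got)
  }
  lab
}

#' Transcriptional strand bias of a mutation class set
#'
#' For each sample, counts stratum mutations of the given (pyrimidine-
#' centred) classes on the untranscribed versus the transcribed strand and
#' returns the log ratio. Mutations are NOT collapsed with their reverse
#' complements here: a C>T change whose pyrimidine lies on the `+` strand,
#' falling in a region transcribed on the `+` strand, is an
#' untranscribed-strand C>T (the `+` strand is then the coding strand);
#' with the pyrimidine on the `-` strand it counts as transcribed. Regions
#' transcribed on both or neither strand are ignored.
#'
#' When either count is zero the Haldane correction adds `pseudocount`
#' (default 0.5) to both before taking the log; this is recorded in the
#' output.
#'
#' @param panel a variant panel.
#' @param reference reference sequence.
#' @param strand_track labelled strand `GRanges`.
#' @param class_set a [signature_definition()].
#' @param stratum allele-count stratum (default `"f2"`).
#' @param log_base base of the logarithm (default natural log).
#' @param pseudocount Haldane correction value (default 0.5).
#' @return object of class `strand_bias`: data.frame with `sample`,
#'   `untranscribed`, `transcribed`, `log_ratio`, `corrected` (logical).
#' @export
strand_bias <- function(panel, reference, strand_track, class_set,
                        stratum = "f2", log_base = exp(1),
                        pseudocount = 0.5) {
  stopifnot(inherits(class_set, "signature_definition"))
  if (length(strand_track) == 0) stop("strand track covers nothing")
  info <- .panel_variant_classes(panel, reference)
  dd <- .derived_dosage(panel, info)
  sel <- which(.stratum_select(info, panel, stratum, dd = dd) &
                 info$class %in% class_set$classes)
  if (length(sel) == 0) stop("no stratum mutations in the class set")
  tau <- strand_classify(data.frame(chrom = info$chrom[sel],
                                    pos = info$pos[sel]),
                         strand_track, reference)
  usable <- tau %in% c("+", "-")
  sel <- sel[usable]
  tau <- tau[usable]
  if (length(sel) == 0) stop("no class-set mutations in singly transcribed regions")
  untx <- info$orient[sel] == tau  # pyrimidine on the coding strand
  m <- dd[, sel, drop = FALSE]
  cu <- as.numeric(m %*% untx)
  ct <- as.numeric(m %*% (!untx))
  corrected <- (cu == 0 | ct == 0)
  cu2 <- ifelse(corrected, cu + pseudocount, cu)
  ct2 <- ifelse(corrected, ct + pseudocount, ct)
  lr <- ifelse(cu == 0 & ct == 0, NA_real_, log(cu2 / ct2, base = log_base))
  out <- data.frame(sample = panel$samples$sample, untranscribed = cu,
                    transcribed = ct, log_ratio = lr, corrected = corrected,
                    stringsAsFactors = FALSE)
  class(out) <- c("strand_bias", "data.frame")
  out
}

#' Mutation rate ratio between high- and low-methylation sites
#'
#' `ratio = (mutations at high sites / number of high sites) /
#'          (mutations at low sites / number of low sites)` —
#' a per-site rate ratio, since the two site lists differ in size.
#'
#' @param panel a variant panel.
#' @param reference reference sequence.
#' @param high_sites,low_sites disjoint data.frames (`chrom`, `pos`) of
#'   sites with high (>= 50%) and low methylation.
#' @param class_set a [signature_definition()] restricting the counted
#'   classes.
#' @param stratum optional allele-count stratum (default all segregating).
#' @return list with `ratio`, `n_high`, `n_low`, `sites_high`, `sites_low`;
#'   `ratio` is `Inf` (with a warning) when no low-site mutations exist.
#' @export
methylation_ratio <- function(panel, reference, high_sites, low_sites,
                              class_set, stratum = "per_genome") {
  stopifnot(inherits(class_set, "signature_definition"))
  key_h <- paste(high_sites$chrom, high_sites$pos)
  key_l <- paste(low_sites$chrom, low_sites$pos)
  if (length(intersect(key_h, key_l)) > 0) {
    stop("high and low site lists must be disjoint")
  }
  info <- .panel_variant_classes(panel, reference)
  sel <- .stratum_select(info, panel, stratum) &
    info$class %in% class_set$classes
  key_v <- paste(info$chrom, info$pos)[sel]
  n_high <- sum(key_v %in% key_h)
  n_low <- sum(key_v %in% key_l)
  if (n_low == 0) {
    warning("no mutations at low-methylation sites: infinite ratio")
    ratio <- Inf
  } else {
    ratio <- (n_high / length(key_h)) / (n_low / length(key_l))
  }
  list(ratio = ratio, n_high = n_high, n_low = n_low,
       sites_high = length(key_h), sites_low = length(key_l))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Exact two-sided p-value computed by summing, over the hypergeometric
#' support fixed by the margins, the probabilities of all tables no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return the two-sided p-value (1 for degenerate margins).
#' @export
fisher_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  m <- sum(tab[1, ])            # row-1 total
  n <- sum(tab[2, ])            # row-2 total
  k <- sum(tab[, 1])            # column-1 total
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Stratify class-set mutations by track deciles
#'
#' Assigns each stratum variant its decile label (0-9) from a decile track
#' (e.g. B statistic or recombination rate in 1kb bins) and, per sample
#' group, tabulates class-set mutations and all mutations in each decile,
#' with the per-decile proportion of class-set mutations. Uncovered variants
#' are skipped (tallied in the output).
#'
#' @param panel a variant panel.
#' @param reference reference sequence.
#' @param decile_track labelled decile `GRanges`.
#' @param class_set a [signature_definition()].
#' @param groups named list of sample-name vectors.
#' @param stratum allele-count stratum (default `"f2"`).
#' @return object of class `stratified_counts`: list with `counts`
#'   (data.frame: group, decile, class_set, total, proportion) and
#'   `n_uncovered`.
#' @export
decile_stratify <- function(panel, reference, decile_track, class_set,
                            groups, stratum = "f2") {
  stopifnot(inherits(class_set, "signature_definition"))
  if (!all(decile_track$label %in% as.character(0:9))) {
    stop("malformed decile label(s) in track")
  }
  info <- .panel_variant_classes(panel, reference)
  dd <- .derived_dosage(panel, info)
  sel <- which(.stratum_select(info, panel, stratum, dd = dd))
  gr <- GenomicRanges::GRanges(info$chrom[sel],
                               IRanges::IRanges(info$pos[sel], width = 1))
  hits <- GenomicRanges::findOverlaps(gr, decile_track, select = "first")
  covered <- !is.na(hits)
  n_uncovered <- sum(!covered)
  if (n_uncovered > 0) {
    message(n_uncovered, " variant(s) not covered by the decile track, skipped")
  }
  sel <- sel[covered]
  dec <- factor(decile_track$label[hits[covered]], levels = as.character(0:9))
  in_set <- info$class[sel] %in% class_set$classes
  rows <- list()
  for (g in names(groups)) {
    ig <- match(groups[[g]], panel$samples$sample)
    if (anyNA(ig)) stop("unknown sample(s) in group ", g)
    w <- colSums(dd[ig, sel, drop = FALSE])
    tot <- tapply(w, dec, sum, default = 0)
    cs <- tapply(w * in_set, dec, sum, default = 0)
    rows[[g]] <- data.frame(group = g, decile = as.integer(names(tot)),
                            class_set = as.numeric(cs),
                            total = as.numeric(tot),
                            proportion = ifelse(tot > 0, cs / tot, 0),
                            stringsAsFactors = FALSE)
  }
  structure(list(counts = do.call(rbind, rows), n_uncovered = n_uncovered),
            class = "stratified_counts")
}
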