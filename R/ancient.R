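# Classes entering the damage-corrected signature-1 log-ratio. All eight are
# C>T substitutions: each signature-1 context XC{C,T} in the numerator is
# paired with the control context XCA in the denominator, and TCA>T enters
# twice to balance the four-vs-four pairing. Because numerator and
# denominator each contain four C>T classes, a uniform excess of C>T calls
# (ancient-DNA cytosine deamination) cancels exactly.
.M_NUMERATOR <- c("TCC>T", "ACC>T", "TCT>T", "CCC>T")
.M_DENOMINATOR <- c("TCA>T", "ACA>T", "TCA>T", "CCA>T")

#' Damage-robust corrected signature-1 log-ratio M
#'
#' Computes `M = log2[(X_TCC X_ACC X_TCT X_CCC) / (X_TCA X_ACA X_TCA X_CCA)]`
#' over the C>T classes of one sample, where X are class counts or
#' intensities (any per-sample normalization cancels in the ratio). The
#' statistic is insensitive to a uniform multiplicative excess of C>T
#' mutations such as that produced by post-mortem cytosine deamination,
#' because four C>T classes appear in the numerator and four in the
#' denominator.
#'
#' @param x named numeric vector of class counts or intensities for one
#'   sample (names are canonical class labels; at least the eight classes
#'   used by the statistic must be present).
#' @param pseudocount value added to all eight class counts when any of them
#'   is zero (default 0.5); set to NA to raise an error instead.
#' @return the raw M value. Attribute `pseudocount_applied` records whether
#'   the correction was used.
#' @export
#' @examples
#' x <- setNames(rep(5, 96), enumerate_classes())
#' m_statistic(x)  # 0
m_statistic <- function(x, pseudocount = 0.5) {
  need <- unique(c(.M_NUMERATOR, .M_DENOMINATOR))
  if (is.null(names(x)) || !all(need %in% names(x))) {
    stop("x must be named by class label and include: ",
         paste(need, collapse = ", "))
  }
  v <- x[need]
  applied <- FALSE
  if (any(v == 0)) {
    if (is.na(pseudocount)) stop("zero intensity in M-statistic class(es): ",
                                 paste(need[v == 0], collapse = ", "))
    v <- v + pseudocount
    applied <- TRUE
  }
  num <- prod(v[.M_NUMERATOR])
  den <- prod(v[.M_DENOMINATOR])
  structure(log2(num / den), pseudocount_applied = applied)
}

#' Normalize M statistics against a reference panel
#'
#' Standardizes per-sample raw M values so that the reference panel (in the
#' source analysis, the African samples) has mean 0 and standard deviation 1.
#'
#' @param raw named numeric vector of raw M values, one per sample.
#' @param reference_samples names of the reference-panel samples (at least 2).
#' @return data.frame with `sample`, `raw`, `normalized`; attributes
#'   `reference_mean` and `reference_sd`.
#' @export
normalize_m <- function(raw, reference_samples) {
  if (is.null(names(raw))) stop("raw must be a named vector")
  missing_ref <- setdiff(reference_samples, names(raw))
  if (length(missing_ref) > 0) {
    stop("reference samples not found: ", paste(missing_ref, collapse = ", "))
  }
  if (length(reference_samples) < 2) stop("reference panel needs >= 2 samples")
  ref <- raw[reference_samples]
  mu <- mean(ref)
  sdev <- stats::sd(ref)
  if (sdev == 0) stop("reference panel has zero standard deviation")
  out <- data.frame(sample = names(raw), raw = as.numeric(raw),
                    normalized = (as.numeric(raw) - mu) / sdev,
                    stringsAsFactors = FALSE)
  attr(out, "reference_mean") <- mu
  attr(out, "reference_sd") <- sdev
  out
}

#' Bootstrap quantiles for the M statistic of one sample
#'
#' Resamples the sample's class counts (multinomially, preserving the total,
#' or as independent Poissons), recomputes M for each replicate, optionally
#' normalizes with supplied reference moments, and returns the empirical 5%
#' and 95% quantiles.
#'
#' @param counts named non-negative integer vector of class counts for one
#'   sample.
#' @param n_boot number of bootstrap replicates (at least 100).
#' @param seed optional integer seed.
#' @param reference_mean,reference_sd optional reference moments; when given,
#'   replicate M values are normalized before taking quantiles.
#' @param method `"multinomial"` (default; totals preserved) or `"poisson"`.
#' @param pseudocount passed to [m_statistic()] per replicate.
#' @return list with `q05`, `q95`, `point` (M of the observed counts, on the
#'   same scale), `n_pseudocount` (replicates needing the zero-count
#'   correction) and `replicates` (the replicate M values).
#' @export
bootstrap_m <- function(counts, n_boot = 1000, seed = NULL,
                        reference_mean = 0, reference_sd = 1,
                        method = c("multinomial", "poisson"),
                        pseudocount = 0.5) {
  method <- match.arg(method)
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  total <- sum(counts)
  if (total == 0) stop("sample has no mutations")
  reps <- numeric(n_boot)
  n_pc <- 0L
  for (b in seq_len(n_boot)) {
    cb <- if (method == "multinomial") {
      as.numeric(stats::rmultinom(1, total, counts / total))
    } else {
      stats::rpois(length(counts), counts)
    }
    names(cb) <- names(counts)
    m <- m_statistic(cb, pseudocount = pseudocount)
    if (isTRUE(attr(m, "pseudocount_applied"))) n_pc <- n_pc + 1L
    reps[b] <- (as.numeric(m) - reference_mean) / reference_sd
  }
  point <- (as.numeric(m_statistic(counts, pseudocount = pseudocount)) -
              reference_mean) / reference_sd
  q <- stats::quantile(reps, c(0.05, 0.95), names = FALSE)
  list(q05 = q[1], q95 = q[2], point = point, n_pseudocount = n_pc,
       replicates = reps)
}

#' Build class counts for an ancient sample from singleton-overlap sites
#'
#' Restricts a list of heterozygous sites observed in an ancient genome to
#' positions that are singletons (a single derived copy over all samples) in
#' a modern reference panel, and tallies those sites into the 96 canonical
#' classes using the panel's polarization and the reference context. This is
#' the site ascertainment used before scoring ancient genomes with
#' [m_statistic()].
#'
#' @param ancient_sites data.frame with columns `chrom` and `pos` of
#'   heterozygous sites in the ancient genome.
#' @param panel a variant panel (see [generate_panel()] / [read_panel_vcf()]).
#' @param reference reference sequence (`DNAStringSet` or the result of
#'   [generate_reference()]).
#' @param stratum panel allele-count stratum defining usable sites
#'   (default `"f1"`, i.e. panel singletons).
#' @return named numeric vector of 96 class counts.
#' @export
ancient_site_filter <- function(ancient_sites, panel, reference,
                                stratum = "f1") {
  info <- .panel_variant_classes(panel, reference)
  sel <- .stratum_select(info, panel, stratum)
  key_panel <- paste(info$chrom[sel], info$pos[sel])
  key_anc <- paste(ancient_sites$chrom, ancient_sites$pos)
  hit <- match(key_anc, key_panel)
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) {
    stop("no ancient heterozygous sites coincide with panel ", stratum,
         " sites")
  }
  cls <- info$class[sel][hit]
  counts <- setNames(numeric(96), enumerate_classes())
  tab <- table(cls)
  counts[names(tab)] <- as.numeric(tab)
  counts
}
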