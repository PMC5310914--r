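#' Specification for a synthetic reference sequence
#'
#' The synthetic reference stands in for a real genome as the source of
#' trinucleotide context: a random sequence with controllable base
#' composition and CpG dinucleotide enrichment (real genomes are CpG-depleted
#' except in islands; `cpg_boost` lets tests enrich or remove CG
#' dinucleotides entirely).
#'
#' @param length sequence length in bp (>= 3).
#' @param base_weights named non-negative weights for A, C, G, T summing to 1.
#' @param cpg_boost non-negative multiplier applied to the frequency of G
#'   following C (1 = independent bases; 0 = no CG dinucleotides at all).
#' @param seed integer seed.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(length, base_weights = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                        cpg_boost = 1, seed = 1) {
  if (length < 3) stop("length must be >= 3")
  if (is.null(names(base_weights))) names(base_weights) <- .BASES
  base_weights <- base_weights[.BASES]
  if (any(is.na(base_weights)) || any(base_weights < 0)) {
    stop("base_weights must be non-negative and named A, C, G, T")
  }
  if (abs(sum(base_weights) - 1) > 1e-9) stop("base_weights must sum to 1")
  if (cpg_boost < 0) stop("cpg_boost must be non-negative")
  structure(list(length = as.integer(length), base_weights = base_weights,
                 cpg_boost = cpg_boost, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic reference sequence with its context frequencies
#'
#' Draws a random sequence from the base weights; when `cpg_boost != 1` the
#' sequence is a first-order Markov chain in which the probability of G
#' following C is multiplied by `cpg_boost` (then renormalized), so CpG
#' content can be enriched or suppressed. Deterministic under the spec's
#' seed.
#'
#' @param spec a [genome_spec()].
#' @return object of class `synthetic_reference`: list with `sequence`
#'   (a `DNAStringSet` named "chr1"), `trinuc_freqs` (named frequencies of
#'   the 32 canonical trinucleotide contexts, summing to 1) and `spec`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  L <- spec$length
  w <- spec$base_weights
  if (spec$cpg_boost == 1) {
    bases <- sample(.BASES, L, replace = TRUE, prob = w)
  } else {
    # transition rows: same as w except after C, where the G weight is boosted
    trans <- matrix(rep(w, 4), nrow = 4, byrow = TRUE,
                    dimnames = list(.BASES, .BASES))
    trans["C", "G"] <- trans["C", "G"] * spec$cpg_boost
    trans <- trans / rowSums(trans)
    cum <- t(apply(trans, 1, cumsum))
    u <- stats::runif(L)
    b <- integer(L)
    b[1] <- sample.int(4, 1, prob = w)
    for (i in 2:L) {
      b[i] <- findInterval(u[i], cum[b[i - 1], ], left.open = TRUE) + 1L
    }
    bases <- .BASES[b]
  }
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- "chr1"
  structure(list(sequence = seq,
                 trinuc_freqs = .canonical_trinuc_freqs(seq[[1]]),
                 spec = spec),
            class = "synthetic_reference")
}

.canonical_trinuc_freqs <- function(dna) {
  raw <- Biostrings::trinucleotideFrequency(dna)
  canon <- canonical_context(names(raw))$context
  out <- setNames(numeric(32), canonical_contexts())
  agg <- tapply(as.numeric(raw), canon, sum)
  out[names(agg)] <- agg
  out / sum(out)
}

# Accepts a synthetic_reference, a DNAStringSet, or a plain string and
# returns list(seq = character string, chrom = name, length).
.ref_seqstring <- function(reference) {
  if (inherits(reference, "synthetic_reference")) {
    s <- as.character(reference$sequence[[1]])
    chrom <- names(reference$sequence)[1]
  } else if (inherits(reference, "DNAStringSet")) {
    s <- as.character(reference[[1]])
    chrom <- if (!is.null(names(reference))) names(reference)[1] else "chr1"
  } else if (is.character(reference) && length(reference) == 1) {
    s <- toupper(reference)
    chrom <- "chr1"
  } else {
    stop("unsupported reference type")
  }
  list(seq = s, chrom = chrom, length = nchar(s))
}

#' Index admissible variant sites by canonical context
#'
#' Lists every internal position of the reference with its canonical
#' trinucleotide context and the orientation of the pyrimidine-centred
#' representation (`"+"` when the middle base is C/T on the reference
#' strand, `"-"` when the canonical context is the reverse complement).
#'
#' @param reference reference sequence (see [generate_reference()]).
#' @return data.frame with columns `pos`, `context`, `orient`.
#' @export
context_site_index <- function(reference) {
  r <- .ref_seqstring(reference)
  if (r$length < 3) stop("reference shorter than 3 bp")
  pos <- 2:(r$length - 1)
  tri <- substring(r$seq, pos - 1, pos + 1)
  ok <- !grepl("[^ACGT]", tri)
  pos <- pos[ok]; tri <- tri[ok]
  cc <- canonical_context(tri)
  data.frame(pos = pos, context = cc$context,
             orient = ifelse(cc$flipped, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Specification of one synthetic population
#'
#' Planted per-class mutation intensity multipliers let tests and the
#' end-to-end analysis bury known spectrum differences in a panel: a
#' population with `class_multipliers["TCC>T"] = 1.5` produces TCC>T
#' mutations at 1.5 times the relative intensity of a baseline population.
#'
#' @param name population label.
#' @param region geographic region label.
#' @param n_samples number of diploid samples (>= 1).
#' @param class_multipliers named positive multipliers over canonical class
#'   labels; unnamed classes default to 1.
#' @param growth optional [growth_model()] used when panel allele frequencies
#'   are drawn from the coalescent.
#' @param source `"tissue"` or `"cell_line"`.
#' @param latitude,longitude optional coordinates for the metadata table.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(name, region, n_samples, class_multipliers = NULL,
                            growth = NULL, source = c("tissue", "cell_line"),
                            latitude = NA_real_, longitude = NA_real_) {
  source <- match.arg(source)
  if (n_samples < 1) stop("n_samples must be >= 1")
  mult <- setNames(rep(1, 96), enumerate_classes())
  if (!is.null(class_multipliers)) {
    bad <- setdiff(names(class_multipliers), names(mult))
    if (length(bad) > 0) stop("unknown class(es): ", paste(bad, collapse = ", "))
    if (any(class_multipliers <= 0)) stop("multipliers must be positive")
    mult[names(class_multipliers)] <- class_multipliers
  }
  if (!is.null(growth)) stopifnot(inherits(growth, "growth_model"))
  structure(list(name = name, region = region,
                 n_samples = as.integer(n_samples),
                 class_multipliers = mult, growth = growth, source = source,
                 latitude = latitude, longitude = longitude),
            class = "population_spec")
}

#' Assemble a variant panel from its parts
#'
#' Low-level constructor used by [generate_panel()] and by tests that plant
#' variants at hand-picked sites.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `aa` (ancestral allele; lowercase = not confidently assigned).
#' @param geno integer matrix of ALT-allele dosages, samples x variants.
#' @param samples data.frame with at least columns `sample`, `population`,
#'   `region`, `source` (and optionally `latitude`, `longitude`).
#' @param truth optional list recording planted ground truth.
#' @return object of class `mut_panel`.
#' @export
build_panel <- function(variants, geno, samples, truth = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "aa")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns: ", paste(need, collapse = ", "))
  }
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(variants)) {
    stop("geno must be n_samples x n_variants")
  }
  if (!all(geno %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
  need_s <- c("sample", "population", "region", "source")
  if (!all(need_s %in% names(samples))) {
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  }
  rownames(geno) <- samples$sample
  structure(list(variants = variants, geno = geno, samples = samples,
                 truth = truth),
            class = "mut_panel")
}

#' @export
print.mut_panel <- function(x, ...) {
  cat("mut_panel:", nrow(x$variants), "variants x", nrow(x$samples),
      "samples (", paste(unique(x$samples$population), collapse = ", "), ")\n")
  invisible(x)
}

#' Generate a multi-population variant panel with planted spectrum structure
#'
#' Emulates a jointly genotyped panel of diploid samples from several
#' populations. Each variant originates in one population (chosen with
#' probability proportional to sample size), draws its mutation class from
#' the reference's context availability times that population's planted
#' class multipliers, lands on a uniformly chosen unused site whose reference
#' context admits the class, and receives a derived allele count either fixed
#' at `f_fixed` or drawn from a coalescent frequency spectrum simulated for
#' the origin population (respecting its growth model). Derived copies are
#' assigned to haplotypes of the origin population, so rare variants are
#' population-private, as real rare variants overwhelmingly are.
#'
#' Doubletons at `f_fixed = 2` follow the configurable homozygote rule: with
#' probability `hom_prob` one sample is homozygous derived, otherwise two
#' distinct samples are heterozygous. A fraction `cpg_repeat_frac` of CpG
#' (NCG>T) doubletons are instead modelled as repeat mutations: two
#' independent carriers drawn from the whole panel regardless of population,
#' which lets them cross any population split.
#'
#' The ancestral allele equals the reference base and is emitted uppercase
#' (confident) except for a `lowercase_aa_frac` fraction emitted lowercase to
#' exercise the confidence filter.
#'
#' @param reference a [generate_reference()] result (or `DNAStringSet`).
#' @param populations list of [population_spec()]s.
#' @param n_variants number of variants to attempt.
#' @param freq_source `"fixed_f"` (all variants at `f_fixed` copies) or
#'   `"coalescent"` (allele counts drawn from a simulated SFS per
#'   population).
#' @param seed integer seed.
#' @param f_fixed derived allele count under `"fixed_f"` (default 2).
#' @param hom_prob probability a doubleton is a single homozygote (default
#'   0.1).
#' @param lowercase_aa_frac fraction of records with lowercase (low
#'   confidence) ancestral annotation.
#' @param cpg_repeat_frac fraction of CpG doubletons planted as repeat
#'   mutations (default 0).
#' @param sfs_trees number of trees behind each population's simulated SFS.
#' @param theta scaled mutation rate for the SFS simulation.
#' @return a [build_panel()] object whose `truth` records the planted
#'   multipliers, per-variant class, origin population, allele count and
#'   repeat flag.
#' @export
generate_panel <- function(reference, populations, n_variants,
                           freq_source = c("fixed_f", "coalescent"),
                           seed = 1, f_fixed = 2, hom_prob = 0.1,
                           lowercase_aa_frac = 0, cpg_repeat_frac = 0,
                           sfs_trees = 200, theta = 2) {
  freq_source <- match.arg(freq_source)
  if (length(populations) < 1) stop("at least one population required")
  stopifnot(all(vapply(populations, inherits, logical(1), "population_spec")))
  set.seed(seed)
  r <- .ref_seqstring(reference)
  sites <- context_site_index(reference)
  ct <- mutation_class_table()

  pop_names <- vapply(populations, `[[`, character(1), "name")
  pop_sizes <- vapply(populations, `[[`, integer(1), "n_samples")
  samples <- do.call(rbind, lapply(populations, function(p) {
    data.frame(sample = paste0(p$name, "-", seq_len(p$n_samples)),
               population = p$name, region = p$region, source = p$source,
               latitude = p$latitude, longitude = p$longitude,
               stringsAsFactors = FALSE)
  }))
  n_tot <- nrow(samples)
  pop_of_sample <- samples$population

  if (n_variants == 0) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           aa = character(0), stringsAsFactors = FALSE)
    geno <- matrix(0L, nrow = n_tot, ncol = 0)
    truth <- list(multipliers = lapply(populations, `[[`, "class_multipliers"),
                  class = character(0), origin = character(0),
                  allele_count = integer(0), is_repeat = logical(0),
                  freq_source = freq_source, seed = seed)
    names(truth$multipliers) <- pop_names
    return(build_panel(variants, geno, samples, truth))
  }

  # context availability and per-population class distributions
  avail <- table(factor(sites$context, levels = canonical_contexts()))
  base_p <- as.numeric(avail[ct$context]) / 3
  absent <- base_p == 0
  if (any(absent)) {
    warning("class(es) with no admissible context in the reference, skipped: ",
            paste(ct$label[absent], collapse = ", "))
  }
  class_p <- lapply(populations, function(p) {
    pr <- base_p * p$class_multipliers[ct$label]
    pr[absent] <- 0
    pr / sum(pr)
  })

  # shuffle site rows within each context for uniform no-replacement draws
  site_pool <- split(sites, sites$context)
  site_pool <- lapply(site_pool, function(d) d[sample.int(nrow(d)), ])
  pool_next <- setNames(rep(1L, length(site_pool)), names(site_pool))

  # per-population allele-count distributions
  freq_dist <- lapply(populations, function(p) {
    if (freq_source == "fixed_f") return(NULL)
    nh <- 2L * p$n_samples
    if (nh < 2) stop("coalescent frequencies need >= 1 diploid sample")
    s <- aggregate_sfs(nh, sfs_trees, theta = theta, model = p$growth,
                       kinds = "single")$single
    pr <- s$counts
    if (sum(pr) == 0) pr <- 1 / seq_len(nh - 1)
    pr / sum(pr)
  })

  origin <- sample.int(length(populations), n_variants, replace = TRUE,
                       prob = pop_sizes)
  cls_idx <- integer(n_variants)
  for (k in seq_along(populations)) {
    sel <- origin == k
    if (any(sel)) {
      cls_idx[sel] <- sample.int(96, sum(sel), replace = TRUE,
                                 prob = class_p[[k]])
    }
  }

  pos <- integer(n_variants)
  orient <- character(n_variants)
  keep <- logical(n_variants)
  for (v in seq_len(n_variants)) {
    ctx <- ct$context[cls_idx[v]]
    pool <- site_pool[[ctx]]
    i <- pool_next[ctx]
    if (is.null(pool) || is.na(i) || i > nrow(pool)) next  # context exhausted
    pos[v] <- pool$pos[i]
    orient[v] <- pool$orient[i]
    pool_next[ctx] <- i + 1L
    keep[v] <- TRUE
  }
  if (!all(keep)) {
    warning(sum(!keep), " variant(s) skipped: admissible sites exhausted")
  }
  origin <- origin[keep]; cls_idx <- cls_idx[keep]
  pos <- pos[keep]; orient <- orient[keep]
  nv <- length(pos)

  anc <- ifelse(orient == "+", ct$ancestral[cls_idx],
                .comp(ct$ancestral[cls_idx]))
  der <- ifelse(orient == "+", ct$derived[cls_idx], .comp(ct$derived[cls_idx]))

  a_count <- if (freq_source == "fixed_f") {
    rep(as.integer(f_fixed), nv)
  } else {
    vapply(seq_len(nv), function(v) {
      d <- freq_dist[[origin[v]]]
      sample.int(length(d), 1, prob = d)
    }, integer(1))
  }

  is_cpg <- ct$cpg[cls_idx] & ct$derived[cls_idx] == "T"
  is_repeat <- is_cpg & a_count == 2 &
    stats::runif(nv) < cpg_repeat_frac

  pop_first <- cumsum(c(1, pop_sizes))[seq_along(pop_sizes)]
  geno <- matrix(0L, nrow = n_tot, ncol = nv)
  for (v in seq_len(nv)) {
    k <- origin[v]
    np <- pop_sizes[k]
    idx0 <- pop_first[k] - 1L
    a <- min(a_count[v], 2L * np)
    if (is_repeat[v]) {
      who <- sample.int(n_tot, 2L)
      geno[who, v] <- 1L
    } else if (a == 2L && (freq_source == "fixed_f") && f_fixed == 2) {
      if (np == 1L || stats::runif(1) < hom_prob) {
        geno[idx0 + sample.int(np, 1L), v] <- 2L
      } else {
        geno[idx0 + sample.int(np, 2L), v] <- 1L
      }
    } else {
      hap <- sample.int(2L * np, a)
      who <- idx0 + ((hap - 1L) %/% 2L) + 1L
      for (s in who) geno[s, v] <- geno[s, v] + 1L
    }
    a_count[v] <- a
  }

  aa <- anc
  if (lowercase_aa_frac > 0) {
    lc <- stats::runif(nv) < lowercase_aa_frac
    aa[lc] <- tolower(aa[lc])
  }

  ord <- order(pos)
  variants <- data.frame(chrom = r$chrom, pos = pos[ord], ref = anc[ord],
                         alt = der[ord], aa = aa[ord],
                         stringsAsFactors = FALSE)
  geno <- geno[, ord, drop = FALSE]
  truth <- list(multipliers = setNames(lapply(populations, `[[`,
                                              "class_multipliers"), pop_names),
                class = ct$label[cls_idx][ord],
                origin = pop_names[origin][ord],
                allele_count = a_count[ord],
                is_repeat = is_repeat[ord],
                freq_source = freq_source, seed = seed)
  build_panel(variants, geno, samples, truth)
}

#' Specification of an annotation track
#'
#' @param kind `"strand"`, `"methylation"` or `"decile"`.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `label`; labels must be valid for the kind (`+`/`-`
#'   for strand, `high`/`low` for methylation, `0`..`9` for decile).
#' @param score for `kind = "decile"`, a numeric per-bin score from which
#'   decile labels are computed (alternative to explicit intervals).
#' @param bin_size bin width in bp used with `score` (default 1000).
#' @return object of class `track_spec`.
#' @export
track_spec <- function(kind = c("strand", "methylation", "decile"),
                       intervals = NULL, score = NULL, bin_size = 1000) {
  kind <- match.arg(kind)
  if (is.null(intervals) && is.null(score)) {
    if (kind == "decile") stop("decile tracks need intervals or a score")
    intervals <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), label = character(0))
  }
  if (!is.null(intervals)) {
    need <- c("chrom", "start", "end", "label")
    if (!all(need %in% names(intervals))) {
      stop("intervals must have columns: ", paste(need, collapse = ", "))
    }
    if (any(intervals$start < 0) || any(intervals$end <= intervals$start)) {
      stop("intervals must be 0-based half-open with start < end")
    }
    valid <- switch(kind,
                    strand = c("+", "-", "both", "none"),
                    methylation = c("high", "low"),
                    decile = as.character(0:9))
    bad <- setdiff(unique(as.character(intervals$label)), valid)
    if (length(bad) > 0) {
      stop("invalid ", kind, " label(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(list(kind = kind, intervals = intervals, score = score,
                 bin_size = bin_size), class = "track_spec")
}

#' Materialize annotation tracks over a reference
#'
#' Turns [track_spec()]s into labelled `GRanges`. For strand tracks,
#' overlapping intervals with contradictory `+`/`-` labels are merged to
#' `"both"` (regions transcribed on both strands); uncovered bases are
#' implicitly `"none"`. For decile tracks built from a score, the genome is
#' cut into `bin_size` bins and each bin is labelled by the decile of its
#' score, so each decile covers close to 10% of bins.
#'
#' @param reference the reference the tracks annotate (for bounds checks).
#' @param specs a [track_spec()] or list of them.
#' @param seed optional integer seed (tracks are deterministic given specs).
#' @return a `GRanges` with metadata column `label`, or a list of them when
#'   several specs are given.
#' @export
generate_tracks <- function(reference, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(specs, "track_spec")) return(.make_track(reference, specs))
  lapply(specs, function(sp) .make_track(reference, sp))
}

.make_track <- function(reference, sp) {
  stopifnot(inherits(sp, "track_spec"))
  r <- .ref_seqstring(reference)
  if (sp$kind == "decile" && !is.null(sp$score) && is.null(sp$intervals)) {
    n_bins <- ceiling(r$length / sp$bin_size)
    if (length(sp$score) != n_bins) {
      stop("score must have one value per ", sp$bin_size, " bp bin (",
           n_bins, ")")
    }
    dec <- .decile_labels(sp$score)
    gr <- GenomicRanges::GRanges(
      r$chrom,
      IRanges::IRanges(start = (seq_len(n_bins) - 1L) * sp$bin_size + 1L,
                       end = pmin(seq_len(n_bins) * sp$bin_size, r$length)))
    gr$label <- as.character(dec)
    return(gr)
  }
  iv <- sp$intervals
  if (any(iv$end > r$length)) stop("interval beyond reference length")
  if (nrow(iv) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$label <- character(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(start = iv$start + 1L,
                                                end = iv$end))
  gr$label <- as.character(iv$label)
  if (sp$kind != "strand") {
    return(sort(gr))
  }
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  lab <- tapply(gr$label[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits),
                function(ls) {
      u <- unique(ls)
      if ("both" %in% u || all(c("+", "-") %in% u)) "both" else u[1]
    })
  dj$label <- as.character(lab[as.character(seq_along(dj))])
  sort(dj)
}

.decile_labels <- function(score) {
  br <- stats::quantile(score, probs = 0:10 / 10, names = FALSE, type = 7)
  br <- unique(br)
  cut(score, breaks = br, labels = FALSE, include.lowest = TRUE) - 1L
}

#' CpG site lists by methylation state
#'
#' Lists the cytosine positions of CpG dinucleotides on the reference strand
#' falling in the `high` and `low` intervals of a methylation track.
#'
#' @param reference reference sequence.
#' @param track a methylation `GRanges` from [generate_tracks()].
#' @return list with `high` and `low` data.frames (`chrom`, `pos`).
#' @export
methylation_site_lists <- function(reference, track) {
  r <- .ref_seqstring(reference)
  cpg <- which(substring(r$seq, 1:(r$length - 1), 2:r$length) == "CG")
  gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(cpg, width = 1))
  hits <- GenomicRanges::findOverlaps(gr, track)
  lab <- rep(NA_character_, length(cpg))
  lab[S4Vectors::queryHits(hits)] <- track$label[S4Vectors::subjectHits(hits)]
  list(high = data.frame(chrom = r$chrom, pos = cpg[lab %in% "high"]),
       low = data.frame(chrom = r$chrom, pos = cpg[lab %in% "low"]))
}
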