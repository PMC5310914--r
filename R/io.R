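#' Write a reference sequence to FASTA
#' @param reference a [generate_reference()] result or `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  seq <- if (inherits(reference, "synthetic_reference")) reference$sequence
         else reference
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Read a reference sequence from FASTA
#' @param path FASTA file.
#' @return a `synthetic_reference`-style object with `sequence` and
#'   `trinuc_freqs`.
#' @export
read_reference_fasta <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  structure(list(sequence = seq,
                 trinuc_freqs = .canonical_trinuc_freqs(seq[[1]]),
                 spec = NULL),
            class = "synthetic_reference")
}

#' Write a variant panel to VCF
#'
#' Emits a VCF 4.2 file with the ancestral allele in the `AA` INFO tag
#' (lowercase = low confidence, following the 1000 Genomes convention) and
#' unphased `GT` genotypes.
#'
#' @param panel a [build_panel()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "mut_panel"))
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample), collapse = "\t")), con)
  if (nrow(panel$variants) > 0) {
    gt <- matrix(gt_code[panel$geno + 1L], nrow = nrow(panel$geno))
    rows <- vapply(seq_len(nrow(panel$variants)), function(v) {
      paste(c(panel$variants$chrom[v], panel$variants$pos[v], ".",
              panel$variants$ref[v], panel$variants$alt[v], ".", "PASS",
              paste0("AA=", panel$variants$aa[v]), "GT", gt[, v]),
            collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a variant panel from VCF
#'
#' Reads a VCF with `AA` INFO annotations and `GT` genotypes into the panel
#' representation used throughout the package. Sample metadata can be
#' supplied from a TSV (see [write_sample_metadata()]); otherwise samples get
#' placeholder population labels.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param metadata optional path to a sample metadata TSV.
#' @return a [build_panel()] object (without planted truth).
#' @export
read_panel_vcf <- function(path, metadata = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  aa <- vcfR::extract.info(v, "AA")
  gt <- vcfR::extract.gt(v, "GT")
  dos <- matrix(0L, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), NULL))
  if (nrow(gt) > 0) {
    parse_gt <- function(g) {
      ifelse(is.na(g), 0L,
             vapply(strsplit(g, "[/|]"),
                    function(p) sum(p == "1"), integer(1)))
    }
    for (i in seq_len(nrow(gt))) dos[, i] <- parse_gt(gt[i, ])
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, aa = aa,
                         stringsAsFactors = FALSE)
  samples <- if (!is.null(metadata)) {
    read_sample_metadata(metadata)
  } else {
    data.frame(sample = colnames(gt), population = "unknown",
               region = "unknown", source = "tissue",
               stringsAsFactors = FALSE)
  }
  samples <- samples[match(colnames(gt), samples$sample), , drop = FALSE]
  build_panel(variants, dos, samples)
}

#' Write and read the sample metadata table
#' @param samples data.frame of sample metadata.
#' @param path TSV file.
#' @return `path` (write) or the data.frame (read).
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write the planted-truth record to JSON
#' @param truth the `truth` element of a generated panel.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an annotation track to BED
#'
#' The track label (strand orientation, methylation state or decile) goes in
#' the BED name column, so labels outside the BED strand vocabulary
#' (`both`, deciles) survive the round trip.
#'
#' @param track a labelled `GRanges` from [generate_tracks()].
#' @param path BED file.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  gr <- track
  names(gr) <- gr$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read an annotation track from BED
#' @param path BED file written by [write_track_bed()].
#' @return a labelled `GRanges`.
#' @export
read_track_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$label <- gr$name
  gr$name <- NULL
  gr
}

#' Write a spectrum count or intensity matrix to TSV
#'
#' One row per canonical class (row label like `"ACG>T"`), one column per
#' sample.
#'
#' @param x a `spectrum_counts` or `intensity_matrix` object, or a matrix
#'   with class-label rownames.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(x, path) {
  m <- if (inherits(x, "spectrum_counts")) x$counts
       else if (inherits(x, "intensity_matrix")) x$values
       else x
  utils::write.table(data.frame(class = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum matrix from TSV
#' @param path TSV written by [write_spectrum_tsv()].
#' @return numeric matrix, classes x samples.
#' @export
read_spectrum_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
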