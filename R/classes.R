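.BASES <- c("A", "C", "G", "T")
.PYRIMIDINES <- c("C", "T")

#' Complement of single bases
#' @param x character vector of bases
#' @return complemented bases
#' @keywords internal
.comp <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse complement of a short sequence string
#' @keywords internal
.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.comp(s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate the 96 canonical trinucleotide mutation classes
#'
#' A mutation class is a single-base substitution together with its two
#' flanking bases, written `left ancestral right > derived` (e.g. `"ACG>T"`:
#' ancestral context ACG mutating so the middle base C becomes T). Classes are
#' stored in canonical pyrimidine-centred form: the ancestral middle base is C
#' or T, purine-centred substitutions being mapped through the reverse
#' complement of the whole context. There are 6 substitution types
#' (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flank pairs = 96 classes.
#'
#' The order is fixed and documented: substitution types in the order above,
#' then left flank (A, C, G, T), then right flank (A, C, G, T).
#'
#' @return character vector of 96 class labels.
#' @export
#' @examples
#' length(enumerate_classes())  # 96
#' head(enumerate_classes())
enumerate_classes <- function() {
  subs <- list(c("C", "A"), c("C", "G"), c("C", "T"),
               c("T", "A"), c("T", "C"), c("T", "G"))
  out <- character(0)
  for (s in subs) {
    for (l in .BASES) {
      for (r in .BASES) {
        out <- c(out, paste0(l, s[1], r, ">", s[2]))
      }
    }
  }
  out
}

#' Table of the 96 canonical classes with their components
#'
#' @return data.frame with columns `label`, `left`, `ancestral`, `right`,
#'   `derived`, `context` (the 3-mer `left ancestral right`) and `cpg`
#'   (logical; ancestral C immediately followed by G).
#' @export
mutation_class_table <- function() {
  labs <- enumerate_classes()
  left <- substr(labs, 1, 1)
  anc <- substr(labs, 2, 2)
  right <- substr(labs, 3, 3)
  der <- substr(labs, 5, 5)
  data.frame(
    label = labs, left = left, ancestral = anc, right = right, derived = der,
    context = paste0(left, anc, right),
    cpg = anc == "C" & right == "G",
    stringsAsFactors = FALSE
  )
}

#' Classify a polarized SNP into its canonical mutation class
#'
#' Takes the ancestral middle base, its two flanking bases (read 5'->3' on the
#' reference strand) and the derived base, and returns the canonical
#' pyrimidine-centred class label. Purine-ancestral inputs are mapped through
#' the reverse complement of the full context and of the derived base, so the
#' 96-class partition is identical whichever strand the variant is reported on.
#'
#' @param left,ancestral,right single flanking / ancestral bases (vectorized).
#' @param derived derived base (vectorized).
#' @return character vector of canonical class labels.
#' @export
#' @examples
#' classify_variant("A", "C", "G", "T")  # "ACG>T"
#' classify_variant("C", "G", "T", "A")  # same class via reverse complement
classify_variant <- function(left, ancestral, right, derived) {
  n <- max(length(left), length(ancestral), length(right), length(derived))
  left <- rep_len(toupper(left), n)
  ancestral <- rep_len(toupper(ancestral), n)
  right <- rep_len(toupper(right), n)
  derived <- rep_len(toupper(derived), n)
  ok <- left %in% .BASES & ancestral %in% .BASES & right %in% .BASES &
    derived %in% .BASES
  if (!all(ok)) {
    stop("ambiguous or invalid base(s) at position(s): ",
         paste(which(!ok), collapse = ", "))
  }
  if (any(derived == ancestral)) {
    stop("derived base equals ancestral base at position(s): ",
         paste(which(derived == ancestral), collapse = ", "))
  }
  flip <- !(ancestral %in% .PYRIMIDINES)
  l2 <- ifelse(flip, .comp(right), left)
  a2 <- ifelse(flip, .comp(ancestral), ancestral)
  r2 <- ifelse(flip, .comp(left), right)
  d2 <- ifelse(flip, .comp(derived), derived)
  paste0(l2, a2, r2, ">", d2)
}

#' Define a mutational signature as a set of classes
#'
#' A signature definition is a named, non-empty subset of the 96 canonical
#' classes. Labels may use `N` as a wildcard in the flank positions, e.g.
#' `"NCG>T"` expands to ACG>T, CCG>T, GCG>T and TCG>T.
#'
#' @param name label for the signature.
#' @param classes character vector of class labels, possibly wildcarded.
#' @return object of class `signature_definition` (list with `name`,
#'   `classes`).
#' @export
#' @examples
#' signature_definition("signature2", "NCG>T")
signature_definition <- function(name, classes) {
  all96 <- enumerate_classes()
  expanded <- unlist(lapply(classes, function(cl) {
    if (!grepl("N", cl)) return(cl)
    pat <- paste0("^", gsub("N", "[ACGT]", gsub(">", ">", cl, fixed = TRUE)), "$")
    grep(pat, all96, value = TRUE)
  }))
  expanded <- unique(expanded)
  bad <- setdiff(expanded, all96)
  if (length(bad) > 0) {
    stop("not canonical classes: ", paste(bad, collapse = ", "))
  }
  if (length(expanded) == 0) stop("empty signature definition")
  structure(list(name = name, classes = expanded),
            class = "signature_definition")
}

#' The European-enriched C>T signature (signature 1)
#'
#' Defined as the four classes TCT>T, TCC>T, CCC>T and ACC>T.
#' @return a [signature_definition()].
#' @export
signature1_definition <- function() {
  signature_definition("signature1", c("TCT>T", "TCC>T", "CCC>T", "ACC>T"))
}

#' The CpG deamination signature (signature 2)
#'
#' Defined as NCG>T for any flanking base N.
#' @return a [signature_definition()].
#' @export
signature2_definition <- function() {
  signature_definition("signature2", "NCG>T")
}

#' Canonicalize a trinucleotide context to pyrimidine-centred form
#'
#' @param context character vector of 3-mers.
#' @return list with `context` (canonical 3-mer) and `flipped` (logical; TRUE
#'   where the reverse complement was taken).
#' @export
canonical_context <- function(context) {
  mid <- substr(context, 2, 2)
  flip <- !(mid %in% .PYRIMIDINES)
  out <- context
  if (any(flip)) out[flip] <- .revcomp(context[flip])
  list(context = out, flipped = flip)
}

#' The 32 canonical trinucleotide contexts
#' @return character vector of 32 pyrimidine-centred 3-mers, in the flank
#'   order used by [enumerate_classes()].
#' @export
canonical_contexts <- function() {
  out <- character(0)
  for (m in .PYRIMIDINES) {
    for (l in .BASES) for (r in .BASES) out <- c(out, paste0(l, m, r))
  }
  out
}
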