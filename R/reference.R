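#' The twenty canonical amino acids
#'
#' One-letter codes in alphabetical order, used as the default substitution
#' alphabet for saturation mutagenesis libraries.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a reference protein from its coding sequence
#'
#' Holds the named reference open reading frame that a saturation-mutagenesis
#' library is built on: the nucleotide coding sequence (CDS) and its
#' translation, with 1-based residue numbering from the initiator methionine.
#'
#' @param name Short identifier, e.g. \code{"CXCR4"}.
#' @param cds Nucleotide coding sequence (a string, length divisible by 3), or
#'   a path to a FASTA file whose first record is the CDS.
#' @return An object of class \code{reference_protein} with elements
#'   \code{name}, \code{cds}, \code{aa} (translated protein) and
#'   \code{length} (number of residues).
#' @examples
#' ref <- reference_protein("toy", "ATGGCTTGCGATGAATTTGGTCATATTAAACTG")
#' ref$aa
#' @export
reference_protein <- function(name, cds) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(cds) == 1L && file.exists(cds)) {
    seqs <- Biostrings::readDNAStringSet(cds)
    if (length(seqs) == 0L) stop("FASTA file contains no sequences: ", cds)
    cds <- as.character(seqs[[1L]])
  }
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length (", nchar(cds), ") is not a multiple of 3")
  if (grepl("[^ACGT]", cds))
    stop("CDS contains characters other than A/C/G/T")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (substr(aa, nchar(aa), nchar(aa)) == "*") {
    # drop the stop codon from residue numbering
    aa <- substr(aa, 1L, nchar(aa) - 1L)
    cds_body <- substr(cds, 1L, nchar(cds) - 3L)
  } else {
    cds_body <- cds
  }
  if (grepl("\\*", aa))
    stop("CDS contains an internal stop codon")
  if (nchar(aa) < 10L)
    stop("reference protein must be at least 10 residues (got ", nchar(aa), ")")
  structure(
    list(name = name, cds = cds_body, cds_full = cds, aa = aa,
         length = nchar(aa)),
    class = "reference_protein"
  )
}

#' @export
print.reference_protein <- function(x, ...) {
  cat("Reference protein '", x$name, "': ", x$length, " residues, CDS ",
      nchar(x$cds), " nt\n", sep = "")
  cat("  ", substr(x$aa, 1L, min(60L, x$length)),
      if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Residue at a position of a reference protein
#' @param ref A \code{reference_protein}.
#' @param position 1-based residue index (vectorised).
#' @return One-letter amino-acid code(s).
#' @export
ref_residue <- function(ref, position) {
  stopifnot(inherits(ref, "reference_protein"))
  if (any(position < 1L | position > ref$length))
    stop("position out of range 1..", ref$length)
  substring(ref$aa, position, position)
}

#' Wild-type codon at a residue position
#' @inheritParams ref_residue
#' @return Codon string(s).
#' @export
ref_codon <- function(ref, position) {
  stopifnot(inherits(ref, "reference_protein"))
  substring(ref$cds, 3L * (position - 1L) + 1L, 3L * position)
}

# Genetic code lookup: amino acid -> sorted codons (standard code).
.codon_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aas <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd))),
    character(1L))
  split(codons, aas)
}

.pkg_cache <- new.env(parent = emptyenv())

codons_for_aa <- function(aa) {
  if (is.null(.pkg_cache$codons_by_aa))
    .pkg_cache$codons_by_aa <- .codon_table()
  cds <- .pkg_cache$codons_by_aa[[aa]]
  if (is.null(cds)) stop("no codon encodes amino acid '", aa, "'")
  cds
}

#' Deterministic mutant codon for an amino-acid substitution
#'
#' Each amino-acid change is represented in simulated reads by a single fixed
#' codon: the lexicographically smallest codon encoding the mutant amino acid.
#' (Real NNK libraries carry codon degeneracy; a fixed codon keeps simulated
#' reads unambiguous.)
#'
#' @param mut_aa One-letter code of the mutant amino acid (\code{"*"} for stop).
#' @return A codon string.
#' @export
mutant_codon <- function(mut_aa) {
  vapply(mut_aa, function(a) codons_for_aa(a)[1L], character(1L))
}

#' Validate a variant table against a reference
#'
#' Checks that positions are in range, wild-type residues match the reference,
#' and mutant differs from wild type. Used by count/enrichment constructors.
#'
#' @param df data.frame with columns \code{position}, \code{wt_aa}, \code{mut_aa}.
#' @param ref A \code{reference_protein}.
#' @return \code{df}, invisibly, after validation.
#' @export
validate_variants <- function(df, ref) {
  stopifnot(all(c("position", "wt_aa", "mut_aa") %in% names(df)))
  if (any(df$position < 1L | df$position > ref$length))
    stop("variant position outside 1..", ref$length)
  wt <- ref_residue(ref, df$position)
  bad <- which(df$wt_aa != wt)
  if (length(bad))
    stop("wild-type residue mismatch at position(s) ",
         paste(utils::head(df$position[bad], 5L), collapse = ", "),
         ": reference has ",
         paste(utils::head(wt[bad], 5L), collapse = ", "))
  if (any(df$mut_aa == df$wt_aa))
    stop("mut_aa equal to wt_aa for some variants")
  invisible(df)
}

# Canonical variant label, e.g. "I204W"
variant_label <- function(df) paste0(df$wt_aa, df$position, df$mut_aa)
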