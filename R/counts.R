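#' Construct a count table
#'
#' Per-condition read counts for every observed single amino-acid variant
#' plus the wild-type sequence. \code{coverage} records, per residue
#' position, how many accepted reads cover that position — the denominator
#' for that position's variant frequencies. With overlapping amplicon
#' fragments positions differ in coverage, and a read carrying a mutation
#' elsewhere in its fragment still covers (and is wild type at) every other
#' position, so coverage exceeds the fully-wild-type read count.
#'
#' @param counts data.frame with columns \code{position, wt_aa, mut_aa, count}.
#' @param wt_count Total fully wild-type (reference-matching) reads.
#' @param ref A \code{reference_protein}.
#' @param condition Condition label, e.g. \code{"naive"} or \code{"bifc"}.
#' @param coverage Named numeric of per-position accepted-read coverage;
#'   defaults to \code{wt_count + variant counts at the position} (adequate
#'   when each variant's reads span only its own position).
#' @param discarded Named integer vector of discarded-read counts by reason.
#' @param total_reads Total reads processed; defaults to
#'   \code{wt_count + sum(counts) + sum(discarded)}.
#' @return A \code{count_table}.
#' @export
count_table <- function(counts, wt_count, ref, condition = "unknown",
                        coverage = NULL, discarded = integer(0),
                        total_reads = NULL) {
  stopifnot(inherits(ref, "reference_protein"))
  counts <- as.data.frame(counts)
  stopifnot(all(c("position", "wt_aa", "mut_aa", "count") %in% names(counts)))
  validate_variants(counts, ref)
  if (any(counts$count < 0)) stop("negative counts")
  if (anyDuplicated(counts[, c("position", "mut_aa")]))
    stop("duplicate variant rows in count table")
  if (is.null(coverage)) {
    coverage <- rep(wt_count, ref$length)
    names(coverage) <- as.character(seq_len(ref$length))
    vsum <- tapply(counts$count, as.character(counts$position), sum)
    coverage[names(vsum)] <- coverage[names(vsum)] + vsum
  }
  if (is.null(total_reads))
    total_reads <- wt_count + sum(counts$count) + sum(discarded)
  structure(
    list(condition = condition, counts = counts, wt_count = wt_count,
         coverage = coverage, discarded = discarded,
         total_reads = total_reads, reference = ref),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table [", x$condition, "] on '", x$reference$name, "': ",
      nrow(x$counts), " variants, ", sum(x$counts$count),
      " variant reads, ", x$wt_count, " WT reads", sep = "")
  if (length(x$discarded))
    cat(", ", sum(x$discarded), " discarded (",
        paste(names(x$discarded), x$discarded, sep = "=", collapse = ", "),
        ")", sep = "")
  cat("; total ", x$total_reads, "\n", sep = "")
  invisible(x)
}

#' Count-table view of a simulated sort (no sequencing step)
#'
#' Extracts one condition's read counts from a \code{sort_sim} directly,
#' bypassing FASTQ emission and re-counting. Useful for scoring at read
#' depths where materialising reads is unnecessary.
#'
#' @param sim A \code{sort_sim}.
#' @param condition One of \code{"naive"}, \code{"expression"}, \code{"bifc"}.
#' @return A \code{count_table}.
#' @export
sim_count_table <- function(sim, condition = c("naive", "expression", "bifc")) {
  condition <- match.arg(condition)
  stopifnot(inherits(sim, "sort_sim"))
  counts <- sim$reads[, c("position", "wt_aa", "mut_aa")]
  counts$count <- sim$reads[[condition]]
  ref <- sim$lib$reference
  # reads here stand for full-length molecules: every accepted read covers
  # every position, so coverage is uniform
  cov <- rep(sim$wt_reads[[condition]] + sum(counts$count), ref$length)
  names(cov) <- as.character(seq_len(ref$length))
  count_table(counts, wt_count = sim$wt_reads[[condition]],
              ref = ref, condition = condition, coverage = cov)
}

# parse "frag=<i>" from FASTQ read headers
.frag_from_header <- function(headers) {
  m <- regmatches(headers, regexpr("frag=\\d+", headers))
  if (length(m) != length(headers)) return(NULL)
  as.integer(sub("frag=", "", m))
}

#' Call codon-level variants from amplicon FASTQ reads
#'
#' Compares each read to its amplicon fragment of the reference CDS by exact
#' ungapped codon-wise comparison (amplicon sequencing has fixed coordinates;
#' no aligner is involved). Reads matching the fragment reference at every
#' codon count as wild type; reads with exactly one mutated codon translating
#' to a non-wild-type amino acid count toward that variant. Everything else
#' is discarded with a reason code: \code{multi_mutant} (more mutated codons
#' than \code{max_mismatch_codons}), \code{ambiguous} (non-ACGT base in a
#' mutated codon), \code{stop_codon} (premature stop, when \code{"*"} is not
#' in the allowed alphabet), \code{indel_or_unaligned} (length matching no
#' fragment). Synonymous single-codon changes count as wild type (identity
#' at the amino-acid level).
#'
#' The fragment of each read is identified from the \code{frag=<i>} tag in
#' the simulator's headers, falling back to unique read length.
#'
#' @param fastq Path to a FASTQ file (one condition).
#' @param ref A \code{reference_protein}.
#' @param fragments List of codon-aligned CDS intervals (as used to emit).
#' @param max_mismatch_codons Maximum mutated codons per read (default 1).
#' @param alphabet Allowed mutant amino acids; reads creating a stop codon
#'   are discarded unless \code{"*"} is included.
#' @param condition Condition label recorded in the output tables.
#' @return List of per-fragment \code{count_table}s (one per fragment, in
#'   fragment order), each with \code{coverage} defined on the fragment's
#'   positions only. Merge with \code{\link{merge_fragment_counts}}.
#' @export
call_codon_variants <- function(fastq, ref, fragments,
                                max_mismatch_codons = 1L,
                                alphabet = AA20, condition = "unknown") {
  stopifnot(inherits(ref, "reference_protein"))
  .check_fragments(fragments, ref)
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  if (length(reads) == 0L) stop("empty FASTQ input: ", fastq)

  fragments <- lapply(fragments, as.integer)
  frag_len <- vapply(fragments, function(fr) fr[2] - fr[1] + 1L, integer(1))
  frag_id <- .frag_from_header(names(reads))
  widths <- Biostrings::width(reads)
  if (is.null(frag_id)) {
    # fall back to read length, which must identify the fragment uniquely
    if (anyDuplicated(frag_len))
      stop("fragments share lengths and headers carry no frag= tag; ",
           "cannot identify fragments")
    frag_id <- match(widths, frag_len)
  }

  allow_stop <- "*" %in% alphabet
  seqs <- as.character(reads)

  out <- vector("list", length(fragments))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    fpos <- .frag_positions(fr)
    ref_codons <- substring(substr(ref$cds, fr[1], fr[2]),
                            seq(1L, frag_len[i], by = 3L),
                            seq(3L, frag_len[i], by = 3L))
    ref_aas <- ref_residue(ref, fpos)

    mine <- which(frag_id == i & !is.na(frag_id))
    bad_len <- sum(widths[mine] != frag_len[i])
    mine <- mine[widths[mine] == frag_len[i]]

    disc <- c(multi_mutant = 0L, ambiguous = 0L, stop_codon = 0L,
              indel_or_unaligned = bad_len, not_in_alphabet = 0L)
    wt_n <- 0L
    var_counts <- new.env(parent = emptyenv())

    n_cod <- length(fpos)
    if (length(mine)) {
      read_codons <- matrix(substring(seqs[mine],
                                      rep(seq(1L, frag_len[i], by = 3L),
                                          each = length(mine)),
                                      rep(seq(3L, frag_len[i], by = 3L),
                                          each = length(mine))),
                            nrow = length(mine))
      mism <- read_codons != matrix(ref_codons, nrow = length(mine),
                                    ncol = n_cod, byrow = TRUE)
      n_mut <- rowSums(mism)
      for (r in seq_along(mine)) {
        if (n_mut[r] == 0L) { wt_n <- wt_n + 1L; next }
        if (n_mut[r] > max_mismatch_codons) {
          disc[["multi_mutant"]] <- disc[["multi_mutant"]] + 1L; next
        }
        j <- which(mism[r, ])[1L]
        cod <- read_codons[r, j]
        if (grepl("[^ACGT]", cod)) {
          disc[["ambiguous"]] <- disc[["ambiguous"]] + 1L; next
        }
        aa <- Biostrings::GENETIC_CODE[[cod]]
        if (aa == ref_aas[j]) { wt_n <- wt_n + 1L; next }  # synonymous
        if (aa == "*" && !allow_stop) {
          disc[["stop_codon"]] <- disc[["stop_codon"]] + 1L; next
        }
        if (!aa %in% alphabet) {
          disc[["not_in_alphabet"]] <- disc[["not_in_alphabet"]] + 1L; next
        }
        key <- paste0(fpos[j], "_", aa)
        var_counts[[key]] <- (if (is.null(var_counts[[key]])) 0L
                              else var_counts[[key]]) + 1L
      }
    }

    keys <- ls(var_counts)
    if (length(keys)) {
      parts <- strsplit(keys, "_", fixed = TRUE)
      cdf <- data.frame(
        position = as.integer(vapply(parts, `[`, "", 1L)),
        mut_aa = vapply(parts, `[`, "", 2L),
        count = vapply(keys, function(k) var_counts[[k]], integer(1)),
        stringsAsFactors = FALSE)
      cdf$wt_aa <- ref_residue(ref, cdf$position)
      cdf <- cdf[order(cdf$position, cdf$mut_aa),
                 c("position", "wt_aa", "mut_aa", "count")]
      rownames(cdf) <- NULL
    } else {
      cdf <- data.frame(position = integer(0), wt_aa = character(0),
                        mut_aa = character(0), count = integer(0))
    }
    # every accepted read of this fragment covers all its positions
    cov <- rep(wt_n + sum(cdf$count), n_cod)
    names(cov) <- as.character(fpos)
    out[[i]] <- count_table(cdf, wt_count = wt_n, ref = ref,
                            condition = condition, coverage = cov,
                            discarded = disc[disc > 0L],
                            total_reads = wt_n + sum(cdf$count) +
                              sum(disc))
  }
  out
}

#' Merge per-fragment count tables into one
#'
#' Sums per-variant counts across fragments covering each position and
#' records per-position effective coverage (sum of each covering fragment's
#' accepted reads) for downstream frequency computation. No reads are
#' created or lost: the merged totals equal the sum of inputs.
#'
#' @param tables List of \code{count_table}s sharing reference and condition.
#' @return A single merged \code{count_table}.
#' @export
merge_fragment_counts <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "count_table")))
  ref <- tables[[1L]]$reference
  cond <- tables[[1L]]$condition
  for (tb in tables[-1L]) {
    if (!identical(tb$reference$name, ref$name) ||
        !identical(tb$reference$cds, ref$cds))
      stop("count tables built on conflicting references")
    if (!identical(tb$condition, cond))
      stop("count tables from different conditions")
  }
  if (length(tables) == 1L) return(tables[[1L]])

  all_counts <- do.call(rbind, lapply(tables, `[[`, "counts"))
  agg <- stats::aggregate(count ~ position + wt_aa + mut_aa, data = all_counts,
                          FUN = sum)
  agg <- agg[order(agg$position, agg$mut_aa),
             c("position", "wt_aa", "mut_aa", "count")]
  rownames(agg) <- NULL

  cov <- numeric(ref$length)
  names(cov) <- as.character(seq_len(ref$length))
  for (tb in tables) cov[names(tb$coverage)] <- cov[names(tb$coverage)] +
    tb$coverage
  disc_all <- unlist(lapply(tables, `[[`, "discarded"))
  disc <- if (length(disc_all)) tapply(disc_all, names(disc_all), sum) else
    integer(0)
  disc <- stats::setNames(as.integer(disc), names(disc))

  count_table(agg, wt_count = sum(vapply(tables, `[[`, numeric(1), "wt_count")),
              ref = ref, condition = cond, coverage = cov, discarded = disc,
              total_reads = sum(vapply(tables, `[[`, numeric(1),
                                       "total_reads")))
}

#' Count variants from a condition's FASTQ in one call
#'
#' Convenience wrapper: \code{\link{call_codon_variants}} followed by
#' \code{\link{merge_fragment_counts}}.
#'
#' @inheritParams call_codon_variants
#' @return A merged \code{count_table}.
#' @export
count_reads <- function(fastq, ref, fragments, max_mismatch_codons = 1L,
                        alphabet = AA20, condition = "unknown") {
  merge_fragment_counts(call_codon_variants(
    fastq, ref, fragments, max_mismatch_codons = max_mismatch_codons,
    alphabet = alphabet, condition = condition))
}

#' Write a count table to TSV
#'
#' Writes the variant counts with columns
#' \code{condition, position, wt_aa, mut_aa, count}; the wild-type row uses
#' \code{mut_aa = "="}. A sidecar \code{<file>.discards.tsv} summarises
#' discarded reads by reason when any were discarded.
#'
#' @param x A \code{count_table}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_count_table <- function(x, file) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(condition = x$condition, x$counts)
  wt_row <- data.frame(condition = x$condition, position = 0L, wt_aa = "=",
                       mut_aa = "=", count = x$wt_count)
  utils::write.table(rbind(wt_row, df), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(x$discarded)) {
    utils::write.table(
      data.frame(reason = names(x$discarded), count = as.integer(x$discarded)),
      paste0(file, ".discards.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(file)
}
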