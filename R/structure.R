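#' Map conservation scores onto a protein structure
#'
#' Projects a per-residue conservation profile onto a PDB structure for
#' surface visualisation: scores are clamped to the display range
#' \code{[-3, +3]} and written into the temperature-factor (B-factor) column
#' of every atom of the matched residues, so external viewers can colour the
#' surface from depleted/deleterious (negative) to enriched (positive).
#' Residues of the chain with no profile score get a sentinel B-factor of
#' 99.0. A plain-text attribute file preserves the unclamped scores.
#'
#' Residue numbering is reconciled by a single integer offset:
#' \code{structure residue number = profile position + offset} (receptor
#' crystal structures of fusion constructs are typically offset-numbered but
#' colinear).
#'
#' @param profile A \code{conservation_profile}.
#' @param pdb Path to a PDB (or mmCIF) file, single model.
#' @param chain Chain identifier to annotate.
#' @param offset Integer numbering offset (default 0).
#' @param clamp B-factor clamp, default \code{c(-3, 3)}.
#' @param out_pdb Output PDB path (written via \pkg{bio3d}).
#' @param out_attr Optional attribute-file path: header lines naming chain
#'   and offset, then one \code{residue<TAB>score} line per mapped residue
#'   (unclamped, full precision).
#' @return A \code{structure_annotation} list: \code{mapped} (data.frame
#'   \code{position, resno, score, clamped}), \code{unmapped} (profile
#'   positions absent from the chain), \code{chain}, \code{offset},
#'   \code{out_pdb}, \code{out_attr}.
#' @export
map_scores_to_structure <- function(profile, pdb, chain, offset = 0L,
                                    clamp = c(-3, 3), out_pdb, out_attr = NULL) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (nrow(profile) == 0L) stop("empty conservation profile")
  struct <- bio3d::read.pdb(pdb)
  atoms <- struct$atom
  in_chain <- atoms$chain == chain
  if (!any(in_chain)) stop("chain '", chain, "' not present in structure")

  target_resno <- profile$position + offset
  chain_resno <- atoms$resno[in_chain]
  mapped_mask <- target_resno %in% chain_resno
  if (!any(mapped_mask))
    stop("no profile positions map onto chain '", chain,
         "' with offset ", offset)

  clamped <- pmin(pmax(profile$score, clamp[1]), clamp[2])
  # sentinel for chain residues without a score
  b <- atoms$b
  b[in_chain] <- 99.0
  for (i in which(mapped_mask)) {
    sel <- in_chain & atoms$resno == target_resno[i]
    b[sel] <- clamped[i]
  }
  struct$atom$b <- round(b, 2)
  bio3d::write.pdb(struct, file = out_pdb)

  mapped <- data.frame(position = profile$position[mapped_mask],
                       resno = target_resno[mapped_mask],
                       score = profile$score[mapped_mask],
                       clamped = clamped[mapped_mask])
  unmapped <- profile$position[!mapped_mask]
  if (length(unmapped))
    message(length(unmapped), " profile position(s) not present in chain ",
            chain, ": ", paste(utils::head(unmapped, 10L), collapse = ", "),
            if (length(unmapped) > 10L) " ..." else "")

  if (!is.null(out_attr)) {
    con <- file(out_attr, "w")
    on.exit(close(con))
    writeLines(c(paste0("# chain ", chain), paste0("# offset ", offset)), con)
    writeLines(sprintf("%d\t%.*g", mapped$resno, 15L, mapped$score), con)
  }
  structure(list(mapped = mapped, unmapped = unmapped, chain = chain,
                 offset = offset, clamp = clamp, out_pdb = out_pdb,
                 out_attr = out_attr),
            class = "structure_annotation")
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat("Structure annotation: chain ", x$chain, ", offset ", x$offset, "; ",
      nrow(x$mapped), " residues mapped, ", length(x$unmapped),
      " unmapped\n", sep = "")
  cat("  B-factors clamped to [", x$clamp[1], ", ", x$clamp[2],
      "]; written to ", x$out_pdb, "\n", sep = "")
  invisible(x)
}

#' Extract a residue set from a structure
#'
#' Builds residue-position sets (e.g. candidate dimer-interface residues)
#' from a structure, either from an explicit residue-number list or by a
#' contact rule: residues of \code{chain} with any heavy atom within
#' \code{cutoff} angstroms of any heavy atom of \code{other_chain}. Returned
#' positions are in profile (1-based reference) numbering, i.e. structure
#' residue number minus \code{offset}.
#'
#' @param pdb Path to a PDB file.
#' @param chain Chain to select residues from.
#' @param residues Explicit structure residue numbers (mutually exclusive
#'   with the contact rule).
#' @param other_chain Chain against which contacts are measured.
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 4.5);
#'   must be positive.
#' @param offset Numbering offset (structure = profile + offset).
#' @return Sorted integer vector of profile positions.
#' @export
extract_residue_set <- function(pdb, chain, residues = NULL,
                                other_chain = NULL, cutoff = 4.5,
                                offset = 0L) {
  struct <- bio3d::read.pdb(pdb)
  atoms <- struct$atom
  if (!any(atoms$chain == chain))
    stop("chain '", chain, "' not present in structure")

  if (!is.null(residues)) {
    have <- unique(atoms$resno[atoms$chain == chain])
    missing <- setdiff(residues, have)
    if (length(missing))
      stop("residues not in chain ", chain, ": ",
           paste(missing, collapse = ", "))
    return(sort(unique(as.integer(residues) - offset)))
  }

  if (is.null(other_chain))
    stop("supply either an explicit residue list or other_chain for contacts")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!any(atoms$chain == other_chain))
    stop("chain '", other_chain, "' not present in structure")

  heavy <- atoms$elesy != "H" & !grepl("^H", atoms$elety)
  a <- atoms[atoms$chain == chain & heavy, c("resno", "x", "y", "z")]
  bxyz <- as.matrix(atoms[atoms$chain == other_chain & heavy,
                          c("x", "y", "z")])
  axyz <- as.matrix(a[, c("x", "y", "z")])
  # squared distances from each chain atom to its nearest partner atom
  d2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), "+") -
    2 * axyz %*% t(bxyz)
  near <- apply(d2, 1L, min) <= cutoff^2 + 1e-9
  sort(unique(as.integer(a$resno[near]) - offset))
}

#' Read a score attribute file
#'
#' Parses the residue/score attribute file written by
#' \code{\link{map_scores_to_structure}}.
#'
#' @param file Attribute file path.
#' @return data.frame \code{resno, score} with attributes \code{chain} and
#'   \code{offset}.
#' @export
read_attribute_file <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- data.frame(resno = as.integer(vapply(parts, `[`, "", 1L)),
                    score = as.numeric(vapply(parts, `[`, "", 2L)))
  ch <- sub("^# chain ", "", grep("^# chain", hdr, value = TRUE))
  of <- sub("^# offset ", "", grep("^# offset", hdr, value = TRUE))
  attr(out, "chain") <- if (length(ch)) ch else NA_character_
  attr(out, "offset") <- if (length(of)) as.integer(of) else NA_integer_
  out
}
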