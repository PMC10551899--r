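#' Predict aggregation-promoting mutations
#'
#' A mutation is called aggregating when its wild-type-normalized log2
#' enrichment ratio in the high-BiFC selection exceeds the threshold in BOTH
#' independent replicates (strict conjunction; a variant absent or unscored
#' in either replicate is never called). Stop and synonymous changes are not
#' missense and are excluded from the call set and denominators.
#'
#' Two fractions are reported, because the natural denominator is ambiguous:
#' predicted calls over variants actually scored in both replicates, and
#' over all possible missense variants of the protein (19 per residue).
#'
#' @param repA,repB \code{enrichment_table}s of the BiFC selection, one per
#'   replicate.
#' @param threshold Log2 enrichment cutoff, exceeded strictly (default 1.0).
#' @param n_possible Total possible missense count for the all-possible
#'   denominator; default \code{19 * max(position)} inferred from the tables.
#' @return An \code{aggregation_calls} list: \code{predicted} (data.frame of
#'   called variants with both replicate scores), \code{n_predicted},
#'   \code{n_scored}, \code{n_possible}, \code{fraction_of_scored},
#'   \code{fraction_of_possible}, \code{threshold}.
#' @export
predict_aggregating <- function(repA, repB, threshold = 1.0,
                                n_possible = NULL) {
  stopifnot(inherits(repA, "enrichment_table"),
            inherits(repB, "enrichment_table"))
  if (!is.finite(threshold)) stop("threshold must be finite")

  key <- function(d) paste0(d$position, "_", d$mut_aa)
  a <- repA[repA$mut_aa != "*", ]
  b <- repB[repB$mut_aa != "*", ]
  m <- merge(data.frame(key = key(a), position = a$position, wt_aa = a$wt_aa,
                        mut_aa = a$mut_aa, lr_a = a$log2_ratio),
             data.frame(key = key(b), lr_b = b$log2_ratio), by = "key")
  scored <- m[!is.na(m$lr_a) & !is.na(m$lr_b), ]
  hit <- scored[scored$lr_a > threshold & scored$lr_b > threshold, ]
  hit <- hit[order(hit$position, hit$mut_aa),
             c("position", "wt_aa", "mut_aa", "lr_a", "lr_b")]
  rownames(hit) <- NULL

  if (is.null(n_possible))
    n_possible <- 19L * max(c(repA$position, repB$position))

  universe <- scored[order(scored$position, scored$mut_aa),
                     c("position", "wt_aa", "mut_aa")]
  rownames(universe) <- NULL

  structure(list(predicted = hit,
                 universe = universe,
                 n_predicted = nrow(hit),
                 n_scored = nrow(scored),
                 n_possible = n_possible,
                 fraction_of_scored = nrow(hit) / nrow(scored),
                 fraction_of_possible = nrow(hit) / n_possible,
                 threshold = threshold),
            class = "aggregation_calls")
}

#' @export
print.aggregation_calls <- function(x, ...) {
  cat("Aggregation calls (log2 ratio > ", x$threshold,
      " in both replicates):\n", sep = "")
  cat(sprintf("  %d predicted / %d scored missense (%.1f%%); / %d possible (%.1f%%)\n",
              x$n_predicted, x$n_scored, 100 * x$fraction_of_scored,
              x$n_possible, 100 * x$fraction_of_possible))
  invisible(x)
}

#' Read a missense variant list (gnomAD-style CSV)
#'
#' Expected columns: \code{position, wt_aa, mut_aa} and optionally
#' \code{allele_count, allele_frequency, source} (and \code{protein},
#' ignored). Duplicated variants are rejected; every record's wild-type
#' residue is checked against the reference and any mismatch is a hard error
#' naming the offending records (a numbering mismatch would silently
#' misalign the whole cross-reference).
#'
#' @param file CSV path.
#' @param ref A \code{reference_protein}.
#' @return data.frame of validated variant records.
#' @export
read_variant_list <- function(file, ref) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_variant_list(df, ref)
}

#' @rdname read_variant_list
#' @param df data.frame already in memory.
#' @export
validate_variant_list <- function(df, ref) {
  stopifnot(all(c("position", "wt_aa", "mut_aa") %in% names(df)))
  if (anyDuplicated(df[, c("position", "mut_aa")])) {
    d <- df[duplicated(df[, c("position", "mut_aa")]), ]
    stop("duplicate variant records: ",
         paste(utils::head(variant_label(d), 5L), collapse = ", "))
  }
  if (any(df$position < 1L | df$position > ref$length))
    stop("variant positions outside reference numbering")
  wt <- ref_residue(ref, df$position)
  bad <- which(df$wt_aa != wt)
  if (length(bad))
    stop("wild-type residue mismatch against reference (numbering error?): ",
         paste(utils::head(variant_label(df[bad, , drop = FALSE]), 5L),
               collapse = ", "))
  if (any(df$mut_aa == df$wt_aa)) stop("synonymous records in variant list")
  df
}

#' Cross-reference predicted variants against an observed variant list
#'
#' Intersects predicted aggregating mutations with variants observed in a
#' population database (e.g. gnomAD missense records) and asks whether the
#' overlap is smaller than chance: a hypergeometric depletion p-value for
#' the number of observed variants among the predicted set, given the
#' scored-variant universe. A depleted overlap is consistent with
#' aggregating mutations being purged from the population.
#'
#' Only observed variants inside the scored universe enter the test;
#' with an empty observed list the p-value is undefined and reported as NA.
#'
#' @param calls An \code{aggregation_calls} object (or data.frame of
#'   predicted variants with position/mut_aa columns).
#' @param observed Validated variant list (see \code{\link{read_variant_list}}).
#' @param universe data.frame of all scored missense variants
#'   (position/mut_aa); defaults to the scored set recorded in \code{calls}
#'   if available, otherwise required.
#' @return A \code{cross_reference} list: \code{overlap} (data.frame of
#'   observed-and-predicted variants), \code{n_overlap}, \code{n_observed},
#'   \code{n_observed_in_universe}, \code{n_predicted}, \code{n_universe},
#'   \code{p_depletion} (one-sided hypergeometric, P(X <= overlap)).
#' @export
cross_reference_variants <- function(calls, observed, universe = NULL) {
  pred <- if (inherits(calls, "aggregation_calls")) calls$predicted else calls
  key <- function(d) paste0(d$position, "_", d$mut_aa)
  if (is.null(universe)) {
    if (inherits(calls, "aggregation_calls") && !is.null(calls$universe))
      universe <- calls$universe
    else stop("a scored-variant universe is required")
  }

  ku <- key(universe); kp <- key(pred); ko <- key(observed)
  if (!all(kp %in% ku)) stop("predicted variants outside the universe")
  obs_in <- observed[ko %in% ku, , drop = FALSE]
  ov <- obs_in[key(obs_in) %in% kp, , drop = FALSE]

  n_u <- length(unique(ku)); n_p <- length(unique(kp))
  n_o <- nrow(obs_in); n_ov <- nrow(ov)
  p <- if (n_o == 0L) NA_real_ else
    stats::phyper(n_ov, n_p, n_u - n_p, n_o)

  structure(list(overlap = ov, n_overlap = n_ov, n_observed = nrow(observed),
                 n_observed_in_universe = n_o, n_predicted = n_p,
                 n_universe = n_u, p_depletion = p),
            class = "cross_reference")
}

#' @export
print.cross_reference <- function(x, ...) {
  cat("Cross-reference: ", x$n_overlap, " of ", x$n_observed_in_universe,
      " observed variants (", x$n_observed, " supplied) fall in the ",
      x$n_predicted, "-variant predicted set (universe ", x$n_universe,
      ")\n", sep = "")
  if (x$n_overlap > 0)
    cat("  overlapping: ",
        paste(variant_label(x$overlap), collapse = ", "), "\n", sep = "")
  cat("  hypergeometric depletion p = ",
      if (is.na(x$p_depletion)) "undefined (no observed variants in universe)"
      else format(x$p_depletion, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permutation test for interface conservation
#'
#' Tests whether candidate dimer-interface residues are more conserved
#' (lower mean conservation score, since depleted mutations have negative
#' log2 ratios) than the remaining membrane-exposed residues. The statistic
#' is \code{mean(score[interface]) - mean(score[other membrane-exposed])};
#' the null is built by permuting the interface labels among the
#' membrane-exposed residues, and the one-sided p-value asks how often a
#' permuted difference is as negative as observed, with add-one correction
#' \code{(b + 1)/(n_perm + 1)}. With \code{exact = TRUE} all label
#' assignments are enumerated instead.
#'
#' @param profile A \code{conservation_profile}.
#' @param interface Integer positions of the candidate interface.
#' @param membrane_exposed Integer positions of all membrane-exposed
#'   residues; must be a strict superset of \code{interface}.
#' @param n_perm Number of label permutations (default 10000, minimum 100).
#' @param seed Integer RNG seed.
#' @param exact Enumerate all \code{choose(n, k)} label assignments instead
#'   of sampling (feasible for small sets); p-value is then the exact
#'   fraction of assignments at least as extreme.
#' @return An \code{interface_test} list: \code{statistic} (observed mean
#'   difference), \code{p_value}, \code{n_interface}, \code{n_other},
#'   \code{n_perm}, \code{exact}.
#' @export
interface_conservation_test <- function(profile, interface, membrane_exposed,
                                        n_perm = 10000L, seed = 1L,
                                        exact = FALSE) {
  stopifnot(inherits(profile, "conservation_profile"))
  interface <- unique(as.integer(interface))
  membrane_exposed <- unique(as.integer(membrane_exposed))
  if (!all(interface %in% membrane_exposed))
    stop("interface residues must be a subset of membrane-exposed residues")
  if (length(interface) == length(membrane_exposed))
    stop("interface equals the membrane-exposed set; no null support")
  if (!exact && n_perm < 100L) stop("n_perm must be >= 100")

  sc <- profile$score[match(membrane_exposed, profile$position)]
  keep <- !is.na(sc)
  if (sum(keep & membrane_exposed %in% interface) == 0L ||
      sum(keep & !membrane_exposed %in% interface) == 0L)
    stop("both residue sets need scored positions")
  pos <- membrane_exposed[keep]; sc <- sc[keep]
  is_if <- pos %in% interface
  k <- sum(is_if); n <- length(pos)

  stat_fun <- function(lab) mean(sc[lab]) - mean(sc[!lab])
  obs <- stat_fun(is_if)

  if (exact) {
    combos <- utils::combn(n, k)
    perm <- apply(combos, 2L, function(ix) {
      lab <- logical(n); lab[ix] <- TRUE; stat_fun(lab)
    })
    p <- mean(perm <= obs + 1e-12)
    n_used <- ncol(combos)
  } else {
    set.seed(seed)
    perm <- replicate(n_perm, {
      lab <- logical(n); lab[sample.int(n, k)] <- TRUE; stat_fun(lab)
    })
    p <- (sum(perm <= obs + 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = obs, p_value = p, n_interface = k,
                 n_other = n - k, n_perm = n_used, exact = exact),
            class = "interface_test")
}

#' @export
print.interface_test <- function(x, ...) {
  cat(sprintf(
    "Interface conservation test: mean difference %.3f (interface n=%d vs other n=%d)\n",
    x$statistic, x$n_interface, x$n_other))
  cat(sprintf("  one-sided p = %.4g (%s, %d permutations)\n", x$p_value,
              if (x$exact) "exact enumeration" else "sampled", x$n_perm))
  invisible(x)
}
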