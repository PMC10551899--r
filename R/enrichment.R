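#' Naive-library frequency thresholds for confidence flags
#'
#' Variants with pseudocount-free naive frequency below 5e-6 are considered
#' absent from the library and receive no score; variants at or above 5e-5
#' are flagged confident; frequencies in between are rare (scored, but
#' noisier between replicates).
#' @export
FREQ_ABSENT <- 5e-6
#' @rdname FREQ_ABSENT
#' @export
FREQ_CONFIDENT <- 5e-5

#' Per-variant frequencies from a count table
#'
#' Computes, for every variant, its frequency among reads covering its
#' position: \code{f = (count + pseudocount) / (coverage + alphabet_size *
#' pseudocount)}, the fragment-local convention that corrects for unequal
#' amplicon coverage. The wild-type frequency at a position is the fraction
#' of covering reads that are wild type there (coverage minus all variant
#' counts at the position). The pseudocount-free frequency
#' (\code{raw_freq}) is retained for the absent/rare/confident flags.
#' Positions with zero coverage yield \code{raw_freq = NA} (flagged absent
#' downstream), never a division by zero.
#'
#' @param tab A \code{count_table}.
#' @param pseudocount Added to every count (default 0.5).
#' @param alphabet_size Number of amino-acid states per position used in the
#'   pseudocount denominator (default 20).
#' @param universe Optional data.frame \code{position, wt_aa, mut_aa} to
#'   report frequencies over (variants missing from the table get count 0);
#'   defaults to the table's own variants.
#' @return data.frame \code{position, wt_aa, mut_aa, count, depth, freq,
#'   raw_freq} with attributes \code{wt_freq}/\code{wt_raw} (per-position
#'   wild-type frequencies, same conventions).
#' @export
compute_frequencies <- function(tab, pseudocount = 0.5, alphabet_size = 20L,
                                universe = NULL) {
  stopifnot(inherits(tab, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  depth <- tab$coverage
  # wild-type reads at each position: coverage minus variants called there
  vsum <- tapply(tab$counts$count, as.character(tab$counts$position), sum)
  wt_at <- depth
  wt_at[names(vsum)] <- wt_at[names(vsum)] - vsum

  if (is.null(universe)) {
    uv <- tab$counts[, c("position", "wt_aa", "mut_aa")]
    cnt <- tab$counts$count
  } else {
    uv <- universe[, c("position", "wt_aa", "mut_aa")]
    key <- function(d) paste0(d$position, "_", d$mut_aa)
    cnt <- tab$counts$count[match(key(uv), key(tab$counts))]
    cnt[is.na(cnt)] <- 0L
  }
  d <- depth[as.character(uv$position)]
  freq <- (cnt + pseudocount) / (d + alphabet_size * pseudocount)
  raw <- ifelse(d > 0, cnt / d, NA_real_)
  freq[d == 0] <- NA_real_

  wt_freq <- (wt_at + pseudocount) / (depth + alphabet_size * pseudocount)
  wt_raw <- ifelse(depth > 0, wt_at / depth, NA_real_)

  out <- data.frame(uv, count = cnt, depth = as.numeric(d),
                    freq = freq, raw_freq = raw)
  attr(out, "wt_freq") <- wt_freq
  attr(out, "wt_raw") <- wt_raw
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Wild-type-normalized log2 enrichment ratios
#'
#' The scan's core statistic. For each variant,
#' \deqn{E_v = \log_2(f_{sel,v}/f_{naive,v}) - \log_2(f_{sel,WT}/f_{naive,WT})}
#' so that by construction the wild-type sequence scores exactly 0; a variant
#' enriched 4-fold while wild type is unchanged scores exactly 2. The
#' wild-type term is evaluated at the variant's own position (fragment-local
#' depth convention). Variants whose pseudocount-free naive frequency is
#' below \code{5e-6} are considered absent from the library and receive
#' \code{NA}; frequencies at or above \code{5e-5} are flagged
#' \code{confident}, in between \code{rare}.
#'
#' @param naive \code{count_table} of the unselected library.
#' @param selected \code{count_table} of a sorted population.
#' @param pseudocount Added to all counts in both conditions (default 0.5).
#' @param alphabet_size See \code{\link{compute_frequencies}}.
#' @param universe Variant universe to score; defaults to the union of
#'   variants seen in either condition.
#' @param replicate Replicate label stored with the table.
#' @return An \code{enrichment_table}: data.frame \code{position, wt_aa,
#'   mut_aa, naive_freq} (raw), \code{log2_ratio, flag} with attributes
#'   \code{selection}, \code{replicate}, \code{pseudocount} and
#'   \code{wt_score} (the recomputed wild-type score, 0).
#' @export
enrichment_ratios <- function(naive, selected, pseudocount = 0.5,
                              alphabet_size = 20L, universe = NULL,
                              replicate = NA_character_) {
  stopifnot(inherits(naive, "count_table"), inherits(selected, "count_table"))
  if (!identical(naive$reference$cds, selected$reference$cds))
    stop("count tables built on different references")
  if (naive$wt_count == 0L || selected$wt_count == 0L)
    stop("wild-type sequence absent from a condition; ",
         "WT normalization is undefined")

  if (is.null(universe)) {
    universe <- unique(rbind(naive$counts[, c("position", "wt_aa", "mut_aa")],
                             selected$counts[, c("position", "wt_aa",
                                                 "mut_aa")]))
    universe <- universe[order(universe$position, universe$mut_aa), ]
    rownames(universe) <- NULL
  }
  fn <- compute_frequencies(naive, pseudocount, alphabet_size, universe)
  fs <- compute_frequencies(selected, pseudocount, alphabet_size, universe)

  posc <- as.character(universe$position)
  wt_n <- attr(fn, "wt_freq")[posc]
  wt_s <- attr(fs, "wt_freq")[posc]
  lr <- log2(fs$freq / fn$freq) - log2(wt_s / wt_n)
  # wild-type's own normalized score, recomputed (identically 0)
  wt_score <- log2(wt_s / wt_n) - log2(wt_s / wt_n)

  raw_naive <- fn$raw_freq
  flag <- ifelse(is.na(raw_naive) | raw_naive < FREQ_ABSENT, "absent",
                 ifelse(raw_naive >= FREQ_CONFIDENT, "confident", "rare"))
  lr[flag == "absent"] <- NA_real_

  out <- data.frame(universe, naive_freq = raw_naive, log2_ratio = lr,
                    flag = flag)
  structure(out,
            class = c("enrichment_table", "data.frame"),
            selection = selected$condition,
            replicate = replicate,
            pseudocount = pseudocount,
            reference = naive$reference$name,
            wt_score = stats::median(wt_score, na.rm = TRUE))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Enrichment table [", attr(x, "selection"),
      if (!is.na(attr(x, "replicate")))
        paste0(", replicate ", attr(x, "replicate")) else "",
      "] on '", attr(x, "reference"), "': ", nrow(x), " variants\n", sep = "")
  print(table(flag = x$flag))
  scored <- x$log2_ratio[!is.na(x$log2_ratio)]
  if (length(scored))
    cat(sprintf("  log2 ratio: median %.2f, range [%.2f, %.2f]\n",
                stats::median(scored), min(scored), max(scored)))
  invisible(x)
}

#' @export
summary.enrichment_table <- function(object, ...) {
  scored <- object[!is.na(object$log2_ratio), ]
  list(selection = attr(object, "selection"),
       replicate = attr(object, "replicate"),
       n_variants = nrow(object),
       flags = table(object$flag),
       quartiles = stats::quantile(scored$log2_ratio,
                                   c(0, .25, .5, .75, 1), na.rm = TRUE))
}

#' Per-residue conservation scores
#'
#' Averages the log2 enrichment ratios of all scored substitutions at each
#' residue position into a mean conservation score: low (negative) scores
#' mark residues intolerant of mutation. Stop substitutions are excluded by
#' default (they conflate nonsense with missense effects). Given several
#' replicates, per-replicate profiles are computed first and then averaged
#' position-wise over the replicates scoring that position.
#'
#' @param x An \code{enrichment_table} or a list of them (replicates).
#' @param exclude_stop Drop \code{mut_aa == "*"} substitutions (default TRUE).
#' @param min_substitutions Positions with fewer scored substitutions are
#'   reported as missing (default 1).
#' @return A \code{conservation_profile}: data.frame \code{position, wt_aa,
#'   score, n_substitutions} (positions with no scored substitutions are
#'   omitted), with attribute \code{replicate_combination = "mean"}.
#' @export
conservation_scores <- function(x, exclude_stop = TRUE,
                                min_substitutions = 1L) {
  if (inherits(x, "enrichment_table")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "enrichment_table")))

  per_rep <- lapply(x, function(et) {
    d <- et[!is.na(et$log2_ratio), , drop = FALSE]
    if (exclude_stop) d <- d[d$mut_aa != "*", , drop = FALSE]
    if (nrow(d) == 0L)
      return(data.frame(position = integer(0), wt_aa = character(0),
                        score = numeric(0), n_substitutions = integer(0)))
    sc <- tapply(d$log2_ratio, d$position, mean)
    ns <- tapply(d$log2_ratio, d$position, length)
    pos <- as.integer(names(sc))
    data.frame(position = pos,
               wt_aa = d$wt_aa[match(pos, d$position)],
               score = as.numeric(sc),
               n_substitutions = as.integer(ns))[ns >= min_substitutions, ]
  })

  if (length(per_rep) == 1L) {
    prof <- per_rep[[1L]]
  } else {
    all_pos <- sort(unique(unlist(lapply(per_rep, `[[`, "position"))))
    score <- rowMeans(do.call(cbind, lapply(per_rep, function(p)
      p$score[match(all_pos, p$position)])), na.rm = TRUE)
    nsub <- apply(do.call(cbind, lapply(per_rep, function(p)
      p$n_substitutions[match(all_pos, p$position)])), 1L, max, na.rm = TRUE)
    wt <- rep(NA_character_, length(all_pos))
    for (p in per_rep) {
      i <- match(p$position, all_pos)
      wt[i] <- p$wt_aa
    }
    prof <- data.frame(position = all_pos, wt_aa = wt, score = score,
                       n_substitutions = as.integer(nsub))
  }
  rownames(prof) <- NULL
  structure(prof, class = c("conservation_profile", "data.frame"),
            replicate_combination = "mean",
            n_replicates = length(x),
            selection = attr(x[[1L]], "selection"))
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile [", attr(x, "selection"), "]: ", nrow(x),
      " residues, ", attr(x, "n_replicates"), " replicate(s)\n", sep = "")
  cat(sprintf("  score: median %.2f, range [%.2f, %.2f]\n",
              stats::median(x$score), min(x$score), max(x$score)))
  invisible(x)
}

#' @export
plot.conservation_profile <- function(x, ...) {
  graphics::plot(x$position, x$score, type = "h",
                 xlab = "residue position", ylab = "mean conservation score",
                 ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Replicate concordance (R-squared)
#'
#' Squared Pearson correlation of log2 enrichment ratios between two
#' replicate sorting experiments. At mutation level, variants scored in both
#' replicates are stratified by naive-library frequency: the
#' \code{confident} stratum contains pairs confident in both replicates; the
#' \code{rare} stratum the remaining scored pairs (rare variants are sampled
#' shallowly during sorting and agree less well). At residue level a single
#' R-squared is computed over mean conservation scores, which average out
#' per-mutation noise and agree better than individual mutations. Pairs with
#' an absent member are excluded throughout; a stratum with fewer than 3
#' pairs is reported as \code{NA}, not 0.
#'
#' @param repA,repB \code{enrichment_table}s of the same selection.
#' @param level \code{"mutation"} or \code{"residue"}.
#' @param exclude_stop Passed to \code{\link{conservation_scores}} at residue
#'   level.
#' @return data.frame \code{stratum, n, r_squared}.
#' @export
replicate_concordance <- function(repA, repB,
                                  level = c("mutation", "residue"),
                                  exclude_stop = TRUE) {
  level <- match.arg(level)
  stopifnot(inherits(repA, "enrichment_table"),
            inherits(repB, "enrichment_table"))
  if (!identical(attr(repA, "selection"), attr(repB, "selection")))
    stop("replicates were scored on different selections")

  r2 <- function(a, b) {
    if (length(a) < 3L) return(NA_real_)
    stats::cor(a, b)^2
  }

  if (level == "residue") {
    pa <- conservation_scores(repA, exclude_stop = exclude_stop)
    pb <- conservation_scores(repB, exclude_stop = exclude_stop)
    m <- merge(pa[, c("position", "score")], pb[, c("position", "score")],
               by = "position", suffixes = c("_a", "_b"))
    return(data.frame(stratum = "residue", n = nrow(m),
                      r_squared = r2(m$score_a, m$score_b)))
  }

  key <- function(d) paste0(d$position, "_", d$mut_aa)
  m <- merge(
    data.frame(key = key(repA), lr_a = repA$log2_ratio, flag_a = repA$flag),
    data.frame(key = key(repB), lr_b = repB$log2_ratio, flag_b = repB$flag),
    by = "key")
  m <- m[!is.na(m$lr_a) & !is.na(m$lr_b), ]
  conf <- m$flag_a == "confident" & m$flag_b == "confident"
  data.frame(
    stratum = c("confident", "rare"),
    n = c(sum(conf), sum(!conf)),
    r_squared = c(r2(m$lr_a[conf], m$lr_b[conf]),
                  r2(m$lr_a[!conf], m$lr_b[!conf])))
}

#' Enrichment heat-map matrix
#'
#' Arranges log2 enrichment ratios as a substitutions-by-positions matrix
#' (the mutational-landscape layout: reference sequence on the horizontal
#' axis, amino-acid substitutions on the vertical axis), clamping scores to
#' \code{[-3, +3]} by default — the display range from strongly depleted to
#' strongly enriched. Missing/absent variants are \code{NA}.
#'
#' @param etab An \code{enrichment_table}.
#' @param clamp Two-sided clamp; use \code{c(-Inf, Inf)} to disable.
#' @param alphabet Row order (default \code{\link{AA20}}).
#' @return Numeric matrix, rows = mutant amino acids, columns = positions
#'   (named \code{<wt><pos>}).
#' @export
enrichment_matrix <- function(etab, clamp = c(-3, 3), alphabet = AA20) {
  stopifnot(inherits(etab, "enrichment_table"))
  pos <- sort(unique(etab$position))
  M <- matrix(NA_real_, nrow = length(alphabet), ncol = length(pos),
              dimnames = list(alphabet, paste0(
                etab$wt_aa[match(pos, etab$position)], pos)))
  ri <- match(etab$mut_aa, alphabet)
  ci <- match(etab$position, pos)
  keep <- !is.na(ri)
  M[cbind(ri[keep], ci[keep])] <- pmin(pmax(etab$log2_ratio[keep],
                                            clamp[1]), clamp[2])
  M
}

#' Export an enrichment heat map
#'
#' Writes the clamped matrix as TSV and optionally renders it to a figure
#' (PNG via \pkg{pheatmap} when available, otherwise base \code{image}),
#' using the depleted-to-enriched colour ramp (orange to dark blue).
#'
#' @param etab An \code{enrichment_table}.
#' @param tsv Output TSV path for the matrix.
#' @param png Optional PNG path for the rendered figure.
#' @param clamp Score clamp, default \code{c(-3, 3)}.
#' @return The matrix, invisibly.
#' @export
export_heatmap <- function(etab, tsv, png = NULL, clamp = c(-3, 3)) {
  M <- enrichment_matrix(etab, clamp = clamp)
  utils::write.table(M, tsv, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(png)) {
    pal <- grDevices::colorRampPalette(
      c("darkorange", "white", "darkblue"))(101)
    grDevices::png(png, width = 1200, height = 600)
    on.exit(grDevices::dev.off())
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                         color = pal, na_col = "black",
                         breaks = seq(clamp[1], clamp[2], length.out = 102))
    } else {
      graphics::image(t(M)[, rev(seq_len(nrow(M)))], col = pal,
                      zlim = clamp, axes = FALSE)
    }
  }
  invisible(M)
}
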