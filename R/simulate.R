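#' Build a single-site saturation mutagenesis (SSM) naive library
#'
#' Enumerates every single amino-acid substitution of the reference protein
#' (one variant per position/mutant pair, mutant distinct from wild type) and
#' assigns each a frequency in the unselected ("naive") plasmid pool. Real
#' naive libraries show large variation in per-mutant frequency; this is
#' emulated by i.i.d. lognormal draws with configurable spread, normalised so
#' that variant frequencies sum to \code{1 - wt_fraction}.
#'
#' @param ref A \code{\link{reference_protein}}.
#' @param alphabet Substitution alphabet; default the 20 canonical amino
#'   acids (\code{\link{AA20}}). Add \code{"*"} to include nonsense variants.
#' @param skew Lognormal sigma of naive frequencies; \code{0} gives a
#'   perfectly uniform library. Default 1.5 (heavily skewed, so a realistic
#'   fraction of variants falls below detection thresholds).
#' @param wt_fraction Fraction of the library that is unmutated wild type.
#' @param seed Integer RNG seed; identical seeds give identical libraries.
#' @return A \code{naive_library}: list with \code{reference},
#'   \code{variants} (data.frame \code{position, wt_aa, mut_aa, freq}),
#'   \code{wt_fraction}, \code{alphabet}.
#' @examples
#' ref <- reference_protein("toy", "ATGGCTTGCGATGAATTTGGTCATATTAAACTG")
#' lib <- build_ssm_library(ref, skew = 1, wt_fraction = 0.2, seed = 1)
#' nrow(lib$variants)  # 11 residues x 19 substitutions
#' @export
build_ssm_library <- function(ref, alphabet = AA20, skew = 1.5,
                              wt_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(ref, "reference_protein"))
  if (length(alphabet) == 0L) stop("alphabet must be nonempty")
  bad <- setdiff(alphabet, c(AA20, "*"))
  if (length(bad))
    stop("alphabet contains unknown codes: ", paste(bad, collapse = ", "))
  if (!is.numeric(skew) || skew < 0) stop("skew must be >= 0")
  if (wt_fraction <= 0 || wt_fraction >= 1)
    stop("wt_fraction must be in (0, 1)")

  pos <- seq_len(ref$length)
  wt <- ref_residue(ref, pos)
  grid <- expand.grid(mut_aa = alphabet, position = pos,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$wt_aa <- wt[grid$position]
  grid <- grid[grid$mut_aa != grid$wt_aa, c("position", "wt_aa", "mut_aa")]
  grid <- grid[order(grid$position, grid$mut_aa), ]
  rownames(grid) <- NULL

  set.seed(seed)
  w <- if (skew == 0) rep(1, nrow(grid)) else
    stats::rlnorm(nrow(grid), meanlog = 0, sdlog = skew)
  grid$freq <- w / sum(w) * (1 - wt_fraction)

  structure(
    list(reference = ref, variants = grid, wt_fraction = wt_fraction,
         alphabet = alphabet, skew = skew, seed = seed),
    class = "naive_library"
  )
}

#' @export
print.naive_library <- function(x, ...) {
  cat("SSM naive library on '", x$reference$name, "': ",
      nrow(x$variants), " variants over ", x$reference$length,
      " residues (alphabet size ", length(x$alphabet), ")\n", sep = "")
  cat(sprintf("  wt fraction %.3g; variant freq range [%.3g, %.3g]\n",
              x$wt_fraction, min(x$variants$freq), max(x$variants$freq)))
  invisible(x)
}

#' Default per-class phenotype effect specification
#'
#' Ground-truth mutation classes for the simulator, mirroring the mutation
#' behaviours seen in BiFC-based receptor scans: \code{neutral} (wild-type
#' like), \code{aggregating} (destabilised protein that self-associates
#' nonspecifically, raising BiFC; expression somewhat reduced),
#' \code{interface} (disrupts the specific dimerisation surface),
#' \code{clustering} (C-terminal tail changes that reduce partitioning into
#' lipid microdomains). Each class gives the multipliers applied to the four
#' phenotype channels; a class is sized either by \code{prop} (fraction of
#' variants, assigned pseudo-randomly) or by \code{positions} (all variants
#' at the listed residues).
#'
#' @param aggregating_prop,interface_positions,clustering_positions Optional
#'   overrides for class sizes/placement; \code{NULL} keeps defaults.
#' @return Named list of class definitions, each a list with optional
#'   \code{prop} or \code{positions} plus \code{expr}, \code{dimer},
#'   \code{clust}, \code{agg} multipliers.
#' @export
default_effect_spec <- function(aggregating_prop = 0.08,
                                interface_positions = NULL,
                                clustering_positions = NULL) {
  spec <- list(
    aggregating = list(prop = aggregating_prop,
                       expr = 0.7, dimer = 0.5, clust = 1, agg = 5),
    interface   = list(prop = 0.06, expr = 1, dimer = 0.15, clust = 1, agg = 0),
    clustering  = list(prop = 0.03, expr = 1, dimer = 1, clust = 0.2, agg = 0),
    neutral     = list(prop = NA_real_, expr = 1, dimer = 1, clust = 1, agg = 0)
  )
  if (!is.null(interface_positions)) {
    spec$interface$prop <- NULL
    spec$interface$positions <- interface_positions
  }
  if (!is.null(clustering_positions)) {
    spec$clustering$prop <- NULL
    spec$clustering$positions <- clustering_positions
  }
  spec
}

#' Assign ground-truth phenotypes to library variants
#'
#' Gives every variant an expression multiplier (\code{expr}), a specific
#' dimerisation factor (\code{dimer}), a microdomain-clustering factor
#' (\code{clust}) and an aggregation propensity (\code{agg}); wild type is
#' \code{expr = dimer = clust = 1, agg = 0}. A cell's simulated BiFC signal is
#' \code{expr * (alpha*dimer + beta*clust + gamma*agg)} times lognormal noise,
#' so the three association mechanisms (specific dimerisation, clustering into
#' lipid microdomains, nonspecific aggregation) contribute additively with
#' global weights.
#'
#' Classes with explicit \code{positions} claim all variants at those
#' residues; classes with \code{prop} then claim pseudo-random subsets of the
#' remaining variants, with counts fixed deterministically
#' (\code{round(prop * n)} via largest remainder); everything left is the
#' fallback class (the one whose \code{prop} is \code{NA}).
#'
#' @param lib A \code{naive_library}.
#' @param effect_spec Class definitions, see \code{\link{default_effect_spec}}.
#' @param alpha,beta,gamma Nonnegative global weights of the dimer, clustering
#'   and aggregation terms in the BiFC signal.
#' @param cv_noise Lognormal cell-to-cell coefficient of variation applied
#'   independently to the expression and BiFC channels. Default 0.5.
#' @param by \code{"variant"} draws class membership independently per
#'   variant; \code{"residue"} draws it per residue position, all
#'   substitutions at a residue sharing the class — mutational effects tied
#'   to structural location (an interface surface, a tail modification
#'   site) are positional, which \code{"residue"} emulates.
#' @param seed Integer RNG seed for the class assignment.
#' @return A \code{phenotype_params}: data.frame of per-variant
#'   \code{position, wt_aa, mut_aa, class, expr, dimer, clust, agg} with
#'   attributes \code{alpha}, \code{beta}, \code{gamma}, \code{cv_noise}.
#' @export
assign_phenotypes <- function(lib, effect_spec = default_effect_spec(),
                              alpha = 1, beta = 1, gamma = 1,
                              cv_noise = 0.5, by = c("variant", "residue"),
                              seed = 1L) {
  by <- match.arg(by)
  stopifnot(inherits(lib, "naive_library"))
  if (any(c(alpha, beta, gamma) < 0) || cv_noise < 0)
    stop("alpha, beta, gamma, cv_noise must be nonnegative")
  needed <- c("expr", "dimer", "clust", "agg")
  for (nm in names(effect_spec)) {
    cls <- effect_spec[[nm]]
    if (!all(needed %in% names(cls)))
      stop("effect class '", nm, "' must define ",
           paste(needed, collapse = ", "))
    if (any(unlist(cls[needed]) < 0, na.rm = TRUE))
      stop("effect class '", nm, "' has negative phenotype parameters")
  }

  v <- lib$variants
  n <- nrow(v)
  cls_of <- rep(NA_character_, n)

  # positional classes first
  for (nm in names(effect_spec)) {
    p <- effect_spec[[nm]]$positions
    if (!is.null(p)) {
      if (any(!p %in% v$position))
        stop("class '", nm, "' names positions outside the library")
      cls_of[v$position %in% p] <- nm
    }
  }

  props <- vapply(effect_spec, function(cl)
    if (is.null(cl$prop)) NA_real_ else cl$prop, numeric(1))
  fallback <- names(effect_spec)[is.na(props) &
                                 vapply(effect_spec, function(cl)
                                   is.null(cl$positions), logical(1))]
  if (length(fallback) != 1L)
    stop("exactly one class must have prop = NA (the fallback class)")
  prop_cls <- setdiff(names(effect_spec)[!is.na(props)], fallback)

  # units to apportion: individual variants, or whole residues
  if (by == "variant") {
    free <- which(is.na(cls_of))
  } else {
    free <- sort(unique(v$position[is.na(cls_of)]))
  }
  if (length(prop_cls)) {
    # largest-remainder apportionment of round(prop * total units)
    n_units <- if (by == "variant") n else length(unique(v$position))
    target <- props[prop_cls] * n_units
    k <- floor(target)
    rem <- target - k
    extra <- sum(round(target)) - sum(k)
    if (extra > 0)
      k[order(rem, decreasing = TRUE)[seq_len(extra)]] <- k[order(rem, decreasing = TRUE)[seq_len(extra)]] + 1L
    if (sum(k) > length(free))
      stop("class proportions exceed available variants")
    set.seed(seed)
    shuffled <- sample(free)
    off <- 0L
    for (i in seq_along(prop_cls)) {
      if (k[i] > 0) {
        units <- shuffled[(off + 1L):(off + k[i])]
        if (by == "variant") cls_of[units] <- prop_cls[i]
        else cls_of[v$position %in% units & is.na(cls_of)] <- prop_cls[i]
        off <- off + as.integer(k[i])
      }
    }
  }
  cls_of[is.na(cls_of)] <- fallback

  for (nm in needed)
    v[[nm]] <- vapply(cls_of, function(cl) effect_spec[[cl]][[nm]], numeric(1))
  v$class <- cls_of
  v$freq <- NULL
  structure(v, class = c("phenotype_params", "data.frame"),
            alpha = alpha, beta = beta, gamma = gamma, cv_noise = cv_noise)
}

#' Sorting experiment specification
#'
#' @param n_cells Number of cells run through the sorter. Default 1e5.
#' @param expr_gate Either \code{"wt"} (fixed threshold at the 5th percentile
#'   of a wild-type cell's expression-signal distribution, so essentially all
#'   wild-type cells pass) or a numeric quantile in (0,1): the fraction of
#'   all cells, ranked by expression signal, that passes.
#' @param bifc_top_fraction Fraction of expression-gated cells collected in
#'   the high-BiFC gate, ranked by BiFC signal relative to expression.
#'   Default 0.05 (the "top 5 percent" gate).
#' @param n_reads Sequencing reads drawn per sorted condition. Default 1e6.
#' @param read_error_rate Per-base substitution error rate for emitted reads.
#' @param gate_statistic \code{"ratio"} gates on BiFC/expression (default,
#'   matching gating on BiFC signal relative to surface expression);
#'   \code{"bifc"} gates on raw BiFC signal.
#' @return A \code{sort_spec} list.
#' @export
sort_spec <- function(n_cells = 1e5, expr_gate = "wt",
                      bifc_top_fraction = 0.05, n_reads = 1e6,
                      read_error_rate = 0,
                      gate_statistic = c("ratio", "bifc")) {
  gate_statistic <- match.arg(gate_statistic)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be a positive integer")
  if (bifc_top_fraction <= 0 || bifc_top_fraction >= 1)
    stop("bifc_top_fraction must be in (0, 1)")
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (read_error_rate < 0) stop("read_error_rate must be >= 0")
  if (is.numeric(expr_gate) && (expr_gate <= 0 || expr_gate >= 1))
    stop("numeric expr_gate must be a quantile in (0, 1)")
  structure(list(n_cells = n_cells, expr_gate = expr_gate,
                 bifc_top_fraction = bifc_top_fraction,
                 n_reads = as.integer(n_reads),
                 read_error_rate = read_error_rate,
                 gate_statistic = gate_statistic),
            class = "sort_spec")
}

# lognormal noise with mean 1 and coefficient of variation cv
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one FACS sort of an SSM library
#'
#' Assigns each cell a single genotype by a multinomial draw from the naive
#' library (cells express at most one library member, preserving the
#' genotype-phenotype link), computes per-cell expression and BiFC signals
#' with independent lognormal noise, applies the expression gate and then a
#' rank-based top-fraction BiFC gate within it, and finally samples
#' sequencing reads multinomially from each condition's cell pool.
#'
#' Per cell, expression signal \code{E = expr * noise_E} and BiFC signal
#' \code{B = expr * (alpha*dimer + beta*clust + gamma*agg) * noise_B}. The
#' BiFC gate takes exactly \code{round(bifc_top_fraction * n_gated)} cells,
#' ranked by \code{B/E} (or raw \code{B}, see \code{\link{sort_spec}}).
#'
#' @param lib A \code{naive_library}.
#' @param phen A \code{phenotype_params} over the same variants.
#' @param sort A \code{\link{sort_spec}}.
#' @param seed Integer RNG seed; all draws are reproducible.
#' @param keep_cells Keep the per-cell genotype/signal/gate table in the
#'   result (memory permitting); useful for diagnostics and small fixtures.
#' @return A \code{sort_sim}: list with \code{cells} (per-variant cell counts
#'   per condition: naive, expression, bifc), \code{reads} (per-variant read
#'   counts per condition), \code{wt_*} counts, \code{gate} sizes, and the
#'   inputs. Row order of count tables matches \code{lib$variants}.
#' @export
simulate_sort <- function(lib, phen, sort = sort_spec(), seed = 1L,
                          keep_cells = FALSE) {
  stopifnot(inherits(lib, "naive_library"),
            inherits(phen, "phenotype_params"),
            inherits(sort, "sort_spec"))
  v <- lib$variants
  if (nrow(phen) != nrow(v) ||
      !all(phen$position == v$position & phen$mut_aa == v$mut_aa))
    stop("phenotypes and library cover different variant sets")
  alpha <- attr(phen, "alpha"); beta <- attr(phen, "beta")
  gamma <- attr(phen, "gamma"); cv <- attr(phen, "cv_noise")

  set.seed(seed)
  # genotype index 0 = WT, 1..n = variants
  probs <- c(lib$wt_fraction, v$freq)
  geno <- sample.int(nrow(v) + 1L, sort$n_cells, replace = TRUE,
                     prob = probs) - 1L

  expr <- c(1, phen$expr)[geno + 1L]
  assoc <- c(alpha + beta, alpha * phen$dimer + beta * phen$clust +
               gamma * phen$agg)[geno + 1L]
  E <- expr * .rlnorm_cv(sort$n_cells, cv)
  B <- expr * assoc * .rlnorm_cv(sort$n_cells, cv)

  if (identical(sort$expr_gate, "wt")) {
    sdlog <- if (cv == 0) 0 else sqrt(log(1 + cv^2))
    thr <- stats::qlnorm(0.05, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    in_expr <- E >= thr
  } else {
    thr <- stats::quantile(E, 1 - sort$expr_gate, names = FALSE)
    in_expr <- E >= thr
  }
  n_expr <- sum(in_expr)
  if (n_expr == 0L) stop("expression gate is empty")

  stat <- if (sort$gate_statistic == "ratio") B / E else B
  k <- round(sort$bifc_top_fraction * n_expr)
  if (k == 0L) stop("BiFC gate is empty (too few expression-gated cells)")
  idx_expr <- which(in_expr)
  ord <- idx_expr[order(stat[idx_expr], decreasing = TRUE)]
  idx_bifc <- ord[seq_len(k)]
  in_bifc <- logical(sort$n_cells)
  in_bifc[idx_bifc] <- TRUE

  tab <- function(sel) tabulate(geno[sel][geno[sel] > 0L], nbins = nrow(v))
  cells <- data.frame(v[, c("position", "wt_aa", "mut_aa")],
                      naive = tab(rep(TRUE, sort$n_cells)),
                      expression = tab(in_expr),
                      bifc = tab(in_bifc))
  wt_cells <- c(naive = sum(geno == 0L),
                expression = sum(geno == 0L & in_expr),
                bifc = sum(geno == 0L & in_bifc))

  reads <- cells[, c("position", "wt_aa", "mut_aa")]
  wt_reads <- c(naive = 0L, expression = 0L, bifc = 0L)
  for (cond in c("naive", "expression", "bifc")) {
    pool <- c(wt_cells[[cond]], cells[[cond]])
    if (sum(pool) == 0L) stop("condition '", cond, "' has no cells")
    draw <- as.vector(stats::rmultinom(1L, sort$n_reads, prob = pool))
    wt_reads[[cond]] <- draw[1L]
    reads[[cond]] <- draw[-1L]
  }

  out <- list(cells = cells, wt_cells = wt_cells,
              reads = reads, wt_reads = wt_reads,
              gate = c(n_cells = sort$n_cells, expression = n_expr,
                       rejected = sort$n_cells - n_expr, bifc = k),
              expr_threshold = thr,
              lib = lib, phen = phen, sort = sort, seed = seed)
  if (keep_cells)
    out$cell_table <- data.frame(genotype = geno, E = E, B = B, stat = stat,
                                 in_expr = in_expr, in_bifc = in_bifc)
  class(out) <- "sort_sim"
  out
}

#' @export
print.sort_sim <- function(x, ...) {
  g <- x$gate
  cat("Simulated sort: ", g[["n_cells"]], " cells -> ",
      g[["expression"]], " in expression gate (",
      sprintf("%.1f%%", 100 * g[["expression"]] / g[["n_cells"]]), ") -> ",
      g[["bifc"]], " in BiFC gate (",
      sprintf("%.1f%%", 100 * g[["bifc"]] / g[["expression"]]),
      " of gated)\n", sep = "")
  cat("  ", x$sort$n_reads, " reads per condition; ",
      nrow(x$cells), " variants\n", sep = "")
  invisible(x)
}

#' Default overlapping amplicon fragments for a CDS
#'
#' Receptor cDNA is typically amplified as three overlapping fragments to
#' cover the full gene with short-read sequencing; this builds \code{n}
#' codon-aligned, equally sized fragments with roughly 10 codons of overlap.
#'
#' @param ref A \code{reference_protein}.
#' @param n Number of fragments (default 3).
#' @param overlap_codons Codons of overlap between neighbours (default 10).
#' @return List of integer vectors \code{c(start, end)}, 1-based nucleotide
#'   coordinates in the CDS, codon-aligned.
#' @export
default_fragments <- function(ref, n = 3L, overlap_codons = 10L) {
  L <- ref$length
  if (n == 1L) return(list(c(1L, 3L * L)))
  core <- ceiling(L / n)
  frags <- vector("list", n)
  for (i in seq_len(n)) {
    a <- max(1L, (i - 1L) * core + 1L - overlap_codons %/% 2L)
    b <- min(L, i * core + overlap_codons %/% 2L)
    frags[[i]] <- as.integer(c(3 * (a - 1) + 1, 3 * b))
  }
  frags
}

.check_fragments <- function(frags, ref) {
  for (fr in frags) {
    if (length(fr) != 2L || fr[1] < 1L || fr[2] > 3L * ref$length ||
        fr[1] > fr[2])
      stop("fragment coordinates out of CDS range")
    if ((fr[1] - 1L) %% 3L != 0L || fr[2] %% 3L != 0L)
      stop("fragments must be codon-aligned (start 3k+1, end 3k)")
  }
  cov <- rep(FALSE, 3L * ref$length)
  for (fr in frags) cov[fr[1]:fr[2]] <- TRUE
  if (!all(cov)) stop("fragments do not tile the CDS")
  invisible(frags)
}

# codons (residue positions) fully covered by a fragment
.frag_positions <- function(fr) ((fr[1] - 1L) %/% 3L + 1L):(fr[2] %/% 3L)

#' Emit simulated FASTQ reads for sorted conditions
#'
#' Converts per-condition read counts into FASTQ files, one per condition.
#' Each read covers one amplicon fragment of the CDS; a variant read carries
#' the fixed mutant codon for its amino-acid change
#' (\code{\link{mutant_codon}}), and every base is independently substituted
#' at \code{error_rate}. A variant's reads are spread over the fragments
#' containing its codon (round-robin); wild-type reads are spread over all
#' fragments. Read headers carry \code{frag=<i>} so callers can identify the
#' fragment without alignment. Quality is fixed at Phred "I".
#'
#' @param sim A \code{sort_sim}, or a list with elements \code{reads}
#'   (data.frame with position/wt_aa/mut_aa plus one count column per
#'   condition) and \code{wt_reads} (named vector).
#' @param fragments List of codon-aligned CDS intervals; default
#'   \code{\link{default_fragments}} of the simulation's reference.
#' @param error_rate Per-base substitution rate; default the sort spec's.
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed (errors and fragment assignment).
#' @return Named character vector of FASTQ paths, one per condition.
#' @export
emit_reads <- function(sim, fragments = NULL, error_rate = NULL,
                       dir = tempfile("fastq"), seed = 1L) {
  stopifnot(inherits(sim, "sort_sim"))
  ref <- sim$lib$reference
  if (is.null(fragments)) fragments <- default_fragments(ref)
  .check_fragments(fragments, ref)
  if (is.null(error_rate)) error_rate <- sim$sort$read_error_rate
  if (error_rate < 0) stop("error_rate must be >= 0")

  v <- sim$reads
  # every variant codon must be covered by >= 1 fragment
  covered <- lapply(fragments, .frag_positions)
  frag_of_pos <- lapply(seq_len(ref$length), function(p)
    which(vapply(covered, function(cp) p %in% cp, logical(1))))
  if (any(lengths(frag_of_pos) == 0L))
    stop("some residue positions are covered by no fragment")

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  paths <- character(0)

  conds <- c("naive", "expression", "bifc")
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    # reseed per condition so each file is reproducible on its own
    set.seed(seed + ci)
    seq_chunks <- list()
    frag_chunks <- list()
    # wild-type reads: round-robin over all fragments
    nwt <- sim$wt_reads[[cond]]
    if (nwt > 0) {
      fi <- rep(seq_along(fragments), length.out = nwt)
      for (i in seq_along(fragments)) {
        ni <- sum(fi == i)
        if (ni > 0) {
          fr <- fragments[[i]]
          seq_chunks[[length(seq_chunks) + 1L]] <-
            rep(substr(ref$cds, fr[1], fr[2]), ni)
          frag_chunks[[length(frag_chunks) + 1L]] <- rep(i, ni)
        }
      }
    }
    # variant reads
    nz <- which(v[[cond]] > 0L)
    for (j in nz) {
      pos <- v$position[j]
      cnt <- v[[cond]][j]
      fis <- rep(frag_of_pos[[pos]], length.out = cnt)
      mc <- mutant_codon(v$mut_aa[j])
      for (i in unique(fis)) {
        ni <- sum(fis == i)
        fr <- fragments[[i]]
        s <- substr(ref$cds, fr[1], fr[2])
        off <- 3L * (pos - 1L) + 1L - fr[1]  # 0-based offset in fragment
        substr(s, off + 1L, off + 3L) <- mc
        seq_chunks[[length(seq_chunks) + 1L]] <- rep(s, ni)
        frag_chunks[[length(frag_chunks) + 1L]] <- rep(i, ni)
      }
    }
    seqs <- unlist(seq_chunks, use.names = FALSE)
    frag_ids <- unlist(frag_chunks, use.names = FALSE)
    if (length(seqs) == 0L) stop("no reads to emit for condition '", cond, "'")

    # shuffle reads deterministically, then inject sequencing errors
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]; frag_ids <- frag_ids[ord]
    if (error_rate > 0) {
      nerr <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
      for (r in which(nerr > 0L)) {
        ch <- strsplit(seqs[r], "")[[1L]]
        hit <- sample.int(length(ch), nerr[r])
        for (h in hit) {
          alt <- setdiff(bases, ch[h])
          ch[h] <- alt[sample.int(3L, 1L)]
        }
        seqs[r] <- paste(ch, collapse = "")
      }
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- sprintf("%s_read%06d frag=%d cond=%s",
                          ref$name, seq_along(seqs), frag_ids, cond)
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(w)
      strrep("I", w), character(1)))
    fp <- file.path(dir, paste0(cond, ".fastq"))
    Biostrings::writeXStringSet(dna, fp, format = "fastq", qualities = qual)
    paths[cond] <- fp
  }
  attr(paths, "fragments") <- fragments
  paths
}
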