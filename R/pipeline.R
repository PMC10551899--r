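#' Simulate a complete replicated BiFC sort-seq scan and score it
#'
#' End-to-end convenience wrapper around the pipeline: builds (or reuses) an
#' SSM naive library with ground-truth phenotypes, simulates independent
#' replicate sorting experiments (each with its own cells, gates and read
#' sampling), and scores wild-type-normalized enrichment per replicate for
#' both the expression and high-BiFC selections. Counting here goes directly
#' from the simulator's read counts (see \code{\link{sim_count_table}});
#' FASTQ emission and codon calling are exercised separately.
#'
#' @param ref A \code{reference_protein}.
#' @param effect_spec Ground-truth class spec
#'   (\code{\link{default_effect_spec}}).
#' @param sort A \code{\link{sort_spec}}.
#' @param n_replicates Number of independent sorts (default 2).
#' @param skew,wt_fraction Library parameters
#'   (\code{\link{build_ssm_library}}).
#' @param assign_by Class assignment unit for \code{\link{assign_phenotypes}}:
#'   \code{"variant"} or \code{"residue"}.
#' @param pseudocount Scoring pseudocount (default 0.5).
#' @param seed Integer seed; replicate r uses \code{seed + r} for its sort.
#' @return A \code{dms_scan} list: \code{lib}, \code{phen} (ground truth),
#'   \code{sims} (per-replicate \code{sort_sim}s), \code{bifc} and
#'   \code{expression} (lists of per-replicate \code{enrichment_table}s).
#' @examples
#' ref <- reference_protein("toy",
#'   paste0("ATG", strrep("GCTTGCGATGAATTTGGTCATATTAAACTGATG", 1)))
#' scan <- simulate_scan(ref, sort = sort_spec(n_cells = 2e4, n_reads = 2e4),
#'                       seed = 7)
#' conservation_scores(scan$bifc)
#' @export
simulate_scan <- function(ref, effect_spec = default_effect_spec(),
                          sort = sort_spec(), n_replicates = 2L,
                          skew = 1.5, wt_fraction = 0.1,
                          assign_by = "variant",
                          pseudocount = 0.5, seed = 1L) {
  lib <- build_ssm_library(ref, skew = skew, wt_fraction = wt_fraction,
                           seed = seed)
  phen <- assign_phenotypes(lib, effect_spec, by = assign_by, seed = seed)

  sims <- lapply(seq_len(n_replicates), function(r)
    simulate_sort(lib, phen, sort, seed = seed + r))

  score <- function(sim, cond, r) {
    enrichment_ratios(sim_count_table(sim, "naive"),
                      sim_count_table(sim, cond),
                      pseudocount = pseudocount,
                      universe = lib$variants[, c("position", "wt_aa",
                                                  "mut_aa")],
                      replicate = as.character(r))
  }
  bifc <- lapply(seq_len(n_replicates), function(r)
    score(sims[[r]], "bifc", r))
  expression <- lapply(seq_len(n_replicates), function(r)
    score(sims[[r]], "expression", r))

  structure(list(lib = lib, phen = phen, sims = sims,
                 bifc = bifc, expression = expression, seed = seed),
            class = "dms_scan")
}

#' @export
print.dms_scan <- function(x, ...) {
  cat("Simulated DMS scan on '", x$lib$reference$name, "': ",
      nrow(x$lib$variants), " variants, ", length(x$sims),
      " replicate sort(s)\n", sep = "")
  cat("  ground-truth classes: ",
      paste(names(table(x$phen$class)), table(x$phen$class),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate aggregation calls against simulator ground truth
#'
#' Precision and recall of predicted aggregating mutations against the
#' planted \code{"aggregating"} class labels of a simulated scan.
#'
#' @param calls An \code{aggregation_calls} object.
#' @param phen The scan's \code{phenotype_params} (ground truth).
#' @return List with \code{precision}, \code{recall}, \code{tp}, \code{fp},
#'   \code{fn}.
#' @export
evaluate_calls <- function(calls, phen) {
  stopifnot(inherits(calls, "aggregation_calls"),
            inherits(phen, "phenotype_params"))
  key <- function(d) paste0(d$position, "_", d$mut_aa)
  truth <- key(phen[phen$class == "aggregating", ])
  pred <- key(calls$predicted)
  tp <- sum(pred %in% truth)
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       tp = tp, fp = length(pred) - tp, fn = length(truth) - tp)
}
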