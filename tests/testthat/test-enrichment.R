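test_that("frequencies follow the per-position depth convention", {
  ref <- toy_ref()
  # pseudocount 0: 50 variant reads over depth 50 + 950 -> 0.05
  tb <- make_counts(ref, list(list(2, "T", 50)), wt_count = 950)
  f <- compute_frequencies(tb, pseudocount = 0)
  expect_equal(f$freq, 0.05)
  expect_equal(f$raw_freq, 0.05)

  # pseudocount 0.5 on a 3-variant fixture matches hand arithmetic
  tb3 <- make_counts(ref, list(list(2, "T", 10), list(2, "W", 0),
                               list(5, "A", 4)), wt_count = 86)
  f3 <- compute_frequencies(tb3, pseudocount = 0.5)
  # position 2 depth: 10 + 0 + 86 = 96; position 5 depth: 4 + 86 = 90
  expect_equal(f3$freq[f3$position == 2 & f3$mut_aa == "T"],
               10.5 / (96 + 10))
  expect_equal(f3$freq[f3$position == 2 & f3$mut_aa == "W"],
               0.5 / (96 + 10))
  expect_equal(f3$freq[f3$position == 5], 4.5 / (90 + 10))

  # zero depth at a position yields NA, not a division by zero
  wd <- c(rep(100, 4), 0, rep(100, 5)); names(wd) <- as.character(1:10)
  tb0 <- make_counts(ref, list(list(5, "T", 0)), wt_count = 100,
                     coverage = wd)
  f0 <- compute_frequencies(tb0, pseudocount = 0.5)
  expect_true(is.na(f0$raw_freq))
})

test_that("enrichment ratios are WT-normalized with the stated identities", {
  ref <- toy_ref()
  # variant enriched 4-fold while WT is unchanged -> log2 ratio exactly 2
  naive <- make_counts(ref, list(list(2, "T", 100)), wt_count = 9900,
                       condition = "naive")
  sel <- make_counts(ref, list(list(2, "T", 400)), wt_count = 9900,
                     condition = "bifc")
  et <- enrichment_ratios(naive, sel, pseudocount = 0)
  expect_equal(et$log2_ratio,
               log2((400 / 10300) / (100 / 10000)) -
                 log2((9900 / 10300) / (9900 / 10000)))
  expect_equal(et$log2_ratio, 2, tolerance = 0.03)

  # unchanged frequencies -> exactly 0; WT's own score is exactly 0
  et0 <- enrichment_ratios(naive, naive, pseudocount = 0.5)
  expect_equal(et0$log2_ratio, 0)
  expect_identical(attr(et0, "wt_score"), 0)

  # WT missing from a condition is a hard error
  expect_error(enrichment_ratios(
    make_counts(ref, list(list(2, "T", 5)), wt_count = 0), sel), "WT")
})

test_that("flags partition variants by raw naive frequency", {
  ref <- toy_ref()
  naive <- make_counts(ref, list(list(2, "T", 60),    # 6e-5 confident
                                 list(3, "W", 10),    # 1e-5 rare
                                 list(5, "A", 0)),    # absent
                       wt_count = 999930, condition = "naive")
  sel <- make_counts(ref, list(list(2, "T", 50), list(3, "W", 50),
                               list(5, "A", 50)), wt_count = 10000,
                     condition = "bifc")
  et <- enrichment_ratios(naive, sel)
  expect_equal(et$flag[et$position == 2], "confident")
  expect_equal(et$flag[et$position == 3], "rare")
  expect_equal(et$flag[et$position == 5], "absent")
  expect_true(is.na(et$log2_ratio[et$flag == "absent"]))
  expect_false(anyNA(et$log2_ratio[et$flag != "absent"]))
  # every variant carries exactly one flag
  expect_true(all(et$flag %in% c("confident", "rare", "absent")))
})

test_that("scores match spreadsheet-style hand computation on a small fixture", {
  ref <- toy_ref()
  pc <- 0.5; A <- 20
  spec_n <- list(list(2, "T", 40), list(2, "W", 10), list(7, "K", 25))
  spec_s <- list(list(2, "T", 80), list(2, "W", 5), list(7, "K", 25))
  naive <- make_counts(ref, spec_n, wt_count = 1000, condition = "naive")
  sel <- make_counts(ref, spec_s, wt_count = 900, condition = "bifc")
  et <- enrichment_ratios(naive, sel, pseudocount = pc)

  hand <- function(cn, cs, dn, ds) {
    fn <- (cn + pc) / (dn + A * pc); fs <- (cs + pc) / (ds + A * pc)
    wn <- (1000 + pc) / (dn + A * pc); ws <- (900 + pc) / (ds + A * pc)
    log2(fs / fn) - log2(ws / wn)
  }
  # position 2 depth: naive 40+10+1000, selected 80+5+900
  expect_equal(et$log2_ratio[et$position == 2 & et$mut_aa == "T"],
               hand(40, 80, 1050, 985))
  expect_equal(et$log2_ratio[et$position == 2 & et$mut_aa == "W"],
               hand(10, 5, 1050, 985))
  expect_equal(et$log2_ratio[et$position == 7],
               hand(25, 25, 1025, 925))
})

test_that("conservation scores average scored substitutions per residue", {
  ref <- toy_ref()
  # hand-built enrichment table via the constructor path
  naive <- make_counts(ref, list(list(2, "T", 100), list(2, "W", 100),
                                 list(2, "K", 100)), wt_count = 1e4,
                       condition = "naive")
  sel <- make_counts(ref, list(list(2, "T", 100), list(2, "W", 100),
                               list(2, "K", 100)), wt_count = 1e4,
                     condition = "bifc")
  et <- enrichment_ratios(naive, sel)
  et$log2_ratio <- c(-3, -1, 1)  # planted substitution scores
  cp <- conservation_scores(et)
  expect_equal(cp$score, -1)
  expect_equal(cp$n_substitutions, 3L)

  # all-zero substitutions -> score 0
  et$log2_ratio <- c(0, 0, 0)
  expect_equal(conservation_scores(et)$score, 0)

  # stop substitutions excluded by default, included on request
  et2 <- et
  et2$mut_aa <- c("T", "W", "*")
  et2$log2_ratio <- c(-2, -2, 10)
  expect_equal(conservation_scores(et2)$score, -2)
  expect_equal(conservation_scores(et2, exclude_stop = FALSE)$score, 2)

  # replicate combination: mean of per-replicate profiles
  eta <- et; eta$log2_ratio <- c(-2, -2, -2)
  etb <- et; etb$log2_ratio <- c(0, 0, 0)
  expect_equal(conservation_scores(list(eta, etb))$score, -1)
})

test_that("null simulation gives mean confident enrichment near zero", {
  # cells sized so the BiFC gate holds ~20 cells for a variant at the
  # confidence threshold; read depth is then the stated 1e6
  ref <- toy_ref()
  spec0 <- list(neutral = list(prop = NA, expr = 1, dimer = 1, clust = 1,
                               agg = 0))
  scan <- simulate_scan(ref, effect_spec = spec0,
                        sort = sort_spec(n_cells = 8e6, n_reads = 1e6),
                        n_replicates = 1L, seed = 17)
  et <- scan$bifc[[1]]
  conf <- et$log2_ratio[et$flag == "confident"]
  expect_gt(length(conf), 100)
  expect_lt(abs(mean(conf)), 0.1)
})

test_that("replicate concordance behaves at the identity and null extremes", {
  ref <- toy_ref()
  scan <- simulate_scan(ref, sort = sort_spec(n_cells = 2e4, n_reads = 1e5),
                        seed = 5)
  a <- scan$bifc[[1]]

  # identical replicates: R^2 = 1 everywhere defined
  cc <- replicate_concordance(a, a)
  expect_equal(cc$r_squared[cc$n >= 3], rep(1, sum(cc$n >= 3)))
  ccr <- replicate_concordance(a, a, level = "residue")
  expect_equal(ccr$r_squared, 1)

  # independent noise: R^2 near 0
  b <- a
  set.seed(99)
  b$log2_ratio <- stats::rnorm(nrow(b))
  cc0 <- replicate_concordance(a, b)
  n <- cc0$n[cc0$stratum == "confident"]
  expect_lt(cc0$r_squared[cc0$stratum == "confident"], (3 / sqrt(n))^2 + 0.05)

  # under-filled strata are undefined, not zero
  tiny <- a[1:2, ]
  class(tiny) <- class(a)
  attr(tiny, "selection") <- attr(a, "selection")
  expect_true(is.na(replicate_concordance(tiny, tiny)$r_squared[2]))
})

test_that("deeper sequencing improves confident-stratum concordance", {
  ref <- mid_ref()
  deep <- simulate_scan(ref, sort = sort_spec(n_cells = 1e6, n_reads = 1e6),
                        assign_by = "residue", seed = 21)
  shallow <- simulate_scan(ref, sort = sort_spec(n_cells = 1e6, n_reads = 1e4),
                           assign_by = "residue", seed = 21)
  r2 <- function(scan) {
    cc <- replicate_concordance(scan$bifc[[1]], scan$bifc[[2]])
    cc$r_squared[cc$stratum == "confident"]
  }
  expect_gt(r2(deep), r2(shallow))
})

test_that("residue averaging beats mutation scores under iid per-mutation noise", {
  # synthetic replicate pair: per-residue true effects, iid noise per mutation
  ref <- toy_ref()
  muts <- c("T", "W", "Q", "R", "S", "V")
  spec <- unlist(lapply(2:10, function(p)
    lapply(muts, function(m) list(p, m, 100))), recursive = FALSE)
  naive <- make_counts(ref, spec, wt_count = 1e4, condition = "naive")
  sel <- make_counts(ref, spec, wt_count = 1e4, condition = "bifc")
  et <- enrichment_ratios(naive, sel)
  stopifnot(identical(et$position, rep(2:10, each = length(muts))))
  for (s in 1:5) {
    set.seed(100 + s)
    a <- et; b <- et
    eff <- rep(stats::rnorm(9, sd = 2), each = length(muts))
    a$log2_ratio <- eff + stats::rnorm(nrow(et), sd = 1)
    b$log2_ratio <- eff + stats::rnorm(nrow(et), sd = 1)
    mut <- stats::cor(a$log2_ratio, b$log2_ratio)^2
    res <- replicate_concordance(a, b, level = "residue")$r_squared
    expect_gte(res, mut)
  }
})

test_that("heat-map matrix clamps to [-3, 3] and preserves layout", {
  ref <- toy_ref()
  naive <- make_counts(ref, list(list(2, "T", 100), list(5, "W", 100)),
                       wt_count = 1e4, condition = "naive")
  sel <- make_counts(ref, list(list(2, "T", 100), list(5, "W", 100)),
                     wt_count = 1e4, condition = "bifc")
  et <- enrichment_ratios(naive, sel)
  et$log2_ratio <- c(-5, 4)
  M <- enrichment_matrix(et)
  expect_equal(M["T", "A2"], -3)   # clamped from -5
  expect_equal(M["W", "E5"], 4 * 0 + 3)  # clamped from 4
  expect_equal(sum(!is.na(M)), 2L)
  # clamping is idempotent
  expect_equal(pmin(pmax(M, -3), 3), M)

  tsv <- tempfile(fileext = ".tsv")
  M2 <- export_heatmap(et, tsv)
  expect_true(file.exists(tsv))
  back <- as.matrix(read.delim(tsv, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(M2))
})
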