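test_that("SSM library enumerates every substitution with valid frequencies", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, skew = 1, wt_fraction = 0.1, seed = 1)
  expect_equal(nrow(lib$variants), 10L * 19L)
  expect_false(any(lib$variants$mut_aa == lib$variants$wt_aa))
  expect_true(all(lib$variants$freq >= 0))
  expect_equal(sum(lib$variants$freq) + lib$wt_fraction, 1, tolerance = 1e-9)

  # zero skew degenerates to a perfectly uniform library
  flat <- build_ssm_library(ref, skew = 0, wt_fraction = 0.1, seed = 1)
  expect_equal(flat$variants$freq, rep(0.9 / 190, 190))

  # identical seeds give identical libraries (including the rare-tail fraction)
  a <- build_ssm_library(ref, skew = 1.5, wt_fraction = 0.1, seed = 42)
  b <- build_ssm_library(ref, skew = 1.5, wt_fraction = 0.1, seed = 42)
  expect_identical(a$variants, b$variants)
  expect_identical(mean(a$variants$freq < 5e-6), mean(b$variants$freq < 5e-6))

  expect_error(build_ssm_library(ref, skew = -1), "skew")
  expect_error(build_ssm_library(ref, alphabet = c("A", "B")), "unknown")
  expect_error(build_ssm_library(ref, wt_fraction = 1.2), "wt_fraction")
})

test_that("phenotype assignment honours class proportions and positions", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, seed = 1)

  # all-neutral spec: every variant identical to wild type
  spec0 <- list(neutral = list(prop = NA, expr = 1, dimer = 1, clust = 1,
                               agg = 0))
  ph0 <- assign_phenotypes(lib, spec0, seed = 1)
  expect_true(all(ph0$expr == 1 & ph0$dimer == 1 & ph0$clust == 1 &
                    ph0$agg == 0))

  # proportional classes: counts equal round(prop * n) deterministically
  spec <- default_effect_spec()
  ph <- assign_phenotypes(lib, spec, seed = 3)
  expect_equal(sum(ph$class == "aggregating"), round(0.08 * 190))
  expect_equal(sum(ph$class == "interface"), round(0.06 * 190))
  expect_equal(sum(ph$class == "clustering"), round(0.03 * 190))
  # identical seed reproduces the same assignment
  expect_identical(ph$class, assign_phenotypes(lib, spec, seed = 3)$class)

  # positional class claims all variants at its residues
  spec_pos <- default_effect_spec(interface_positions = c(4L, 7L))
  php <- assign_phenotypes(lib, spec_pos, seed = 1)
  expect_true(all(php$class[php$position %in% c(4, 7)] == "interface"))
  expect_true(all(php$class[!php$position %in% c(4, 7)] != "interface"))

  expect_error(assign_phenotypes(lib, list(x = list(prop = NA))), "define")
})

test_that("sorting conserves cells and takes an exact top-fraction BiFC gate", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, seed = 2)
  phen <- assign_phenotypes(lib, seed = 2)
  sim <- simulate_sort(lib, phen, sort_spec(n_cells = 2e4, n_reads = 1e4),
                       seed = 5)
  g <- sim$gate
  expect_equal(g[["expression"]] + g[["rejected"]], g[["n_cells"]])
  expect_equal(g[["bifc"]], round(0.05 * g[["expression"]]))
  # naive cell counts account for every cell
  expect_equal(sum(sim$cells$naive) + sim$wt_cells[["naive"]], 2e4)
  # reads per condition sum to the requested depth
  for (cond in c("naive", "expression", "bifc"))
    expect_equal(sum(sim$cells[[cond]] * 0 + sim$reads[[cond]]) +
                   sim$wt_reads[[cond]], 1e4)
  expect_error(sort_spec(n_cells = 0), "positive")
  expect_error(sort_spec(bifc_top_fraction = 1), "bifc_top_fraction")
})

test_that("all-neutral phenotypes leave condition frequencies at naive values", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, skew = 0.5, wt_fraction = 0.1, seed = 7)
  spec0 <- list(neutral = list(prop = NA, expr = 1, dimer = 1, clust = 1,
                               agg = 0))
  phen <- assign_phenotypes(lib, spec0, seed = 7)
  sim <- simulate_sort(lib, phen, sort_spec(n_cells = 2e5, n_reads = 1e5),
                       seed = 9)
  # per-variant BiFC-gate frequency within 4 multinomial SEs of naive frequency
  n_gate <- sum(sim$cells$bifc) + sim$wt_cells[["bifc"]]
  p <- lib$variants$freq
  se <- sqrt(p * (1 - p) / n_gate)
  obs <- sim$cells$bifc / n_gate
  expect_true(all(abs(obs - p) <= 4 * se + 1e-12))
})

test_that("gate membership matches exhaustive enumeration on small noiseless sorts", {
  # 3 distinct association levels, zero noise: the BiFC gate must consist of
  # cells of the highest-B/E genotypes, filled in rank order.
  ref <- toy_ref()
  lib <- build_ssm_library(ref, skew = 0, wt_fraction = 0.3, seed = 1)
  # keep 3 variants at distinct positions, concentrating frequency on them
  lib$variants <- lib$variants[c(1, 20, 39), ]
  lib$variants$freq <- c(0.3, 0.2, 0.2)
  rownames(lib$variants) <- NULL
  spec <- list(
    high = list(positions = 1L, expr = 1, dimer = 1, clust = 1, agg = 3),
    low = list(positions = 2L, expr = 1, dimer = 0.2, clust = 0.2, agg = 0),
    mid = list(positions = 3L, expr = 1, dimer = 0.5, clust = 1, agg = 0),
    neutral = list(prop = NA, expr = 1, dimer = 1, clust = 1, agg = 0))
  phen <- assign_phenotypes(lib, spec, cv_noise = 0, seed = 1)

  sim <- simulate_sort(lib, phen, sort_spec(n_cells = 50, n_reads = 100),
                       seed = 3, keep_cells = TRUE)
  ct <- sim$cell_table
  # oracle: per-genotype deterministic B/E, rank all 50 cells, take top k
  ratio_of <- c(2, 1 * phen$dimer + 1 * phen$clust + 1 * phen$agg)
  cell_ratio <- ratio_of[ct$genotype + 1L]
  k <- sim$gate[["bifc"]]
  # fill genotypes in decreasing ratio order; stable order within ties
  ord <- order(cell_ratio, decreasing = TRUE)
  expected_sel <- rep(FALSE, 50)
  expected_sel[ord[seq_len(k)]] <- TRUE
  # counts per genotype must match (tie order within a genotype is arbitrary
  # only across equal-ratio genotypes, which are distinct here)
  expect_equal(tapply(expected_sel, ct$genotype, sum),
               tapply(ct$in_bifc, ct$genotype, sum))
  expect_equal(sum(ct$in_bifc), k)
})

test_that("raising aggregation propensity never shrinks a variant's gate share", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, skew = 0, wt_fraction = 0.2, seed = 4)
  spec0 <- list(neutral = list(prop = NA, expr = 1, dimer = 1, clust = 1,
                               agg = 0))
  target <- vkey(lib$variants)[5]
  counts <- sapply(c(0, 1, 3, 8), function(a) {
    phen <- assign_phenotypes(lib, spec0, seed = 4)
    phen$agg[vkey(phen) == target] <- a
    sim <- simulate_sort(lib, phen, sort_spec(n_cells = 5e3, n_reads = 1e3),
                         seed = 11)
    sim$cells$bifc[vkey(sim$cells) == target]
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("FASTQ emission is deterministic and carries the expected codon changes", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, seed = 1)
  phen <- assign_phenotypes(lib, seed = 1)
  sim <- simulate_sort(lib, phen, sort_spec(n_cells = 5e3, n_reads = 2e3),
                       seed = 2)

  d1 <- tempfile(); d2 <- tempfile()
  f1 <- emit_reads(sim, error_rate = 0, dir = d1, seed = 5)
  f2 <- emit_reads(sim, error_rate = 0, dir = d2, seed = 5)
  for (cond in names(f1))
    expect_identical(unname(tools::md5sum(f1[[cond]])),
                     unname(tools::md5sum(f2[[cond]])))

  # single fragment, one variant: every read carries the expected codon
  sim1 <- sim
  sim1$reads <- sim$reads[1, ]
  sim1$reads$naive <- 100L; sim1$reads$expression <- 0L; sim1$reads$bifc <- 0L
  sim1$wt_reads <- c(naive = 0L, expression = 1L, bifc = 1L)
  frag <- list(c(1L, 30L))
  fq <- emit_reads(sim1, fragments = frag, error_rate = 0, seed = 1)
  reads <- parse_fastq_base(fq[["naive"]])
  expect_equal(nrow(reads), 100L)
  pos <- sim1$reads$position[1]
  expected <- ref$cds
  substr(expected, 3 * (pos - 1) + 1, 3 * pos) <-
    mutant_codon(sim1$reads$mut_aa[1])
  expect_true(all(reads$seq == expected))
})

test_that("introduced sequencing errors match an independent FASTQ recount", {
  ref <- toy_ref()
  lib <- build_ssm_library(ref, seed = 1)
  phen <- assign_phenotypes(lib, seed = 1)
  sim <- simulate_sort(lib, phen, sort_spec(n_cells = 5e3, n_reads = 3e3),
                       seed = 2)
  frags <- default_fragments(ref)
  fq <- emit_reads(sim, fragments = frags, error_rate = 0.002, seed = 8)
  fq0 <- emit_reads(sim, fragments = frags, error_rate = 0, seed = 8)
  # recount mismatches between the two emissions with the base-R parser;
  # identical seed means identical read order, so reads pair up line by line
  for (cond in c("naive", "bifc")) {
    withq <- parse_fastq_base(fq[[cond]])
    noq <- parse_fastq_base(fq0[[cond]])
    expect_equal(withq$header, noq$header)
    mism <- mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, withq$seq, noq$seq)
    expect_gt(sum(mism), 0)
    # every mismatch is a substitution (lengths preserved)
    expect_equal(nchar(withq$seq), nchar(noq$seq))
    # rate is plausible for binomial errors at 0.002 per base
    total_bases <- sum(nchar(noq$seq))
    expect_lt(abs(sum(mism) / total_bases - 0.002),
              4 * sqrt(0.002 / total_bases) + 1e-6)
  }
})
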