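---
title: "Methods: BiFC sort-seq deep mutational scanning, from simulated sorts to conservation surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BiFC sort-seq deep mutational scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifcscan)
```

## The experiment being modelled

A single-site saturation mutagenesis (SSM) library of a membrane receptor,
fused to the C-terminal half of split Venus (VC), is expressed in cells
stably expressing the wild-type receptor fused to the N-terminal half (VN).
Transfection conditions keep expression to essentially one library member
per cell, so each cell's fluorescence reports one genotype. Cells pass two
FACS gates: an *expression* gate on surface staining of the VC-fused
mutant, and within it a *high-BiFC* gate on the top 5% of cells ranked by
Venus fluorescence relative to surface expression. Receptor transcripts
from sorted populations are amplified as three overlapping fragments and
sequenced; comparing sorted to naive (unselected plasmid) frequencies
scores every substitution's effect on receptor self-association.

Three mechanisms can raise a cell's BiFC signal: specific dimerisation,
co-clustering into cholesterol-rich lipid microdomains, and nonspecific
aggregation of destabilised protein. The scan cannot separate them per se —
this is why downstream analysis distinguishes *depleted* mutations
(candidate interface or clustering determinants) from *enriched* ones
(candidate aggregators).

## The simulator

`simulate_scan()` chains the generator stages; each is exported separately.

**Library.** `build_ssm_library()` enumerates every (position, mutant)
pair over a configurable alphabet (default the 20 canonical amino acids;
stop optional). Naive frequencies are i.i.d. lognormal with sigma `skew`
(default 1.5), normalised to `1 - wt_fraction` (default `wt_fraction` =
0.1). The heavy skew is deliberate: real SSM plasmid pools show orders-of-
magnitude frequency variation, which is what makes the absent/rare/
confident flags meaningful. `skew = 0` gives the degenerate uniform
library used in several tests.

**Phenotypes.** `assign_phenotypes()` gives each variant four ground-truth
parameters (wild type: `expr = dimer = clust = 1`, `agg = 0`):

| class | expr | dimer | clust | agg | share |
|---|---|---|---|---|---|
| neutral | 1 | 1 | 1 | 0 | remainder |
| aggregating | 0.7 | 0.5 | 1 | 5 | 8% |
| interface | 1 | 0.15 | 1 | 0 | 6% |
| clustering | 1 | 1 | 0.2 | 0 | 3% |

Defaults mirror the mutation behaviours the assay distinguishes:
destabilised aggregators gain BiFC despite losing some surface expression;
interface and clustering mutants lose the specific term only. Classes are
sized by proportion (deterministic largest-remainder counts, then a seeded
shuffle) or pinned to explicit residues (`positions`). The `by` argument
chooses the assignment unit: `"variant"` (independent per substitution) or
`"residue"` (all substitutions at a residue share a class). Residue-level
assignment reflects that interface burial or a palmitoylation site is a
property of the position, not of the particular substitution; it is the
right mode whenever residue-level statistics (conservation scores,
residue-level concordance) are being studied, and the per-variant mode
remains the default for variant-level recovery experiments.

**Sort.** Each of `n_cells` cells draws one genotype from the naive
frequencies. Signals are

* expression `E = expr × ε_E`,
* BiFC `B = expr × (α·dimer + β·clust + γ·agg) × ε_B`,

with `α = β = γ = 1` by default and `ε` independent lognormal noise with
mean 1 and coefficient of variation `cv_noise = 0.5` on both channels (the
assay gives no basis for a more structured noise model; 0.5 is a typical
flow-cytometry spread for transient expression). The expression gate is a
fixed threshold at the 5th percentile of a wild-type cell's expression
distribution (so essentially all wild-type cells pass); a quantile gate on
all cells is available instead. The BiFC gate is *rank-based*: exactly
`round(bifc_top_fraction × n_gated)` cells, ranked by `B/E` (gating
"relative to surface expression"; raw `B` is a config option for
sensitivity analysis). Rank gating makes the 5% occupancy an exact
invariant rather than a noisy target. Reads are multinomial draws from
each condition's cell pool — amplification bias is deliberately not
modelled, since sampling noise is the quantity of interest.

**Reads.** `emit_reads()` writes per-condition FASTQ. Each read spans one
codon-aligned fragment (default three overlapping fragments); a variant
read carries one fixed mutant codon — the lexicographically smallest codon
for the target amino acid — plus i.i.d. substitution errors at
`read_error_rate`. Real NNK degeneracy is out of scope; a deterministic
codon keeps read-level ground truth exact. Headers carry `frag=<i>` and
reads are seeded per condition, so output is byte-reproducible.

## Counting

`call_codon_variants()` compares each read to its fragment reference by
exact ungapped codon-wise comparison — amplicon coordinates are fixed, so
no aligner is involved, and length-discrepant reads are discarded as
`indel_or_unaligned`. A read is wild type (zero mutated codons, or a
synonymous single-codon change), a single variant (one mutated codon, non-
wild-type amino acid), or discarded with a reason code (`multi_mutant`,
`ambiguous`, `stop_codon` when stops are excluded, `not_in_alphabet`).
Fragments must be codon-aligned; partially covered codons would otherwise
be uncallable. The invariant `wt + variants + discarded = total` holds for
every table, and merging per-fragment tables neither creates nor loses
reads.

**Coverage convention.** Frequencies are per position: the denominator at
position *p* is the number of accepted reads covering *p* (`coverage`),
and the wild-type numerator at *p* is coverage minus all variant counts
there — a read mutant elsewhere in its fragment is still wild type at *p*.
With overlapping fragments, coverage varies along the gene; this
fragment-local convention corrects for that, and is also why the WT
normalisation term of the enrichment ratio is evaluated at the variant's
own position.

## Scoring

With pseudocount *c* (default 0.5, applied identically to all conditions)
and alphabet size *A* (default 20):

* `f_v = (count_v + c) / (coverage_p + A·c)`
* `E_v = log2(f_sel,v / f_naive,v) − log2(f_sel,WT / f_naive,WT)`

The flags use the *pseudocount-free* naive frequency: `absent` below
5×10⁻⁶ (no score, matching "missing from the library"), `confident` at or
above 5×10⁻⁵, `rare` between. Zero coverage at a position flags its
variants absent rather than dividing by zero; a wild-type count of zero in
either condition is a hard error, since the normalisation is undefined.

Conservation scores are unweighted means over the scored substitutions at
each residue, excluding stop substitutions by default (nonsense conflates
translation truncation with missense effects; they remain in the raw
table). With several replicates, per-replicate profiles are computed first
and averaged position-wise — averaging before or after the residue mean is
not equivalent in the presence of missing values, and the per-replicate-
first order treats replicates symmetrically.

Replicate concordance is squared Pearson correlation on the log2 scale,
stratified at mutation level into confident-in-both versus the remaining
scored pairs; strata with fewer than 3 pairs are reported `NA`, not 0.

## Classification and testing

`predict_aggregating()` applies the strict conjunction `E > 1` in both
replicates; absence in either replicate blocks a call. Because the natural
denominator for "x% of missense mutations" is ambiguous, both fractions
(of scored, of all possible missense) are reported. The cross-reference
against an observed variant list reports a one-sided hypergeometric
depletion p-value (`P(X ≤ overlap)`) over the scored-variant universe;
wild-type mismatches in the observed list are a hard error naming the
records, since silent numbering offsets would corrupt the entire overlap.

`interface_conservation_test()` uses the difference of mean conservation
scores (interface minus other membrane-exposed residues), permuting
interface labels among the membrane-exposed set. Sampled permutations use
the add-one estimate `(b + 1)/(n_perm + 1)`; `exact = TRUE` enumerates all
label assignments for small sets. Equality comparisons carry a 1e-12
tolerance so ties of floating-point statistics count as "as extreme".

## Structure mapping

`map_scores_to_structure()` writes scores clamped to [−3, +3] — the
display range from strongly depleted to strongly enriched — into the
B-factor column of every atom of matched residues (two decimals, PDB
fixed-width), with 99.0 as sentinel for unscored residues; a plain-text
attribute file retains full precision. Numbering is reconciled by a single
integer offset per chain, which suffices for colinear crystal constructs;
alignment-based mapping is out of scope. `extract_residue_set()` builds
interface sets from explicit residue lists or a heavy-atom contact rule
(default 4.5 Å against a second chain; "close contact" has no canonical
numeric definition, and the cutoff is configurable).

## Problem sizes and calibration choices

The packaged experiments use two synthetic references: a 10-residue toy
(190 variants) for identities, recovery and oracle comparisons, and a
50-residue protein (950 variants) whose skewed library straddles the
5×10⁻⁵/5×10⁻⁶ thresholds, for frequency-stratified concordance. Sorts use
10⁵ cells and 10⁶ reads by default — stand-in values, as the original
experiments do not report per-replicate cell or read totals.

Two experiment-design points deserve emphasis:

* **Null calibration needs gate occupancy.** The top-5% gate of a 10⁵-cell
  sort holds ~4.7×10³ cells, so a variant at the 5×10⁻⁵ confidence
  threshold expects *less than one* gated cell and its log-ratio is
  Jensen-biased regardless of read depth. The null-calibration experiment
  therefore sorts 8×10⁶ cells (~20 expected gate cells at the threshold),
  at which point the mean confident-variant enrichment is within ±0.1 of
  zero. This mirrors the real design constraint that sorted cell numbers,
  not reads, limit accuracy for rare variants.
* **Residue-level signal requires residue-level effects.** When classes
  are drawn independently per variant, residue averaging shrinks true
  signal and noise alike and residue-level concordance gains nothing. The
  concordance experiments therefore use `by = "residue"` assignment, the
  biologically appropriate mode for positional effects.

## What passing tests do and do not show

The generator reproduces the *sampling structure* of a sort-seq scan —
skewed naive pools, genotype-linked gating, multinomial reads, replicate
independence — so it validates the statistics and their implementation.
It does not emulate PCR/RT amplification bias, FACS instrument
compensation or drift between sorting sessions, codon degeneracy, double
transfection, or epistasis between the tag fusions and mutations. High
recovery on simulation therefore certifies the pipeline, not the
biological accuracy of any particular scan; on real data the enrichment
of an individual mutation remains an estimate until verified by targeted
mutagenesis, and conservation scores (which agree better across
replicates) are the more reliable residue-level readout.
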