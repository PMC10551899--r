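# Shared fixtures: a 10-residue toy receptor and small hand-built tables.

toy_ref <- function() {
  # MACDEFGHIK
  reference_protein("toy", "ATGGCTTGCGATGAATTTGGTCATATTAAA")
}

vkey <- function(d) paste0(d$position, "_", d$mut_aa)

# 50-residue reference whose SSM library (950 variants) has a naive
# frequency spectrum straddling the 5e-5 / 5e-6 flag thresholds
mid_ref <- function(n_residues = 50L) {
  codons <- c("GCT", "TGC", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT", "AAA",
              "CTG", "AAT", "CCT", "CAG", "CGT", "TCT", "ACT", "GTT", "TGG",
              "TAT")
  body <- rep(codons, length.out = n_residues - 1L)
  reference_protein("mid", paste0("ATG", paste(body, collapse = "")))
}

# count_table from a compact spec list(c(pos, mut, count), ...)
make_counts <- function(ref, spec, wt_count, condition = "naive", ...) {
  df <- do.call(rbind, lapply(spec, function(s)
    data.frame(position = as.integer(s[[1]]), mut_aa = s[[2]],
               count = as.integer(s[[3]]))))
  df$wt_aa <- ref_residue(ref, df$position)
  count_table(df[, c("position", "wt_aa", "mut_aa", "count")],
              wt_count = wt_count, ref = ref, condition = condition, ...)
}

# minimal single-chain (or two-chain) PDB text with CA+CB atoms per residue
write_toy_pdb <- function(file, chains) {
  # chains: named list chain -> data.frame(resno, x, y, z)
  lines <- character(0)
  serial <- 0L
  for (ch in names(chains)) {
    d <- chains[[ch]]
    for (i in seq_len(nrow(d))) {
      for (at in c("CA", "CB")) {
        serial <- serial + 1L
        dz <- if (at == "CB") 0.5 else 0
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, at, ch, d$resno[i], d$x[i], d$y[i], d$z[i] + dz, 1, 0))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      ALA %s%4d", serial + 1L, ch,
                              d$resno[nrow(d)]))
  }
  writeLines(c(lines, "END"), file)
  file
}

# independent FASTQ parser (base R, no package code) used as a recount oracle
parse_fastq_base <- function(file) {
  lines <- readLines(file)
  stopifnot(length(lines) %% 4L == 0L)
  data.frame(header = sub("^@", "", lines[seq(1, length(lines), 4)]),
             seq = lines[seq(2, length(lines), 4)],
             stringsAsFactors = FALSE)
}
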