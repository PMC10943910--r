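# Shared fixtures and independent oracles for the test suite.

PEP34 <- "AAEKEFIKYPYPTPLQYQQLATRLKVEKKLVRRW"
CORE30 <- "EFIKYPYPTPLQYQQLATRLKVEKKLVRRW"

random_peptide <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Brute-force hydrophobic moment: explicit per-residue sine/cosine sums.
oracle_moment <- function(peptide, scale, delta_deg = 100) {
  res <- strsplit(peptide, "")[[1]]
  sx <- 0; sy <- 0
  for (i in seq_along(res)) {
    a <- (i - 1) * delta_deg * pi / 180
    sx <- sx + scale[[res[i]]] * cos(a)
    sy <- sy + scale[[res[i]]] * sin(a)
  }
  sqrt(sx^2 + sy^2)
}

# Term-by-term Henderson-Hasselbalch summation over individual groups.
oracle_charge <- function(peptide, pH, pka) {
  res <- strsplit(peptide, "")[[1]]
  groups <- c("Nterm", "Cterm", res[res %in% pka$group])
  total <- 0
  for (g in groups) {
    row <- pka[pka$group == g, ]
    total <- total + if (row$type == "basic")
      1 / (1 + 10^(pH - row$pka))
    else -1 / (1 + 10^(row$pka - pH))
  }
  total
}

# Independent per-frame codon loop over a hand-inlined genetic code,
# independent of the package's translation path.
oracle_translate_frame <- function(seq, offset) {
  code <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L",
            CTC = "L", CTA = "L", CTG = "L", ATT = "I", ATC = "I",
            ATA = "I", ATG = "M", GTT = "V", GTC = "V", GTA = "V",
            GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
            CCT = "P", CCC = "P", CCA = "P", CCG = "P", ACT = "T",
            ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
            GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
            TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
            AAT = "N", AAC = "N", AAA = "K", AAG = "K", GAT = "D",
            GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C",
            TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R",
            CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
            GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  n <- nchar(seq)
  aa <- character(0)
  i <- offset + 1
  while (i + 2 <= n) {
    cod <- substr(seq, i, i + 2)
    aa <- c(aa, if (cod %in% names(code)) code[[cod]] else "X")
    i <- i + 3
  }
  paste(aa, collapse = "")
}

oracle_revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Fragments of one strand orientation by splitting the oracle translation.
oracle_fragments <- function(seq, offset, min_len) {
  aa <- oracle_translate_frame(seq, offset)
  parts <- strsplit(gsub("X", "*", aa), "*", fixed = TRUE)[[1]]
  parts[nchar(parts) >= min_len]
}

make_separable_table <- function() {
  pos <- replicate(10, paste(sample(c("K", "R", "W"), 12, TRUE),
                             collapse = ""))
  neg <- replicate(10, paste(sample(c("D", "E", "G"), 12, TRUE),
                             collapse = ""))
  featurize_set(c(pos, neg), rep(c("ACP", "nonACP"), each = 10))
}

write_domtbl_fixture <- function(path, id = "cand1") {
  hdr <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  row <- paste(id, "-", "34", "Homeodomain", "PF00046.24", "57",
               "2.1e-08", "33.1", "0.1", "1", "1", "3.1e-12", "1.2e-08",
               "32.6", "0.1", "1", "30", "1", "30", "1", "30", "0.95",
               "mined candidate")
  writeLines(c(hdr, row), path)
  path
}
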