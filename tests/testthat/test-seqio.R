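test_that("FASTA parsing handles plain, wrapped and fixture records", {
  f <- withr::local_tempfile()
  writeLines(c(">p1 first peptide", "AAEKE"), f)
  r <- read_fasta(f, "protein")
  expect_equal(r$id, "p1")
  expect_equal(r$description, "first peptide")
  expect_equal(r$sequence, "AAEKE")

  # wrapped lines and lower case are joined and upper-cased
  writeLines(c(">p2", "aaek", "efik"), f)
  expect_equal(read_fasta(f, "protein")$sequence, "AAEKEFIK")

  fx <- read_fasta(system.file("extdata", "homeodomain34.fasta",
                               package = "acpmine"), "protein")
  expect_equal(nrow(fx), 1L)
  expect_equal(nchar(fx$sequence), 34L)
  expect_equal(fx$sequence, PEP34)
})

test_that("invalid-letter policy rejects or fails, never silently alters", {
  f <- withr::local_tempfile()
  writeLines(c(">ok", "AAKR", ">bad", "ABCK"), f)
  expect_warning(r <- read_fasta(f, "protein"), "rejected")
  expect_equal(r$id, "ok")
  expect_equal(attr(r, "n_rejected"), 1L)
  expect_error(read_fasta(f, "protein", invalid = "error"), "invalid")
})

test_that("FASTA reader errors on missing/empty/headerless input", {
  expect_error(read_fasta(tempfile(), "protein"), "not found")
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_error(read_fasta(f, "protein"), "empty")
  writeLines(c("ACGT", ">late"), f)
  expect_error(read_fasta(f, "dna"), "header")
})

test_that("FASTA round trip preserves id/sequence pairs", {
  set.seed(7)
  recs <- data.frame(id = sprintf("s%d", 1:5),
                     description = c("", "desc here", "", "", "x"),
                     sequence = vapply(c(3, 61, 120, 60, 10),
                                       random_peptide, character(1)),
                     alphabet = "protein")
  f <- withr::local_tempfile()
  write_fasta(recs, f)
  back <- read_fasta(f, "protein")
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$description, recs$description)
  # writer wraps at 60 columns
  expect_true(all(nchar(readLines(f)) <= 61))
})

test_that("FASTQ parsing returns dna records and enforces its contracts", {
  f <- withr::local_tempfile()
  writeLines(c("@r1", "ATGAAA", "+", "IIIIII"), f)
  r <- read_fastq(f)
  expect_equal(r$sequence, "ATGAAA")
  expect_equal(r$alphabet, "dna")

  writeLines(c("@r1", "ATGAAA", "+", "IIIIII",
               "@r2 desc", "CCGT", "+", "!!!!"), f)
  r2 <- read_fastq(f)
  expect_equal(r2$id, c("r1", "r2"))

  writeLines(c("@r1", "ATGAAA", "+", "IIIII"), f)
  expect_error(read_fastq(f), "length mismatch in record r1")

  writeLines(c("@r1", "ATGAAA", "+"), f)
  expect_error(read_fastq(f), "truncated")
})

test_that("six-frame translation matches the standard code on examples", {
  fr <- six_frame_translate("ATGAAATAA", min_len = 2)
  plus1 <- fr[fr$frame == 1, ]
  expect_equal(plus1$peptide, "MK")
  expect_equal(plus1$nt_start, 0L)
  expect_equal(plus1$nt_end, 6L)

  fr2 <- six_frame_translate("ATGAAA", min_len = 1)
  expect_equal(fr2$peptide[fr2$frame == 1], "MK")
  # brute-force oracle: codon loop per frame on both strands
  seq <- "ATGAAA"
  expected <- unlist(lapply(0:2, function(o)
    c(oracle_fragments(seq, o, 1),
      oracle_fragments(oracle_revcomp(seq), o, 1))))
  expect_setequal(fr2$peptide, expected)
  expect_equal(nrow(fr2), length(expected))
})

test_that("translation handles stops, N codons and short reads", {
  # N inside a codon splits the fragment
  fr <- six_frame_translate("ATGNAAATGAAA", min_len = 1)
  p1 <- fr[fr$frame == 1, ]
  expect_equal(p1$peptide, c("M", "MK"))
  expect_equal(nrow(six_frame_translate("AT", min_len = 1)), 0L)
  # record shorter than min_len simply yields nothing at that length
  expect_equal(nrow(six_frame_translate("ATGTAA", min_len = 5)), 0L)
})

test_that("fragment counts partition by length and coordinates re-encode", {
  set.seed(11)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 120, TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    all1 <- six_frame_translate(seq, min_len = 1)
    all5 <- six_frame_translate(seq, min_len = 5)
    expect_equal(nrow(all1),
                 nrow(all5) + sum(nchar(all1$peptide) < 5))
    # every fragment re-translates from its coordinates under the oracle
    for (i in seq_len(nrow(all5))) {
      row <- all5[i, ]
      nt <- substr(seq, row$nt_start + 1, row$nt_end)
      if (row$frame < 0) nt <- oracle_revcomp(nt)
      expect_equal(oracle_translate_frame(nt, 0), row$peptide)
    }
  }
})

test_that("reverse-complementing a read swaps +k and -k fragment sets", {
  set.seed(13)
  for (rep in 1:10) {
    seq <- random_dna <- paste(sample(c("A", "C", "G", "T"), 90, TRUE),
                               collapse = "")
    a <- six_frame_translate(seq, min_len = 1)
    b <- six_frame_translate(oracle_revcomp(seq), min_len = 1)
    for (f in 1:3) {
      expect_setequal(a$peptide[a$frame == f], b$peptide[b$frame == -f])
      expect_setequal(a$peptide[a$frame == -f], b$peptide[b$frame == f])
    }
  }
})

test_that("six-frame translation agrees with Biostrings on random reads", {
  skip_if_not_installed("Biostrings")
  set.seed(17)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 99, TRUE), collapse = "")
    fr <- six_frame_translate(seq, min_len = 1)
    for (i in seq_len(nrow(fr))) {
      row <- fr[i, ]
      nt <- substr(seq, row$nt_start + 1, row$nt_end)
      dna <- Biostrings::DNAString(nt)
      if (row$frame < 0) dna <- Biostrings::reverseComplement(dna)
      expect_equal(as.character(Biostrings::translate(dna,
                                                      no.init.codon = TRUE)),
                   row$peptide)
    }
  }
})
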