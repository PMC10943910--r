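#' Sequence input/output and six-frame translation
#'
#' Sequence sets are plain data frames with columns `id`, `description`,
#' `sequence` and `alphabet` (`"dna"` or `"protein"`), one row per record.
#' DNA sequences are case-folded to upper case and may contain only ACGTN;
#' protein sequences only the 20 canonical one-letter codes. Records failing
#' validation are routed per `invalid` policy, never silently altered.
#'
#' @name seqio
NULL

.STOP <- "*"

# Standard genetic code (translation table 1), codon -> one-letter residue.
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

.new_seqset <- function(id, description, sequence, alphabet) {
  data.frame(id = as.character(id),
             description = as.character(description),
             sequence = as.character(sequence),
             alphabet = alphabet,
             stringsAsFactors = FALSE)
}

.validate_records <- function(recs, alphabet, invalid) {
  recs$sequence <- toupper(gsub("[ \t\r]", "", recs$sequence))
  pat <- if (alphabet == "dna") "^[ACGTN]+$" else
    paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")
  ok <- nzchar(recs$sequence) & grepl(pat, recs$sequence)
  if (any(!ok)) {
    bad <- recs$id[!ok]
    if (invalid == "error")
      stop("record(s) with invalid ", alphabet, " letters: ",
           paste(bad, collapse = ", "))
    warning(sum(!ok), " record(s) rejected for invalid ", alphabet,
            " letters: ", paste(bad, collapse = ", "))
    recs <- recs[ok, , drop = FALSE]
    rownames(recs) <- NULL
  }
  attr(recs, "n_rejected") <- sum(!ok)
  recs
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param alphabet `"protein"` or `"dna"`; controls validation.
#' @param invalid Policy for records with letters outside the alphabet:
#'   `"reject"` drops them with a warning (the count is available as the
#'   `n_rejected` attribute), `"error"` fails hard.
#' @return A sequence data frame (see [seqio]) in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       invalid = c("reject", "error")) {
  alphabet <- match.arg(alphabet)
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | cumsum(grepl("^>", lines)) > 0]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  if (!startsWith(lines[1], ">"))
    stop("not a FASTA file (first non-blank line is not a '>' header): ", path)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, character(1), collapse = "")
  seqs <- seqs[match(seq_along(headers), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs)))
    stop("record(s) with empty sequence: ",
         paste(id[!nzchar(seqs)], collapse = ", "))
  .validate_records(.new_seqset(id, desc, seqs, alphabet), alphabet, invalid)
}

#' Write records to a 60-column-wrapped FASTA file
#'
#' @param records A sequence data frame (see [seqio]).
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste0(">", records$id[i], " ", records$description[i])
    else paste0(">", records$id[i])
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(hdr, substring(s, starts,
                                pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}

#' Read a FASTQ file as DNA records
#'
#' Expects 4-line records with Phred+33 qualities. Qualities are length-checked
#' against the sequence and then discarded: no quality filtering is applied at
#' this stage (upstream read QC is out of scope).
#'
#' @param path Path to an uncompressed FASTQ file.
#' @inheritParams read_fasta
#' @return A DNA sequence data frame in file order.
#' @export
read_fastq <- function(path, invalid = c("reject", "error")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 4L != 1L]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at end of ", path,
         " (", length(lines), " lines, not a multiple of 4)")
  n <- length(lines) %/% 4L
  if (n == 0L) stop("empty FASTQ file: ", path)
  at <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(at, "@")))
    stop("malformed FASTQ: header line without '@' at record ",
         which(!startsWith(at, "@"))[1])
  if (any(!startsWith(plus, "+")))
    stop("malformed FASTQ: separator line without '+' in record ",
         sub("^@", "", at[which(!startsWith(plus, "+"))[1]]))
  headers <- sub("^@", "", at)
  id <- sub("\\s.*$", "", headers)
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism))
    stop("quality/sequence length mismatch in record ", id[which(mism)[1]])
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  .validate_records(.new_seqset(id, desc, seqs, "dna"), "dna", invalid)
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Split one strand-oriented sequence into stop-/N-free fragments for frames
# 1..3 (offsets 0..2 on that strand).
.translate_strand <- function(seq, min_len) {
  n <- nchar(seq)
  out <- vector("list", 3L)
  for (off in 0:2) {
    ncod <- (n - off) %/% 3L
    frags <- list()
    if (ncod >= 1L) {
      starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(seq, starts, starts + 2L)
      aa <- GENETIC_CODE_TABLE[codons]
      aa[is.na(aa)] <- "X"                     # codon containing N
      brk <- c(which(aa == .STOP | aa == "X"), ncod + 1L)
      run_start <- 1L
      for (b in brk) {
        if (b > run_start) {
          pep <- paste(aa[run_start:(b - 1L)], collapse = "")
          if (nchar(pep) >= min_len)
            frags[[length(frags) + 1L]] <- list(
              pep = pep,
              s = off + 3L * (run_start - 1L),   # 0-based on this strand
              e = off + 3L * (b - 1L))
        }
        run_start <- b + 1L
      }
    }
    out[[off + 1L]] <- frags
  }
  out
}

#' Six-frame translation of a DNA read into peptide fragments
#'
#' Translates all six reading frames under the standard genetic code
#' (translation table 1), splitting fragments at stop codons and at any codon
#' containing N. Coordinates are 0-based half-open on the forward strand of
#' the read; frames are numbered +1..+3 (forward) and -1..-3 (reverse
#' complement), each frame k starting at offset k-1 of its strand.
#'
#' @param record A single DNA sequence string, or a one-row DNA sequence data
#'   frame (see [seqio]).
#' @param min_len Minimum fragment length in residues (>= 1).
#' @return A data frame with columns `read_id`, `frame` (integer in
#'   {-3..-1, 1..3}), `nt_start`, `nt_end`, `peptide`. Reads shorter than one
#'   codon yield zero rows.
#' @export
six_frame_translate <- function(record, min_len = 1L) {
  if (!.is_count(min_len)) stop("min_len must be a positive integer")
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop("six_frame_translate() takes one record; see translate_reads()")
    if (!identical(record$alphabet, "dna")) stop("record must be dna")
    read_id <- record$id
    seq <- record$sequence
  } else {
    read_id <- "read"
    seq <- toupper(record)
  }
  if (!grepl("^[ACGTN]*$", seq)) stop("sequence contains non-ACGTN letters")
  n <- nchar(seq)
  empty <- data.frame(read_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      peptide = character(), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  fwd <- .translate_strand(seq, min_len)
  rev <- .translate_strand(.revcomp(seq), min_len)
  rows <- list()
  for (f in 1:3) {
    for (fr in fwd[[f]])
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, frame = f,
        nt_start = fr$s, nt_end = fr$e, peptide = fr$pep,
        stringsAsFactors = FALSE)
    for (fr in rev[[f]])   # map reverse-strand coords to forward strand
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, frame = -f,
        nt_start = n - fr$e, nt_end = n - fr$s, peptide = fr$pep,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Six-frame translate every read in a set
#'
#' @param reads A DNA sequence data frame.
#' @inheritParams six_frame_translate
#' @return Row-bound fragment data frame across all reads.
#' @export
translate_reads <- function(reads, min_len = 1L) {
  parts <- lapply(seq_len(nrow(reads)), function(i)
    six_frame_translate(reads[i, , drop = FALSE], min_len))
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- six_frame_translate("", min_len)
  rownames(out) <- NULL
  out
}
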