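#' Seeded synthetic data: peptide classes and reads with planted ORFs
#'
#' Generates (a) labelled peptide sets from residue-frequency class profiles
#' with controlled composition shifts and (b) DNA reads carrying planted
#' open reading frames that encode known peptides, together with a
#' ground-truth manifest. All outputs are pure functions of (config, seed).
#'
#' @name synthetic_data
NULL

#' Bundled class profile
#'
#' `"acp"` is enriched in K, R, W, F, L and depleted in D, E relative to the
#' uniform `"background"` profile, mirroring the strongly cationic and
#' hydrophobic/aromatic composition of experimentally validated anticancer
#' peptides (K + R around a quarter of all residues, few acidic residues).
#' Frequencies are documented in the bundled `class_profiles.tsv`. The
#' default length range 10-50 reflects curated ACP collections, which
#' contain few peptides under 10 residues.
#'
#' @param name `"acp"` or `"background"`.
#' @param len_range Length range (residues), within [5, 50].
#' @return Object of class `class_profile`: `name`, `freq` (20
#'   probabilities), `len_range`, optional `transition` matrix.
#' @export
class_profile <- function(name = c("acp", "background"),
                          len_range = c(10L, 50L)) {
  name <- match.arg(name)
  freq <- .residue_vector("class_profiles.tsv", name)
  new_class_profile(name, freq, len_range)
}

#' Construct a class profile from explicit frequencies
#'
#' @param name Profile name (token).
#' @param freq Named numeric vector of 20 residue frequencies summing to 1.
#' @param len_range Length range, within [5, 50].
#' @param transition Optional 20x20 row-stochastic matrix of first-order
#'   residue transition probabilities (used instead of i.i.d. sampling).
#' @return A `class_profile` object.
#' @export
new_class_profile <- function(name, freq, len_range = c(5L, 50L),
                              transition = NULL) {
  freq <- freq[AA_ALPHABET]
  if (anyNA(freq) || any(freq < 0) || abs(sum(freq) - 1) > 1e-9)
    stop("freq must be 20 non-negative values summing to 1")
  if (length(len_range) != 2L || len_range[1L] > len_range[2L] ||
        len_range[1L] < 5L || len_range[2L] > 50L)
    stop("len_range must be within [5, 50]")
  if (!is.null(transition)) {
    stopifnot(is.matrix(transition), all(dim(transition) == 20L))
    if (any(abs(rowSums(transition) - 1) > 1e-9))
      stop("transition rows must sum to 1")
  }
  structure(list(name = name, freq = freq,
                 len_range = as.integer(len_range),
                 transition = transition),
            class = "class_profile")
}

#' Shift one composition feature of a profile
#'
#' For a residue, its frequency is raised by `delta` and the remaining mass
#' renormalized proportionally. For a dipeptide `"XY"`, the profile gains a
#' first-order chain bias: the transition probability X->Y is boosted by
#' `delta` and row X renormalized.
#'
#' @param profile A `class_profile`.
#' @param feature A residue (1 letter) or dipeptide (2 letters) token.
#' @param delta Frequency (or transition-probability) increment.
#' @return A shifted `class_profile`.
#' @export
plant_feature_shift <- function(profile, feature, delta) {
  stopifnot(inherits(profile, "class_profile"))
  if (!is.character(feature) || !nchar(feature) %in% 1:2 ||
        !all(strsplit(feature, "")[[1]] %in% AA_ALPHABET))
    stop("feature must be a canonical residue or dipeptide token")
  if (nchar(feature) == 1L) {
    p <- profile$freq
    new_f <- p[feature] + delta
    if (new_f < 0 || new_f > 1)
      stop("delta pushes ", feature, " frequency outside [0, 1]")
    p[setdiff(AA_ALPHABET, feature)] <-
      p[setdiff(AA_ALPHABET, feature)] * (1 - new_f) / (1 - p[feature])
    p[feature] <- new_f
    new_class_profile(paste0(profile$name, "_", feature, "shift"),
                      p, profile$len_range, profile$transition)
  } else {
    from <- substr(feature, 1L, 1L); to <- substr(feature, 2L, 2L)
    tr <- profile$transition
    if (is.null(tr))
      tr <- matrix(rep(profile$freq, each = 20L), nrow = 20L,
                   dimnames = list(AA_ALPHABET, AA_ALPHABET), byrow = FALSE)
    new_p <- tr[from, to] + delta
    if (new_p < 0 || new_p > 1)
      stop("delta pushes transition ", feature, " outside [0, 1]")
    tr[from, ] <- tr[from, ] * (1 - new_p) / (1 - tr[from, to])
    tr[from, to] <- new_p
    new_class_profile(paste0(profile$name, "_", feature, "shift"),
                      profile$freq, profile$len_range, tr)
  }
}

#' Sample peptides from a class profile
#'
#' Residues are drawn i.i.d. from the profile frequencies (or by the
#' first-order chain when the profile carries a transition matrix); lengths
#' are uniform on the profile's range. Bit-reproducible for a given seed.
#'
#' @param profile A `class_profile`.
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param label Class label stored in the description field
#'   (default the profile name mapped to ACP/nonACP is left to the caller).
#' @param prefix Record id prefix.
#' @return A protein sequence data frame (see [seqio]).
#' @export
sample_peptides <- function(profile, n, seed, label = profile$name,
                            prefix = profile$name) {
  stopifnot(inherits(profile, "class_profile"))
  if (!.is_count(n)) stop("n must be a positive integer")
  .with_seed(seed, {
    lens <- sample(seq.int(profile$len_range[1L], profile$len_range[2L]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      if (is.null(profile$transition)) {
        paste(sample(AA_ALPHABET, L, replace = TRUE, prob = profile$freq),
              collapse = "")
      } else {
        res <- character(L)
        res[1L] <- sample(AA_ALPHABET, 1L, prob = profile$freq)
        for (i in seq_len(L - 1L))
          res[i + 1L] <- sample(AA_ALPHABET, 1L,
                                prob = profile$transition[res[i], ])
        paste(res, collapse = "")
      }
    }, character(1))
    .new_seqset(sprintf("%s_%05d", prefix, seq_len(n)),
                paste0("label=", label), seqs, "protein")
  })
}

#' Sample a labelled two-class training set
#'
#' Convenience wrapper: `n` peptides from each of an ACP-like and a
#' background profile, featurized and labelled.
#'
#' @param n Peptides per class.
#' @param seed Integer seed.
#' @param acp,background Class profiles.
#' @return A labelled feature table (see [featurize_set()]); peptides are
#'   kept in the `peptides` attribute.
#' @export
sample_training_set <- function(n, seed,
                                acp = class_profile("acp"),
                                background = class_profile("background")) {
  pos <- sample_peptides(acp, n, seed, label = "ACP", prefix = "acp")
  neg <- sample_peptides(background, n, seed + 1L, label = "nonACP",
                         prefix = "bg")
  tbl <- featurize_set(c(pos$sequence, neg$sequence),
                       rep(c("ACP", "nonACP"), each = n))
  attr(tbl, "peptides") <- rbind(pos, neg)
  tbl
}

.CODONS_BY_AA <- local({
  split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
})

.reverse_translate <- function(peptide) {
  codes <- strsplit(peptide, "")[[1]]
  paste(vapply(codes, function(a) {
    cs <- .CODONS_BY_AA[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

#' Generate DNA reads with planted peptide-encoding ORFs
#'
#' Each planted peptide is reverse-translated with uniform random codon
#' choice, flanked by stop codons on both sides, and embedded at a random
#' offset on a random strand of an otherwise random-base read; remaining
#' reads are pure random background. Constant Phred+33 quality 'I'. The
#' manifest records, per planted peptide, the encoding read, frame and
#' forward-strand 0-based half-open nucleotide coordinates of the codons,
#' in the convention of [six_frame_translate()] — so every manifest entry is
#' recoverable verbatim by six-frame translation.
#'
#' @param peptides Character vector of peptides to plant (each <= 50
#'   residues by default read length).
#' @param n_background Number of background-only reads.
#' @param read_length Read length in nt; must be at least
#'   `3 * max peptide length + 6` (ORF plus stop flanks).
#' @param seed Integer seed.
#' @return List of class `synthetic_reads`: `reads` (DNA sequence data
#'   frame with a `quality` column), `manifest` (peptide, read_id, frame,
#'   nt_start, nt_end), `seed`.
#' @export
generate_reads <- function(peptides = character(), n_background = 0L,
                           read_length = 300L, seed = 1L) {
  if (!.is_count(read_length)) stop("read_length must be a positive integer")
  if (length(peptides)) {
    vapply(peptides, .assert_peptide, character(1))
    need <- 3L * max(nchar(peptides)) + 6L
    if (read_length < need)
      stop("read_length ", read_length, " too short for the longest planted ",
           "peptide (needs >= ", need, ")")
  }
  .with_seed(seed, {
    n_plant <- length(peptides)
    rand_read <- function()
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
            collapse = "")
    reads <- character(n_plant + n_background)
    man <- vector("list", n_plant)
    stops <- c("TAA", "TAG", "TGA")
    for (i in seq_len(n_plant)) {
      orf <- paste0(sample(stops, 1L), .reverse_translate(peptides[i]),
                    sample(stops, 1L))
      bg <- rand_read()
      offset <- sample.int(read_length - nchar(orf) + 1L, 1L) - 1L # 0-based
      minus <- sample(c(TRUE, FALSE), 1L)
      insert <- if (minus) .revcomp(orf) else orf
      read <- paste0(substr(bg, 1L, offset), insert,
                     substr(bg, offset + nchar(orf) + 1L, read_length))
      reads[i] <- read
      cod_start <- offset + 3L                     # first peptide codon
      cod_end <- cod_start + 3L * nchar(peptides[i])
      if (minus) {
        # insert was reverse-complemented: forward coords flip within it
        f_start <- offset + (nchar(orf) - (cod_end - offset))
        f_end <- offset + (nchar(orf) - (cod_start - offset))
        frame <- -(((read_length - f_end) %% 3L) + 1L)
        cod_start <- f_start; cod_end <- f_end
      } else {
        frame <- (cod_start %% 3L) + 1L
      }
      man[[i]] <- data.frame(peptide = peptides[i],
                             read_id = sprintf("planted_%04d", i),
                             frame = frame, nt_start = cod_start,
                             nt_end = cod_end, stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_background))
      reads[n_plant + j] <- rand_read()
    ids <- c(sprintf("planted_%04d", seq_len(n_plant)),
             if (n_background) sprintf("bg_%04d", seq_len(n_background)))
    out <- .new_seqset(ids, "", reads, "dna")
    out$quality <- strrep("I", read_length)
    manifest <- if (n_plant) do.call(rbind, man)
    else data.frame(peptide = character(), read_id = character(),
                    frame = integer(), nt_start = integer(),
                    nt_end = integer(), stringsAsFactors = FALSE)
    structure(list(reads = out, manifest = manifest, seed = seed),
              class = "synthetic_reads")
  })
}

#' Write synthetic reads as FASTQ plus a manifest
#'
#' @param x A `synthetic_reads` object.
#' @param fastq,manifest Output paths.
#' @return Invisibly, the two paths.
#' @export
write_synthetic_reads <- function(x, fastq, manifest) {
  stopifnot(inherits(x, "synthetic_reads"))
  con <- file(fastq, "w")
  writeLines(paste0("@", x$reads$id, "\n", x$reads$sequence, "\n+\n",
                    x$reads$quality), con)
  close(con)
  utils::write.table(x$manifest, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq = fastq, manifest = manifest))
}
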