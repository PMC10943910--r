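#' Sliding-window candidate mining
#'
#' Candidates are every contiguous window of each length in
#' `[min_len, max_len]` over every translated fragment, deduplicated with
#' full provenance, scored by a fitted [acp_fit()] model and ranked.
#'
#' @name mining
NULL

#' Enumerate sliding windows over a peptide fragment
#'
#' All contiguous substrings of each length in `[min_len,
#' min(max_len, nchar(fragment))]`, step 1, ordered by (length ascending,
#' offset ascending). The emitted count is the closed form
#' `sum over lengths L of (n - L + 1)`.
#'
#' @param fragment Peptide string.
#' @param min_len,max_len Window length bounds (residues).
#' @return Data frame with `peptide`, `start` (0-based offset in the
#'   fragment), `length`. Fragments shorter than `min_len` yield zero rows.
#' @export
enumerate_windows <- function(fragment, min_len = 5L, max_len = 50L) {
  if (!.is_count(min_len)) stop("min_len must be a positive integer")
  if (!.is_count(max_len, min_len)) stop("max_len must be >= min_len")
  n <- nchar(fragment)
  lens <- seq.int(min_len, min(max_len, n))
  if (n < min_len)
    return(data.frame(peptide = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  parts <- lapply(lens, function(L) {
    starts <- 0:(n - L)
    data.frame(peptide = substring(fragment, starts + 1L, starts + L),
               start = starts, length = L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Deduplicate window candidates, merging provenance
#'
#' @param windows Data frame with at least columns `peptide`, `read_id`,
#'   `frame`, `start`, `length` (one row per window occurrence).
#' @return List with `candidates` (unique `peptide`, `length`, `n_sources`)
#'   and `provenance` (the input rows, one per occurrence). The total number
#'   of provenance rows equals the input row count.
#' @export
deduplicate <- function(windows) {
  if (!nrow(windows))
    return(list(candidates = data.frame(peptide = character(),
                                        length = integer(),
                                        n_sources = integer()),
                provenance = windows))
  tab <- table(windows$peptide)
  uniq <- !duplicated(windows$peptide)
  cand <- data.frame(peptide = windows$peptide[uniq],
                     length = nchar(windows$peptide[uniq]),
                     n_sources = as.integer(tab[windows$peptide[uniq]]),
                     stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  list(candidates = cand, provenance = windows)
}

#' Mine reads for ACP candidates
#'
#' Runs the full per-read pipeline: six-frame translation, sliding-window
#' enumeration, deduplication, composition featurization and classifier
#' scoring. The report is sorted by score descending with deterministic
#' tie-breaking (shorter peptide first, then lexicographic).
#'
#' @param reads DNA sequence data frame (see [read_fastq()]).
#' @param model A fitted `acp_model`.
#' @param min_len,max_len Candidate window length bounds.
#' @return List of class `acp_mining`: `candidates` (peptide, length, score,
#'   label, n_sources), `provenance`, and `stage_counts` (reads, fragments,
#'   windows, unique candidates, predicted ACP).
#' @export
mine_reads <- function(reads, model, min_len = 5L, max_len = 50L) {
  if (!nrow(reads)) stop("empty read set")
  stopifnot(inherits(model, "acp_model"))
  frags <- translate_reads(reads, min_len = min_len)
  win_parts <- lapply(seq_len(nrow(frags)), function(i) {
    w <- enumerate_windows(frags$peptide[i], min_len, max_len)
    if (!nrow(w)) return(NULL)
    data.frame(peptide = w$peptide, read_id = frags$read_id[i],
               frame = frags$frame[i],
               start = w$start, length = w$length,
               stringsAsFactors = FALSE)
  })
  win_parts <- win_parts[!vapply(win_parts, is.null, logical(1))]
  windows <- if (length(win_parts)) do.call(rbind, win_parts)
  else data.frame(peptide = character(), read_id = character(),
                  frame = integer(), start = integer(), length = integer())
  dd <- deduplicate(windows)
  cand <- dd$candidates
  if (nrow(cand)) {
    cand$score <- unname(acp_score(model, cand$peptide))
    cand$label <- ifelse(cand$score > model$threshold, "ACP", "nonACP")
    ord <- order(-cand$score, cand$length, cand$peptide)
    cand <- cand[ord, c("peptide", "length", "score", "label", "n_sources")]
    rownames(cand) <- NULL
  } else {
    cand$score <- numeric(); cand$label <- character()
  }
  structure(list(candidates = cand, provenance = dd$provenance,
                 stage_counts = c(reads = nrow(reads),
                                  fragments = nrow(frags),
                                  windows = nrow(windows),
                                  unique_candidates = nrow(cand),
                                  predicted_acp = sum(cand$label == "ACP"))),
            class = "acp_mining")
}

#' @export
print.acp_mining <- function(x, n = 10L, ...) {
  cat("ACP candidate mining report\n")
  cat("  stages:", paste(names(x$stage_counts), x$stage_counts,
                         sep = "=", collapse = ", "), "\n")
  cat("  top candidates:\n")
  print(utils::head(x$candidates, n))
  invisible(x)
}

#' Write a candidate report as delimited text
#' @param x An `acp_mining` report.
#' @param path Output path.
#' @param top_n Also write the top-N candidates as FASTA to
#'   `paste0(path, ".fasta")` when non-NULL.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path, top_n = NULL) {
  utils::write.table(x$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(top_n) && nrow(x$candidates)) {
    top <- utils::head(x$candidates, top_n)
    recs <- .new_seqset(sprintf("candidate_%03d", seq_len(nrow(top))),
                        sprintf("score=%.4f label=%s", top$score, top$label),
                        top$peptide, "protein")
    write_fasta(recs, paste0(path, ".fasta"))
  }
  invisible(path)
}

#' Parse HMMER per-domain tabular output (domtblout)
#'
#' Reads the whitespace-delimited per-domain table written by profile-HMM
#' search tools ('#' lines are comments; 22 fixed columns plus a free-text
#' description). Alignment coordinates, printed 1-based inclusive, are
#' converted to this package's 0-based half-open convention.
#'
#' @param path Path to a domtblout file.
#' @return Data frame with `candidate_id`, `domain_name`, `accession`,
#'   `e_value` (the per-domain independent E-value), `ali_start`, `ali_end`.
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout row at line ", i, ": expected >= 22 columns, got ",
           length(f))
    data.frame(candidate_id = f[1], domain_name = f[4], accession = f[5],
               e_value = as.numeric(f[13]),
               ali_start = as.integer(f[18]) - 1L,   # 1-based -> 0-based
               ali_end = as.integer(f[19]),          # inclusive -> half-open
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(candidate_id = character(), domain_name = character(),
                  accession = character(), e_value = numeric(),
                  ali_start = integer(), ali_end = integer())
  rownames(out) <- NULL
  out
}

#' Attach domain annotations to mined candidates
#'
#' Annotation never changes scores or ranking; it adds a `domains` column
#' (comma-separated `name(accession)` with E-value <= `e_max`) and an
#' `annotated` flag. Hits referencing unknown candidate ids are skipped with
#' a warning.
#'
#' @param candidates Candidate data frame (from [mine_reads()]
#'   `$candidates`) with a `peptide` column; hits are matched on
#'   `candidate_id` against a `candidate_id` column if present, else against
#'   the peptide string.
#' @param hits Data frame from [parse_domtblout()].
#' @param e_max Maximum E-value for a hit to be attached.
#' @return The candidate data frame with `domains` and `annotated` columns.
#' @export
annotate_candidates <- function(candidates, hits, e_max = 0.01) {
  key <- if ("candidate_id" %in% names(candidates))
    candidates$candidate_id else candidates$peptide
  unknown <- setdiff(unique(hits$candidate_id), key)
  if (length(unknown))
    warning("skipping hit(s) for unknown candidate id(s): ",
            paste(unknown, collapse = ", "))
  hits <- hits[hits$candidate_id %in% key & hits$e_value <= e_max, ,
               drop = FALSE]
  lab <- vapply(key, function(k) {
    h <- hits[hits$candidate_id == k, , drop = FALSE]
    if (!nrow(h)) "" else
      paste(sprintf("%s(%s)", h$domain_name, h$accession), collapse = ",")
  }, character(1))
  candidates$domains <- unname(lab)
  candidates$annotated <- nzchar(candidates$domains)
  candidates
}
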