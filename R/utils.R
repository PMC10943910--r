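# Shared validation and RNG helpers.

.assert_peptide <- function(peptide, arg = "peptide") {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide))
    stop(arg, " must be a single character string")
  if (!nzchar(peptide)) stop(arg, " must be non-empty")
  bad <- setdiff(unique(strsplit(peptide, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    stop(arg, " contains non-canonical residue(s): ",
         paste(bad, collapse = ", "))
  invisible(peptide)
}

.peptide_codes <- function(peptide) {
  match(strsplit(peptide, "")[[1]], AA_ALPHABET)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
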