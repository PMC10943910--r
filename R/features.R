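#' Composition features and discriminative feature selection
#'
#' The classifier's feature space: 20 mono-residue frequencies (alphabetical
#' by one-letter code) followed by 400 overlapping-dipeptide frequencies
#' (lexicographic AA..YY). This column order is a frozen contract; trained
#' models reference features by these names.
#'
#' @name features
NULL

#' Names of the 420 composition features, in frozen order
#'
#' @return Character vector: the 20 residues then the 400 dipeptides.
#' @export
feature_names <- function() {
  c(AA_ALPHABET,
    as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0))))
}

#' Mono-residue composition
#'
#' @inheritParams elemental_formula
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
mono_composition <- function(peptide) {
  .assert_peptide(peptide)
  codes <- .peptide_codes(peptide)
  stats::setNames(tabulate(codes, 20L) / length(codes), AA_ALPHABET)
}

#' Overlapping dipeptide composition
#'
#' Bigram counts divided by (length - 1); a length-1 peptide yields the
#' all-zero vector.
#'
#' @inheritParams elemental_formula
#' @return Named numeric vector of 400 frequencies (lexicographic AA..YY).
#' @export
dipeptide_composition <- function(peptide) {
  .assert_peptide(peptide)
  codes <- .peptide_codes(peptide)
  nm <- feature_names()[-(1:20)]
  n <- length(codes)
  if (n < 2L) return(stats::setNames(numeric(400L), nm))
  idx <- (codes[-n] - 1L) * 20L + codes[-1L]
  stats::setNames(tabulate(idx, 400L) / (n - 1L), nm)
}

.composition_row <- function(codes) {
  n <- length(codes)
  mono <- tabulate(codes, 20L) / n
  di <- if (n < 2L) numeric(400L)
  else tabulate((codes[-n] - 1L) * 20L + codes[-1L], 400L) / (n - 1L)
  c(mono, di)
}

# n x 420 composition matrix for a character vector of peptides.
.composition_matrix <- function(peptides) {
  m <- matrix(0, nrow = length(peptides), ncol = 420L,
              dimnames = list(names(peptides), feature_names()))
  split_codes <- lapply(strsplit(peptides, ""), match, table = AA_ALPHABET)
  for (i in seq_along(peptides)) {
    codes <- split_codes[[i]]
    if (anyNA(codes))
      stop("peptide ", i, " contains non-canonical residues")
    m[i, ] <- .composition_row(codes)
  }
  m
}

#' Build a labelled feature table from peptides
#'
#' @param peptides Character vector of peptide sequences, or a protein
#'   sequence data frame (see [seqio]).
#' @param labels Factor or character vector of class labels, `"ACP"` /
#'   `"nonACP"`; omit for an unlabelled table.
#' @return A data frame with a `label` factor column (if labels given)
#'   followed by the 420 feature columns, rows in input order.
#' @export
featurize_set <- function(peptides, labels = NULL) {
  if (is.data.frame(peptides)) {
    ids <- peptides$id
    peptides <- stats::setNames(peptides$sequence, ids)
  }
  m <- .composition_matrix(peptides)
  out <- as.data.frame(m)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("ACP", "nonACP"))
    if (length(bad)) stop("labels must be ACP or nonACP; got: ",
                          paste(bad, collapse = ", "))
    if (length(labels) != nrow(out))
      stop("labels length does not match number of peptides")
    out <- cbind(label = factor(labels, levels = c("ACP", "nonACP")), out)
  }
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. The degenerate case of two constant, equal groups
#' is defined (not an error) as t = 0, p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance Student test instead.
#' @return List with `t_stat`, `df`, `p_raw`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, df = length(a) + length(b) - 2, p_raw = 1))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_raw = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value)
}

#' Select class-discriminative features (t-test + Bonferroni)
#'
#' Per-feature two-sided t-tests between the ACP and nonACP groups, with
#' Bonferroni family-wise correction. Features with zero variance in both
#' groups are untestable: they are excluded from the Bonferroni multiplier m
#' and never selected. A feature is selected iff `min(1, m * p_raw) < alpha`.
#'
#' @param table Labelled feature table from [featurize_set()].
#' @param alpha Family-wise significance level.
#' @param var_equal Use the Student instead of the Welch test.
#' @return Data frame with one row per feature: `feature_id`, `t_stat`,
#'   `df`, `p_raw`, `p_adj`, `testable`, `selected`.
#' @export
select_features <- function(table, alpha = 0.05, var_equal = FALSE) {
  if (!"label" %in% names(table)) stop("table must have a label column")
  lab <- table$label
  for (lv in c("ACP", "nonACP"))
    if (sum(lab == lv) < 2L)
      stop("need at least 2 rows per class; ", lv, " has ", sum(lab == lv))
  x <- as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
  ia <- lab == "ACP"; ib <- lab == "nonACP"
  va <- apply(x[ia, , drop = FALSE], 2L, stats::var)
  vb <- apply(x[ib, , drop = FALSE], 2L, stats::var)
  testable <- va > 0 | vb > 0
  m <- sum(testable)
  res <- data.frame(feature_id = colnames(x),
                    t_stat = NA_real_, df = NA_real_,
                    p_raw = NA_real_, p_adj = NA_real_,
                    testable = testable, selected = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in which(testable)) {
    w <- welch_t_test(x[ia, j], x[ib, j], var_equal = var_equal)
    res$t_stat[j] <- w$t_stat
    res$df[j] <- w$df
    res$p_raw[j] <- w$p_raw
  }
  res$p_adj[testable] <- pmin(1, m * res$p_raw[testable])
  res$selected[testable] <- res$p_adj[testable] < alpha
  attr(res, "m") <- m
  attr(res, "alpha") <- alpha
  res
}

#' Write a feature-selection result as delimited text
#' @param res Result of [select_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
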