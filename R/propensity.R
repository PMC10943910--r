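#' Windowed antimicrobial-propensity scanning
#'
#' Scans a peptide with a fixed-size window (default 5 residues), scoring
#' each window as the mean residue propensity under a 20-entry scale. A
#' residue is flagged active when it lies in at least one window whose score
#' strictly exceeds the threshold; maximal runs of flagged residues form the
#' reported regions, and their residue coverage is summarized as a
#' percentage of the peptide.
#'
#' @name propensity
NULL

#' Bundled antimicrobial propensity scale
#'
#' A generic stand-in scale (values in [0, 1], higher = more active) with
#' the cationic/aromatic preference typical of antimicrobial propensity
#' tools: high K, R, W, F, L; low D, E. It is a clearly labelled synthetic
#' stand-in, not the scale of any published server; users may load their own
#' with [read_scale()].
#'
#' @return Named numeric vector over the 20 residues.
#' @export
propensity_scale <- function() {
  v <- .residue_vector("synthetic_amp_propensity.tsv", "propensity")
  attr(v, "name") <- "synthetic_amp_propensity"
  v
}

#' Read a residue scale from tabular text
#'
#' @param path Two-column delimited file with a header: residue, value.
#' @return Named numeric vector over the 20 residues in [AA_ALPHABET] order.
#' @export
read_scale <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tbl) < 2L) stop("scale file needs residue + value columns")
  v <- tbl[[2L]]
  names(v) <- tbl[[1L]]
  if (!setequal(names(v), AA_ALPHABET))
    stop("scale file must cover exactly the 20 canonical residues")
  v[AA_ALPHABET]
}

#' Per-window propensity scores
#'
#' @inheritParams elemental_formula
#' @param scale Residue propensity scale (named numeric, 20 entries).
#' @param window Window size in residues.
#' @return Numeric vector of length `length - window + 1`; element i is the
#'   mean propensity of residues i..i+window-1 (1-based window start).
#' @export
window_scores <- function(peptide, scale = propensity_scale(), window = 5L) {
  .assert_peptide(peptide)
  if (!.is_count(window)) stop("window must be a positive integer")
  n <- nchar(peptide)
  if (n < window) stop("peptide shorter than the window")
  h <- unname(scale[.peptide_codes(peptide)])
  cs <- c(0, cumsum(h))
  stats::setNames((cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) /
                    window,
                  seq_len(n - window + 1L))
}

#' Flag active regions from window scores
#'
#' A residue is flagged iff it is covered by at least one window whose score
#' strictly exceeds `threshold`; maximal runs of flagged residues become
#' regions (1-based inclusive intervals).
#'
#' @param scores Window scores from [window_scores()] (1-based window
#'   starts as names or positions).
#' @param threshold Score threshold (strict inequality).
#' @param window Window size used to compute `scores`.
#' @return Data frame with `start`, `end` (1-based inclusive), possibly
#'   zero rows.
#' @export
flag_regions <- function(scores, threshold = 0.25, window = 5L) {
  n <- length(scores) + window - 1L
  flagged <- logical(n)
  above <- which(scores > threshold)
  for (i in above) flagged[i:(i + window - 1L)] <- TRUE
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Residue coverage of flagged regions
#'
#' @param regions Data frame of disjoint 1-based inclusive intervals within
#'   `[1, length]`.
#' @param length Peptide length in residues.
#' @return List with `percent` (unrounded) and `percent_rounded` (nearest
#'   integer).
#' @export
coverage_percent <- function(regions, length) {
  if (nrow(regions)) {
    if (any(regions$start < 1L | regions$end > length |
              regions$start > regions$end))
      stop("regions out of range or inverted")
    ord <- order(regions$start)
    if (any(regions$start[ord][-1L] <= regions$end[ord][-nrow(regions)]))
      stop("regions overlap")
  }
  pct <- 100 * sum(regions$end - regions$start + 1L) / length
  list(percent = pct, percent_rounded = as.integer(round(pct)))
}

#' Full propensity scan of a peptide
#'
#' @inheritParams window_scores
#' @param threshold Flagging threshold (strict).
#' @return Object of class `propensity_profile`: `peptide`, `window`,
#'   `threshold`, `scores`, `regions`, `coverage` (see
#'   [coverage_percent()]).
#' @export
scan_propensity <- function(peptide, scale = propensity_scale(),
                            window = 5L, threshold = 0.25) {
  scores <- window_scores(peptide, scale, window)
  regions <- flag_regions(scores, threshold, window)
  structure(list(peptide = peptide, window = window, threshold = threshold,
                 scale_name = attr(scale, "name"),
                 scores = scores, regions = regions,
                 coverage = coverage_percent(regions, nchar(peptide))),
            class = "propensity_profile")
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat("Antimicrobial propensity scan (window ", x$window,
      ", threshold ", x$threshold, ")\n", sep = "")
  cat("  peptide:", x$peptide, "\n")
  if (nrow(x$regions)) {
    cat("  flagged regions:",
        paste(sprintf("%d-%d", x$regions$start, x$regions$end),
              collapse = ", "), "\n")
  } else cat("  flagged regions: none\n")
  cat(sprintf("  coverage: %.1f%% (%d%% rounded)\n",
              x$coverage$percent, x$coverage$percent_rounded))
  invisible(x)
}

#' @export
plot.propensity_profile <- function(x, ...) {
  starts <- as.integer(names(x$scores))
  graphics::plot(starts, x$scores, type = "b", pch = 16,
                 xlab = "window start (residue)",
                 ylab = "mean propensity", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (nrow(x$regions))
    graphics::rect(x$regions$start, graphics::par("usr")[3], x$regions$end,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("tomato", 0.15), border = NA)
  invisible(x)
}

#' Write a propensity profile as delimited text
#' @param x A `propensity_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# peptide\t%s", x$peptide), con)
  writeLines(sprintf("# window\t%d\tthreshold\t%g", x$window, x$threshold),
             con)
  writeLines("window_start\tscore", con)
  writeLines(sprintf("%s\t%.6f", names(x$scores), x$scores), con)
  writeLines(sprintf("# region\t%d\t%d", x$regions$start, x$regions$end),
             con)
  writeLines(sprintf("# coverage_percent\t%.4f\t%d", x$coverage$percent,
                     x$coverage$percent_rounded), con)
  invisible(path)
}
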