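#' Terminal-extension design
#'
#' Proposes and scores short N- or C-terminal extensions of a base peptide
#' (the strategy behind prepending AAEK to a mined 30-mer core), quantifying
#' the change in formal charge, GRAVY and hydrophobic moment per residue,
#' optionally under a classifier-retention constraint.
#'
#' @name modify
NULL

.paste_extension <- function(base, extension, terminus) {
  if (terminus == "N") paste0(extension, base) else paste0(base, extension)
}

#' Score a single terminal extension
#'
#' The objective is the weighted sum
#' `w_charge * delta_charge + w_gravy * delta_gravy +
#'  w_moment * delta_moment_per_residue`, with deltas computed
#' modified-minus-base from scratch.
#'
#' @param base Base peptide.
#' @param extension Extension peptide (non-empty).
#' @param terminus `"N"` (prepend, default) or `"C"` (append).
#' @param weights Numeric length-3 vector `(charge, gravy, moment)`.
#' @param model Optional `acp_model`; when given, the candidate's calibrated
#'   score on the modified peptide is included.
#' @return One-row data frame: `extension`, `terminus`, `modified`,
#'   `delta_charge_integer`, `delta_gravy`, `delta_moment_per_residue`,
#'   `objective`, and `classifier_score` when a model is supplied.
#' @export
score_extension <- function(base, extension, terminus = c("N", "C"),
                            weights = c(charge = 1, gravy = 1, moment = 1),
                            model = NULL) {
  terminus <- match.arg(terminus)
  .assert_peptide(base, "base")
  .assert_peptide(extension, "extension")
  if (length(weights) != 3L || !all(is.finite(weights)))
    stop("weights must be three finite numbers")
  mod <- .paste_extension(base, extension, terminus)
  d_charge <- net_charge_integer(mod) - net_charge_integer(base)
  d_gravy <- gravy(mod) - gravy(base)
  d_moment <- hydrophobic_moment(mod) / nchar(mod) -
    hydrophobic_moment(base) / nchar(base)
  out <- data.frame(extension = extension, terminus = terminus,
                    modified = mod,
                    delta_charge_integer = d_charge,
                    delta_gravy = d_gravy,
                    delta_moment_per_residue = d_moment,
                    objective = weights[1L] * d_charge +
                      weights[2L] * d_gravy + weights[3L] * d_moment,
                    stringsAsFactors = FALSE)
  if (!is.null(model))
    out$classifier_score <- unname(acp_score(model, mod))
  out
}

# Vectorized deltas for all extensions of a fixed length at one terminus.
# Charge and GRAVY depend only on extension composition; the moment needs
# per-position residue identities plus the base's phase-shifted vector sum.
.extension_deltas <- function(base, ext_matrix, terminus,
                              gravy_scale = hydro_scale("kd"),
                              moment_scale = hydro_scale("eisenberg"),
                              delta_deg = 100) {
  k <- ncol(ext_matrix)
  nb <- nchar(base)
  n <- nb + k
  base_codes <- .peptide_codes(base)
  delta <- delta_deg * pi / 180
  charge_per <- stats::setNames(rep(0, 20), AA_ALPHABET)
  charge_per[c("K", "R")] <- 1; charge_per[c("D", "E")] <- -1
  d_charge <- rowSums(matrix(charge_per[ext_matrix], ncol = k))
  base_g <- gravy(base, gravy_scale)
  ext_gsum <- rowSums(matrix(gravy_scale[ext_matrix], ncol = k))
  d_gravy <- (ext_gsum + base_g * nb) / n - base_g
  # base residues occupy positions (k..n-1) for N-terminal extensions,
  # (0..nb-1) for C-terminal; extension positions are the complement.
  base_off <- if (terminus == "N") k else 0L
  ext_off <- if (terminus == "N") 0L else nb
  hb <- moment_scale[base_codes]
  ang_b <- (seq_len(nb) - 1L + base_off) * delta
  bx <- sum(hb * cos(ang_b)); by <- sum(hb * sin(ang_b))
  ang_e <- (seq_len(k) - 1L + ext_off) * delta
  he <- matrix(moment_scale[ext_matrix], ncol = k)
  ex <- he %*% cos(ang_e); ey <- he %*% sin(ang_e)
  mom <- sqrt((bx + ex)^2 + (by + ey)^2)
  base_mom <- hydrophobic_moment(base, moment_scale, delta_deg)
  d_moment <- drop(mom) / n - base_mom / nb
  list(d_charge = d_charge, d_gravy = d_gravy, d_moment = d_moment)
}

#' Search terminal extensions of a base peptide
#'
#' Exhaustive enumeration of all `20^length` extensions for `length <= 4`
#' (lexicographic order); for longer extensions a greedy per-position search
#' extends one residue at a time, keeping the best objective. Candidates are
#' ranked by objective descending with lexicographic tie-break. When a model
#' is supplied, candidates whose modified peptide scores below the model
#' threshold are excluded (classifier-retention constraint) and counted.
#'
#' @inheritParams score_extension
#' @param length Extension length in residues.
#' @param top_n Number of ranked candidates to return.
#' @return List of class `extension_search`: `candidates` (top-n data
#'   frame with deltas, objective and, with a model, `classifier_score`),
#'   `n_enumerated`, `n_excluded` (failed retention), `mode`
#'   (`"exhaustive"` or `"greedy"`).
#' @export
search_extensions <- function(base, length = 4L, terminus = c("N", "C"),
                              weights = c(charge = 1, gravy = 1, moment = 1),
                              model = NULL, top_n = 10L) {
  terminus <- match.arg(terminus)
  .assert_peptide(base, "base")
  if (!.is_count(length)) stop("length must be a positive integer")
  if (!.is_count(top_n)) stop("top_n must be a positive integer")
  if (length <= 4L) {
    grid <- do.call(expand.grid,
                    c(rev(replicate(length, AA_ALPHABET, simplify = FALSE)),
                      list(stringsAsFactors = FALSE)))
    ext_matrix <- as.matrix(grid[, rev(seq_len(length)), drop = FALSE])
    exts <- do.call(paste0, as.data.frame(ext_matrix))
    mode <- "exhaustive"
  } else {
    ext <- character(0)
    for (pos in seq_len(length)) {
      trials <- vapply(AA_ALPHABET, function(a)
        paste0(paste(ext, collapse = ""), a), character(1))
      obj <- vapply(trials, function(e)
        score_extension(base, e, terminus, weights)$objective, numeric(1))
      ext <- c(ext, AA_ALPHABET[which.max(obj)])
    }
    exts <- paste(ext, collapse = "")
    ext_matrix <- matrix(ext, nrow = 1L)
    mode <- "greedy"
  }
  d <- .extension_deltas(base, ext_matrix, terminus)
  cand <- data.frame(extension = exts, terminus = terminus,
                     delta_charge_integer = d$d_charge,
                     delta_gravy = d$d_gravy,
                     delta_moment_per_residue = d$d_moment,
                     objective = weights[1L] * d$d_charge +
                       weights[2L] * d$d_gravy + weights[3L] * d$d_moment,
                     stringsAsFactors = FALSE)
  n_enumerated <- nrow(cand)
  n_excluded <- 0L
  ord <- order(-cand$objective, cand$extension)
  cand <- cand[ord, , drop = FALSE]
  if (!is.null(model)) {
    # score lazily from the top until top_n retained candidates are found
    kept <- integer(0); scores <- numeric(0); i <- 1L
    while (length(kept) < top_n && i <= nrow(cand)) {
      take <- seq.int(i, min(i + 4L * top_n, nrow(cand)))
      mods <- .paste_extension(base, cand$extension[take], terminus)
      s <- unname(acp_score(model, mods))
      ok <- s > model$threshold
      n_excluded <- n_excluded + sum(!ok)
      kept <- c(kept, take[ok]); scores <- c(scores, s[ok])
      i <- max(take) + 1L
    }
    cand <- cand[utils::head(kept, top_n), , drop = FALSE]
    cand$classifier_score <- utils::head(scores, top_n)
  } else {
    cand <- utils::head(cand, top_n)
  }
  cand$modified <- .paste_extension(base, cand$extension, terminus)
  rownames(cand) <- NULL
  structure(list(candidates = cand, n_enumerated = n_enumerated,
                 n_excluded = n_excluded, mode = mode,
                 weights = weights, base = base),
            class = "extension_search")
}

#' @export
print.extension_search <- function(x, ...) {
  cat("Terminal-extension search (", x$mode, "): ", x$n_enumerated,
      " candidates enumerated, ", x$n_excluded,
      " excluded by classifier retention\n", sep = "")
  print(utils::head(x$candidates[, setdiff(names(x$candidates), "modified")],
                    10L))
  invisible(x)
}

#' Apply an extension and report properties before and after
#'
#' @inheritParams score_extension
#' @return List with `peptide` (the modified sequence), `before` and
#'   `after` ([property_report()] objects).
#' @export
apply_extension <- function(base, extension, terminus = c("N", "C")) {
  terminus <- match.arg(terminus)
  .assert_peptide(base, "base")
  .assert_peptide(extension, "extension")
  mod <- .paste_extension(base, extension, terminus)
  list(peptide = mod,
       before = property_report(base),
       after = property_report(mod))
}
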