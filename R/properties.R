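#' Physicochemical peptide descriptors
#'
#' Elemental formula, average/monoisotopic mass, net charge (formal counting
#' and Henderson-Hasselbalch), isoelectric point, GRAVY and the helical-wheel
#' hydrophobic moment. Residue formulas, masses, pKa sets and hydrophobicity
#' scales ship as plain tabular data files and are immutable at run time.
#'
#' @name properties
NULL

WATER_AVERAGE_MASS <- 18.01528
WATER_MONO_MASS <- 18.010565

#' Bundled pKa set
#'
#' Side-chain pKa values for D, E, C, Y, H, K, R plus the free N- and
#' C-terminus, from standard textbook compilations.
#'
#' @param name `"emboss"` (default) or `"lehninger"`.
#' @return A data frame with columns `group`, `pka`, `type` and a `name`
#'   attribute.
#' @export
pka_set <- function(name = c("emboss", "lehninger")) {
  name <- match.arg(name)
  tbl <- .load_table("pka_sets.tsv")
  out <- tbl[tbl$set == name, c("group", "pka", "type")]
  rownames(out) <- NULL
  attr(out, "name") <- name
  out
}

#' Bundled hydrophobicity scale
#'
#' `"kd"` is the Kyte-Doolittle hydropathy scale (the GRAVY default);
#' `"eisenberg"` is the Eisenberg consensus scale (the hydrophobic-moment
#' default).
#'
#' @param name Scale name.
#' @return Named numeric vector over the 20 residues, in [AA_ALPHABET] order.
#' @export
hydro_scale <- function(name = c("kd", "eisenberg")) {
  name <- match.arg(name)
  v <- .residue_vector("hydrophobicity_scales.tsv", name)
  attr(v, "name") <- name
  v
}

#' Elemental formula of a peptide
#'
#' Sum of residue formulas plus one water; free unmodified termini assumed.
#'
#' @param peptide Peptide string over the 20 canonical residues.
#' @return Named integer vector with counts for C, H, N, O, S, of class
#'   `elemental_formula`.
#' @export
elemental_formula <- function(peptide) {
  .assert_peptide(peptide)
  tbl <- .load_table("residue_formulas.tsv")
  m <- as.matrix(tbl[, c("C", "H", "N", "O", "S")])
  rownames(m) <- tbl$residue
  f <- colSums(m[.peptide_codes(peptide), , drop = FALSE])
  f["H"] <- f["H"] + 2L   # + H2O
  f["O"] <- f["O"] + 1L
  structure(as.integer(f), names = colnames(m), class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  keep <- x > 0L
  paste0(names(x)[keep], ifelse(x[keep] == 1L, "", x[keep]), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Average (or monoisotopic) mass of a peptide in Daltons
#'
#' @inheritParams elemental_formula
#' @param monoisotopic Use monoisotopic instead of average residue masses.
#' @return Mass in Da.
#' @export
average_mass <- function(peptide, monoisotopic = FALSE) {
  .assert_peptide(peptide)
  col <- if (monoisotopic) "monoisotopic" else "average"
  masses <- .residue_vector("residue_masses.tsv", col)
  water <- if (monoisotopic) WATER_MONO_MASS else WATER_AVERAGE_MASS
  sum(masses[.peptide_codes(peptide)]) + water
}

#' Formal integer net charge
#'
#' The counting rule (#K + #R) - (#D + #E): histidine and the termini are
#' excluded. This is the convention of peptide-synthesis data sheets, where a
#' cationic peptide's charge is quoted as a small positive integer; the
#' pH-graded alternative is [net_charge_hh()].
#'
#' @inheritParams elemental_formula
#' @return Signed integer.
#' @export
net_charge_integer <- function(peptide) {
  .assert_peptide(peptide)
  cnt <- tabulate(.peptide_codes(peptide), nbins = 20L)
  names(cnt) <- AA_ALPHABET
  as.integer(cnt["K"] + cnt["R"] - cnt["D"] - cnt["E"])
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' Basic groups (K, R, H side chains and the N-terminus) contribute
#' `1 / (1 + 10^(pH - pKa))`; acidic groups (D, E, C, Y side chains and the
#' C-terminus) contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @inheritParams elemental_formula
#' @param pH pH in [0, 14].
#' @param pka A pKa set from [pka_set()].
#' @param termini Include the free terminal groups (default TRUE).
#' @return Net charge (real).
#' @export
net_charge_hh <- function(peptide, pH = 7, pka = pka_set(),
                          termini = TRUE) {
  .assert_peptide(peptide)
  if (!is.numeric(pH) || any(pH < 0 | pH > 14))
    stop("pH must lie in [0, 14]")
  cnt <- tabulate(.peptide_codes(peptide), nbins = 20L)
  names(cnt) <- AA_ALPHABET
  groups <- pka$group
  counts <- ifelse(groups %in% c("Nterm", "Cterm"),
                   as.integer(termini), cnt[groups])
  counts[is.na(counts)] <- 0L
  vapply(pH, function(ph) {
    pos <- sum(counts[pka$type == "basic"] /
                 (1 + 10^(ph - pka$pka[pka$type == "basic"])))
    neg <- sum(counts[pka$type == "acidic"] /
                 (1 + 10^(pka$pka[pka$type == "acidic"] - ph)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Root of [net_charge_hh()] on [0, 14]; the charge is strictly decreasing in
#' pH, so the root is unique when both signs are attained.
#'
#' @inheritParams net_charge_hh
#' @param tol Bisection tolerance on the charge (default 1e-3).
#' @return pI in pH units, with `abs(net_charge_hh(pI)) < tol`.
#' @export
isoelectric_point <- function(peptide, pka = pka_set(), termini = TRUE,
                              tol = 1e-3) {
  .assert_peptide(peptide)
  f <- function(ph) net_charge_hh(peptide, ph, pka, termini)
  lo <- 0; hi <- 14
  c_lo <- f(lo); c_hi <- f(hi)
  if (c_lo == 0 && c_hi == 0)
    stop("peptide has no ionizable groups; pI is undefined")
  if (c_lo < 0 || c_hi > 0)
    stop("net charge does not change sign on [0, 14]; pI is undefined")
  repeat {
    mid <- (lo + hi) / 2
    c_mid <- f(mid)
    if (abs(c_mid) < tol) return(mid)
    if (c_mid > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12)
      stop("bisection failed to converge")   # unreachable for monotone charge
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' @inheritParams elemental_formula
#' @param scale A hydrophobicity scale from [hydro_scale()] (default
#'   Kyte-Doolittle).
#' @return Mean per-residue scale value.
#' @export
gravy <- function(peptide, scale = hydro_scale("kd")) {
  .assert_peptide(peptide)
  mean(scale[.peptide_codes(peptide)])
}

#' Hydrophobic moment (amphipathicity)
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed at
#' successive angles of `delta_deg` degrees around a helical wheel
#' (100 degrees/residue for an alpha helix, 160 for a beta strand).
#'
#' @inheritParams gravy
#' @param scale Scale from [hydro_scale()] (default Eisenberg consensus).
#' @param delta_deg Angular step per residue, in degrees.
#' @return Total moment; divide by length for the per-residue moment.
#' @export
hydrophobic_moment <- function(peptide, scale = hydro_scale("eisenberg"),
                               delta_deg = 100) {
  .assert_peptide(peptide)
  h <- scale[.peptide_codes(peptide)]
  ang <- (seq_along(h) - 1L) * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2)
}

#' Full physicochemical report for a peptide
#'
#' @inheritParams elemental_formula
#' @param pka pKa set for the charge/pI calculations.
#' @param gravy_scale Scale for GRAVY.
#' @param moment_scale Scale for the hydrophobic moment.
#' @param delta_deg Helical angular step for the moment.
#' @return An object of class `peptide_properties`: a list with fields
#'   `peptide`, `length`, `formula`, `average_mass`, `net_charge_integer`,
#'   `net_charge_at_pH7`, `pI`, `gravy`, `hydrophobic_moment`,
#'   `moment_per_residue`.
#' @export
property_report <- function(peptide, pka = pka_set(),
                            gravy_scale = hydro_scale("kd"),
                            moment_scale = hydro_scale("eisenberg"),
                            delta_deg = 100) {
  .assert_peptide(peptide)
  mom <- hydrophobic_moment(peptide, moment_scale, delta_deg)
  structure(list(
    peptide = peptide,
    length = nchar(peptide),
    formula = elemental_formula(peptide),
    average_mass = average_mass(peptide),
    net_charge_integer = net_charge_integer(peptide),
    net_charge_at_pH7 = net_charge_hh(peptide, 7, pka),
    pI = isoelectric_point(peptide, pka),
    gravy = gravy(peptide, gravy_scale),
    hydrophobic_moment = mom,
    moment_per_residue = mom / nchar(peptide)
  ), class = "peptide_properties")
}

#' @export
print.peptide_properties <- function(x, digits = 3, ...) {
  cat("Peptide property report\n")
  cat("  sequence:          ", x$peptide, "\n")
  cat("  length:            ", x$length, "residues\n")
  cat("  formula:           ", format(x$formula), "\n")
  cat("  average mass:      ", formatC(x$average_mass, format = "f",
                                       digits = 2), "Da\n")
  cat("  net charge (K+R-D-E):", sprintf("%+d", x$net_charge_integer), "\n")
  cat("  net charge at pH 7:", round(x$net_charge_at_pH7, digits), "\n")
  cat("  isoelectric point: ", round(x$pI, digits), "\n")
  cat("  GRAVY:             ", round(x$gravy, digits), "\n")
  cat("  hydrophobic moment:", round(x$hydrophobic_moment, digits),
      sprintf("(%s per residue)", round(x$moment_per_residue, digits)), "\n")
  invisible(x)
}

#' Serialize a property report to flat key-value text
#'
#' @param x A `peptide_properties` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_properties <- function(x, path) {
  stopifnot(inherits(x, "peptide_properties"))
  vals <- c(peptide = x$peptide,
            length = x$length,
            formula = format(x$formula),
            average_mass = sprintf("%.4f", x$average_mass),
            net_charge_integer = x$net_charge_integer,
            net_charge_at_pH7 = sprintf("%.6f", x$net_charge_at_pH7),
            pI = sprintf("%.4f", x$pI),
            gravy = sprintf("%.6f", x$gravy),
            hydrophobic_moment = sprintf("%.6f", x$hydrophobic_moment),
            moment_per_residue = sprintf("%.6f", x$moment_per_residue))
  writeLines(paste(names(vals), vals, sep = "\t"), path)
  invisible(path)
}
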