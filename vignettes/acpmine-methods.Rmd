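---
title: "Methods: composition-based ACP mining and peptide design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based ACP mining and peptide design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`acpmine` implements an in-silico workflow for deriving anticancer peptide
(ACP) candidates from metagenomic sequencing reads. The workflow has five
scientific components:

1. **Translation bridge.** DNA reads are translated in all six reading
   frames under the standard genetic code; fragments are split at stop
   codons and at any codon containing an ambiguous base.
2. **Candidate enumeration.** Every contiguous window of length 5 up to 50
   residues over every fragment is a candidate peptide, deduplicated with
   full provenance.
3. **Composition classifier.** Peptides are represented by 20 mono-residue
   plus 400 overlapping-dipeptide frequencies. Class-discriminative
   features are chosen by per-feature Welch t-tests with Bonferroni
   family-wise correction, and a linear soft-margin SVM on the
   z-standardized selected features produces a calibrated score in [0, 1].
4. **Physicochemical characterization.** Elemental formula, average mass,
   formal and pH-dependent net charge, isoelectric point, GRAVY and the
   helical-wheel hydrophobic moment.
5. **Region scanning and terminal design.** A fixed-window
   antimicrobial-propensity scan flags active regions, and a terminal
   extension search quantifies how short N-/C-terminal additions change
   charge, hydrophobicity and amphipathicity.

## The translation bridge

How nucleotide reads become peptide candidates is this package's own
design decision: reads are not assembled; each read is translated
independently in six frames (`six_frame_translate()`), and a codon
containing N terminates a fragment rather than being guessed. Coordinates
are reported 0-based half-open on the forward strand, frames +1..+3 and
-1..-3 by the common convention (frame k starts at offset k-1 of its
strand). A direct protein-FASTA entry point (`read_fasta(...,
alphabet = "protein")`) bypasses translation for pre-translated inputs.
FASTQ qualities are parsed for integrity (a record whose quality string
does not match its sequence length is an error naming the record) and then
discarded: no quality computation belongs to this stage of the workflow.

Protein records containing non-canonical letters (B, J, O, U, X, Z) are
rejected with a warning by default, or rejected hard with
`invalid = "error"`; they are never silently altered, because composition
features are undefined for non-canonical letters.

## Composition features and selection

The feature order — the 20 residues alphabetically by one-letter code,
then the 400 dipeptides lexicographically — is a frozen contract
(`feature_names()`); saved models reference features by these names.
Dipeptide frequencies use overlapping bigrams normalized by length − 1,
the dominant convention in composition-based peptide classifiers; a
length-1 peptide has an all-zero dipeptide block by definition.

Selection uses the Welch (unequal-variance) t-test by default because the
two classes differ in composition variance by construction; the pooled
Student variant is available (`var_equal = TRUE`). Tests are two-sided:
the direction of enrichment is not pre-specified. The Bonferroni
multiplier `m` counts only *testable* features — those with non-zero
variance in at least one class — since adjusting by columns that cannot
reject at all would inflate the correction arbitrarily. A feature is
selected iff `min(1, m * p_raw) < alpha` with `alpha = 0.05` by default.

Whether the classifier should see only the selected features or all 420
is genuinely open; the package defaults to the selected set (it is the
better-conditioned choice at the default training size of 200 peptides
per class) and exposes `select = FALSE` for the full set.

## The classifier

`acp_fit()` standardizes the chosen features to zero mean and unit
variance (statistics frozen into the model, never recomputed at predict
time), fits a linear soft-margin SVM (regularization constant
`cost = 1`), and calibrates the decision values with a logistic fit on
the training decisions so scores live in [0, 1]. The linear kernel is
deliberate: with 420 interpretable frequency features, the weight vector
itself is the diagnostic (see `coef()` and `summary()`), and the
parameter-recovery tests demand that a planted discriminative residue
carry the largest weight. The decision threshold defaults to 0.5 with a
strict inequality: a score exactly at the threshold is non-ACP.

When perfectly separable data make the logistic calibration diverge, the
calibration falls back to the identity logistic map `plogis(d)`, keeping
scores monotone in the decision value. Models serialize to versioned
key-value text with an md5 checksum; numbers are written with 17
significant digits so a save/load round trip is bit-exact.

## Physicochemical descriptors

* **Elemental formula** is the sum of residue formulas plus one water;
  free unmodified termini are assumed throughout.
* **Average mass** uses a 4-decimal residue mass table derived from
  standard atomic average masses, so formula and mass agree through the
  atomic masses to well within 0.05 Da; monoisotopic masses are available
  behind a flag.
* **Integer net charge** is the counting rule (#K + #R) − (#D + #E),
  excluding histidine and the termini. This is the convention under which
  peptide-synthesis data sheets quote a cationic peptide's charge, and it
  is the mode used by the worked example (the bundled 34-mer is +5 with
  5 K, 3 R, 3 E). The physically graded alternative is the
  Henderson–Hasselbalch charge `net_charge_hh()`, whose basic groups (K,
  R, H, N-terminus) contribute `1/(1+10^(pH−pKa))` and acidic groups (D,
  E, C, Y, C-terminus) contribute `−1/(1+10^(pKa−pH))`.
* **Isoelectric point** is found by bisection of the HH charge on
  [0, 14] to a charge tolerance of 1e-3; the charge is strictly
  decreasing in pH so the root is unique whenever both signs occur. A
  peptide with no ionizable groups has no pI and raises an error.
* **pKa sets**: the bundled default is the EMBOSS compilation, with the
  Lehninger textbook set as an alternative; both ship as immutable data
  files. Predicted pI is tool- and pKa-set-dependent; this package makes
  the set explicit rather than matching any particular server's output.
* **Hydrophobicity**: GRAVY uses the Kyte–Doolittle hydropathy scale; the
  hydrophobic moment uses the Eisenberg consensus scale. Both are
  swappable by name or replaceable via `read_scale()`. The moment is the
  magnitude of the vector sum of per-residue values at successive angles
  of 100°/residue (α-helix; 160° available for β-strands), and its
  magnitude is invariant to the arbitrary starting angle.

## Propensity scanning

`scan_propensity()` scores every window of 5 residues as the mean residue
propensity and flags a residue when at least one covering window strictly
exceeds the threshold (default 0.25). Maximal runs of flagged residues
form the reported regions; residue coverage is their union size as a
percentage of the peptide, reported unrounded and rounded to the nearest
integer. The window-membership rule is chosen so a single above-threshold
window starting at residue 1 yields the residue interval 1–6 style of
report (window start indices map onto residue intervals); a
center-assignment alternative would shrink regions by window − 1. With
regions 1–6 and 12–16 on a 34-mer, 11 of 34 residues are covered: 32%
after rounding.

The bundled propensity scale is a clearly labelled **synthetic stand-in**
(`synthetic_amp_propensity.tsv`) with the cationic/aromatic preference
typical of antimicrobial propensity methods. Published servers do not
print their scales; reproducing any particular server's per-window
probabilities is a non-goal, and users may supply a scale file.

## Terminal extension design

`search_extensions()` generalizes the hand-designed strategy of
prepending a short cassette (such as AAEK) to a mined core peptide. The
objective is `w_charge·Δcharge + w_gravy·ΔGRAVY + w_moment·Δ(moment per
residue)` with default weights (1, 1, 1) — no published objective exists
for this step, so the weights are explicit, logged configuration. All
20^k extensions are enumerated exhaustively for k ≤ 4 (160 000 at k = 4,
vectorized closed-form deltas); beyond that a documented greedy
per-position approximation is used. When a model is supplied, candidates
whose modified peptide drops below the classifier threshold are excluded
and counted (classifier-retention constraint).

One honest discrepancy deserves note: the AAEK cassette contains one
lysine and one glutamate, so its formal charge delta under the counting
rule is exactly 0, even though such extensions are usually motivated as
increasing charge and hydrophobicity. The package reports deltas as
computed and does not adjust any rule to match a qualitative expectation.

## What the synthetic generator emulates — and what it does not

The generator stands in for curated ACP/non-ACP training collections and
for metagenomic read sets, which cannot be bundled.

* The **ACP-like profile** (bundled `class_profiles.tsv`) is strongly
  cationic and hydrophobic/aromatic: K 0.15, R 0.12, L 0.11, W 0.10,
  F 0.10, acidic residues at 0.015, all other residues 0.03. K + R make
  up 27% of residues, matching the pronounced cationic bias of validated
  ACPs, against a uniform 5% background profile. Default lengths are
  uniform on 10–50 residues — curated ACP collections contain few
  peptides under 10 residues, while 50 is the upper bound the mining
  window uses.
* **Residues are i.i.d. within a class** (or first-order Markov when a
  dipeptide shift is planted). Real peptides have positional structure —
  amphipathic periodicity, terminal biases — that i.i.d. sampling does
  not reproduce. Composition-feature methods are blind to residue order,
  so this is sufficient for testing them, but passing tests here say
  nothing about performance on real sequence structure.
* **Reads** embed each reverse-translated peptide (uniform random codon
  choice; codon bias is irrelevant in peptide space) flanked by stop
  codons at a random offset and strand inside random-base reads of 300 nt
  by default (150 nt in the scaled test configurations). Stop-flanking
  makes every planted peptide an exact translated fragment, giving the
  mining round-trip a sharp ground truth. There is no sequencing-error
  model, no quality realism and no community structure.

`plant_feature_shift()` raises one residue frequency by `delta` and
renormalizes the remaining mass proportionally (a +0.10 shift in K on a
uniform profile gives K = 0.15 and 0.85/19 elsewhere, exactly); dipeptide
shifts boost one transition probability of the first-order chain.

## Problem sizes and numerical choices

The packaged evaluations use: 200 peptides per class for training and
held-out evaluation; 1000 replicates of 50-per-class complete-null sets
for the family-wise-error check; 100 replicates of 200-per-class sets for
planted-feature recovery; and 12 planted peptides (20–40 residues) among
20 background reads of 150 nt for the mining round trip. These sizes give
stable estimates (binomial standard errors of a few percent) at desk-scale
runtimes.

Ties in candidate ranking break by (shorter peptide first, then
lexicographic); extension ranking breaks ties lexicographically — both
purely for determinism. Degenerate inputs are defined rather than left to
chance: two constant equal groups give t = 0, p = 1; a length-1 peptide
has a zero dipeptide block; a read shorter than one codon translates to
nothing; an empty region set has 0% coverage.

## Known limitations

* Candidate counts from real metagenomic data depend on the source
  library and thresholds; no count is a reproduction target.
* Domain annotation (`parse_domtblout()`) is a parse-only adapter over
  externally produced profile-HMM search output; the package does not
  score HMMs.
* The classifier is a fresh implementation trained on synthetic or
  user-provided sets; it does not reproduce the weights or scores of any
  hosted prediction server.
* Isoelectric points and hydrophobicities are scale- and
  pKa-set-dependent; values from different tools are not directly
  comparable.
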