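test_that("elemental formula reproduces free glycine and the 34-mer", {
  g <- elemental_formula("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O", "S")],
               c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
  f <- elemental_formula(PEP34)
  expect_equal(unclass(f)[c("C", "H", "N", "O")],
               c(C = 197L, H = 312L, N = 52L, O = 49L))
  expect_equal(format(f), "C197H312N52O49")
})

test_that("peptide-bond condensation: formula(ab) = formula(a)+formula(b)-H2O", {
  set.seed(21)
  for (rep in 1:15) {
    a <- random_peptide(sample(1:20, 1))
    b <- random_peptide(sample(1:20, 1))
    lhs <- unclass(elemental_formula(paste0(a, b)))
    rhs <- unclass(elemental_formula(a)) + unclass(elemental_formula(b)) -
      c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)
    expect_equal(lhs, rhs)
  }
})

test_that("average mass matches the data sheet and is additive", {
  expect_equal(average_mass("G"), 75.07, tolerance = 0.01)
  expect_lt(abs(average_mass(PEP34) - 4192.92), 0.05)
  set.seed(22)
  for (rep in 1:10) {
    a <- random_peptide(sample(2:30, 1))
    b <- random_peptide(sample(2:30, 1))
    expect_equal(average_mass(paste0(a, b)),
                 average_mass(a) + average_mass(b) - 18.01528,
                 tolerance = 1e-9)
  }
})

test_that("formula and mass agree through atomic masses", {
  atomic <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
              S = 32.065)
  set.seed(23)
  for (rep in 1:20) {
    p <- random_peptide(sample(1:50, 1))
    via_formula <- sum(unclass(elemental_formula(p)) * atomic)
    expect_lt(abs(average_mass(p) - via_formula), 0.05)
  }
})

test_that("integer net charge follows the K+R-D-E counting rule", {
  expect_identical(net_charge_integer(PEP34), 5L)
  expect_identical(net_charge_integer("KRDE"), 0L)
  expect_identical(net_charge_integer("HHH"), 0L)  # H excluded by the mode
})

test_that("Henderson-Hasselbalch charge is monotone and has the right limits", {
  grid <- seq(0, 14, by = 0.5)
  for (p in c(PEP34, "KDYH", "GG")) {
    ch <- net_charge_hh(p, grid)
    expect_true(all(diff(ch) < 0))
  }
  # 34-mer at pH 0: 5 K + 3 R + N-terminus fully protonated, no H present
  expect_equal(net_charge_hh(PEP34, 0), 9, tolerance = 1e-3)
})

test_that("HH charge equals the term-by-term oracle to 1e-9", {
  pka <- pka_set()
  set.seed(24)
  peps <- c(PEP34, replicate(10, random_peptide(sample(2:40, 1))))
  for (p in peps)
    for (ph in c(2, 7, 11))
      expect_equal(net_charge_hh(p, ph, pka), oracle_charge(p, ph, pka),
                   tolerance = 1e-9)
})

test_that("isoelectric point is the bisection root of the HH charge", {
  pka <- pka_set()
  # glycine: only the termini ionize -> pI is their pKa midpoint
  mid <- mean(pka$pka[pka$group %in% c("Nterm", "Cterm")])
  expect_equal(isoelectric_point("G"), mid, tolerance = 0.01)
  expect_lt(abs(net_charge_hh("G", isoelectric_point("G"))), 1e-3)
  expect_gt(isoelectric_point("KK"), isoelectric_point("EE"))
  # 8 basic vs 3 acidic side chains: charge still positive at pH 7
  expect_gt(net_charge_hh(PEP34, 7), 0)
  expect_gt(isoelectric_point(PEP34), 7)
  expect_lt(abs(net_charge_hh(PEP34, isoelectric_point(PEP34))), 1e-3)
  expect_error(isoelectric_point("AAA", termini = FALSE), "ionizable")
})

test_that("GRAVY is the mean scale value and permutation-invariant", {
  kd <- hydro_scale("kd")
  expect_equal(gravy(strrep("W", 9)), unname(kd["W"]))
  set.seed(25)
  for (rep in 1:10) {
    p <- random_peptide(20)
    shuffled <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    expect_equal(gravy(p), gravy(shuffled), tolerance = 1e-12)
    chars <- strsplit(p, "")[[1]]
    expect_equal(gravy(p), sum(kd[chars]) / length(chars),
                 tolerance = 1e-12)
  }
})

test_that("hydrophobic moment matches the trigonometric oracle", {
  sc <- hydro_scale("eisenberg")
  expect_equal(hydrophobic_moment("W"), abs(sc[["W"]]))
  # 18 residues x 100 degrees = 5 full turns: vectors cancel
  expect_equal(hydrophobic_moment(strrep("L", 18)), 0, tolerance = 1e-9)
  set.seed(26)
  for (rep in 1:20) {
    p <- random_peptide(sample(2:40, 1))
    expect_equal(hydrophobic_moment(p), oracle_moment(p, sc),
                 tolerance = 1e-9)
    expect_equal(hydrophobic_moment(p, delta_deg = 160),
                 oracle_moment(p, sc, 160), tolerance = 1e-9)
  }
})

test_that("moment magnitude is invariant to the starting angle", {
  # re-indexing n -> n+k rotates the sum but not its magnitude: compare
  # against an oracle accumulated with an arbitrary phase offset
  sc <- hydro_scale("eisenberg")
  set.seed(27)
  for (rep in 1:10) {
    p <- random_peptide(15)
    res <- strsplit(p, "")[[1]]
    for (k in c(1, 7)) {
      sx <- sum(sc[res] * cos((seq_along(res) - 1 + k) * 100 * pi / 180))
      sy <- sum(sc[res] * sin((seq_along(res) - 1 + k) * 100 * pi / 180))
      expect_equal(hydrophobic_moment(p), sqrt(sx^2 + sy^2),
                   tolerance = 1e-9)
    }
  }
})

test_that("property report aggregates the descriptors deterministically", {
  r <- property_report(PEP34)
  expect_s3_class(r, "peptide_properties")
  expect_equal(r$length, 34L)
  expect_equal(format(r$formula), "C197H312N52O49")
  expect_equal(r$net_charge_integer, 5L)
  expect_equal(r$moment_per_residue, r$hydrophobic_moment / 34)
  expect_identical(r, property_report(PEP34))
  g <- property_report("G")
  expect_equal(g$length, 1L)
  expect_equal(format(g$formula), "C2H5NO2")
  # serialization round trip through the key-value text format
  f <- withr::local_tempfile()
  write_properties(r, f)
  kv <- read.delim(f, header = FALSE, col.names = c("key", "value"))
  expect_equal(kv$value[kv$key == "formula"], "C197H312N52O49")
  expect_equal(as.numeric(kv$value[kv$key == "average_mass"]),
               r$average_mass, tolerance = 1e-4)
})

test_that("descriptors reject empty or non-canonical input", {
  expect_error(elemental_formula(""), "non-empty")
  expect_error(average_mass("AXB"), "non-canonical")
  expect_error(net_charge_hh("AK", pH = 15), "pH")
  expect_error(gravy(""), "non-empty")
})
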