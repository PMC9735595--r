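test_that("residue formulas match their definitions and reject unknowns", {
  expect_equal(residue_formula("G"), c(C = 2, H = 3, N = 1, O = 1))
  expect_equal(residue_formula("C"), c(C = 3, H = 5, N = 1, O = 1, S = 1))
  expect_error(residue_formula("X"), "X")
  expect_error(residue_formula("B"), "B")
})

test_that("formula algebra is consistent and never goes negative", {
  a <- parse_formula("C3H7NO2S")
  b <- parse_formula("H2O")
  expect_equal(formula_mass(formula_add(a, b)),
               formula_mass(a) + formula_mass(b))
  expect_equal(formula_subtract(formula_add(a, b), b), a)
  expect_error(formula_subtract(b, a), "negative")
  expect_error(parse_formula("C3Xx2"), "unknown element")
})

test_that("peptide masses agree with the residue-mass-table oracle", {
  # oracle: independent residue-mass summation (frozen Unimod table)
  expect_equal(peptide_mono_mass("VPCVS"), 503.2414, tolerance = 1e-4)
  expect_equal(peptide_mono_mass("VPCVS"), oracle_peptide_mass("VPCVS"),
               tolerance = 2e-5)
  set.seed(11)
  for (i in 1:20) {
    s <- random_sequence(sample(2:25, 1))
    expect_equal(peptide_mono_mass(s), oracle_peptide_mass(s),
                 tolerance = 1e-4)
  }
  expect_error(peptide_mono_mass(""), "non-empty")
})

test_that("peptide formula equals residue sum plus one water", {
  s <- "GASPV"
  f <- peptide_formula(s)
  acc <- c(H = 2, O = 1)
  for (aa in strsplit(s, "")[[1]]) acc <- formula_add(acc, residue_formula(aa))
  expect_equal(f, acc[names(f)])
})

test_that("carbamidomethylated albumin fragment matches the printed mass", {
  m <- peptide_mono_mass("ALVLIAFAQYLQQCPFEDHVK",
                         data.frame(name = "carbamidomethyl", pos = 14))
  expect_lt(abs(ppm_error(2489.2799, m)), 1)
  # site constraint enforced
  expect_error(
    peptide_mono_mass("ALVLIAFAQYLQQCPFEDHVK",
                      data.frame(name = "carbamidomethyl", pos = 1)),
    "not allowed")
  expect_error(peptide_mono_mass("AAAA", "carbamidomethyl"), "requires")
})

test_that("mass additivity: concatenation loses one water", {
  set.seed(21)
  for (i in 1:15) {
    a <- random_sequence(sample(1:12, 1))
    b <- random_sequence(sample(1:12, 1))
    expect_equal(peptide_mono_mass(paste0(a, b)),
                 peptide_mono_mass(a) + peptide_mono_mass(b) - 18.010565,
                 tolerance = 1e-6)
  }
})

test_that("disulfide mass is symmetric, loses 2 H, and needs cysteines", {
  m <- disulfide_mass("ALVLIAFAQYLQQCPFEDHVK", "VPCVS")
  expect_lt(abs(ppm_error(2933.484, m)), 1)
  # cystine from two free cysteines (C6H12N2O4S2 formula oracle)
  expect_equal(disulfide_mass("C", "C"),
               formula_mass(parse_formula("C6H12N2O4S2")), tolerance = 1e-9)
  expect_equal(disulfide_mass("C", "C"), 240.0239, tolerance = 1e-4)
  set.seed(31)
  for (i in 1:10) {
    a <- paste0(random_sequence(sample(1:10, 1)), "C")
    b <- paste0("C", random_sequence(sample(1:10, 1)))
    expect_identical(disulfide_mass(a, b), disulfide_mass(b, a))
    expect_equal(disulfide_mass(a, b),
                 peptide_mono_mass(a) + peptide_mono_mass(b) - 2.015650,
                 tolerance = 1e-6)
  }
  expect_error(disulfide_mass("AAAA", "VPCVS"), "no cysteine in the first")
  expect_error(disulfide_mass("VPCVS", "AAAA"), "no cysteine in the second")
})

test_that("the four printed thiol-adduct deltas reproduce to 4 decimals", {
  printed <- c(Cys = 119.0041, homoCys = 133.0198, CysGly = 176.0255,
               GSH = 305.0682)
  for (nm in names(printed)) {
    expect_lt(abs(adduct_delta(nm)$delta - printed[[nm]]), 5e-4)
  }
  expect_error(adduct_delta("nonsense"), "library")
})

test_that("every library delta matches the mass of its formula change", {
  lib <- delta_library()
  for (i in seq_len(nrow(lib))) {
    expect_lt(abs(lib$delta[i] - formula_mass(parse_formula(lib$formula[i]))),
              1e-4)
  }
  # disulfide-type adducts are free compound minus H2
  free_cys <- formula_mass(parse_formula("C3H7NO2S"))
  expect_equal(adduct_delta("Cys")$delta, free_cys - 2.015650,
               tolerance = 1e-6)
  # library round-trips through its plain-text serialization
  p <- withr::local_tempfile(fileext = ".tsv")
  write_delta_library(p)
  back <- read.delim(p)
  expect_equal(back$delta, lib$delta, tolerance = 1e-9)
})

test_that("m/z follows (M + z*proton)/z and rejects bad charges", {
  expect_equal(mz(100, 1), 101.00728, tolerance = 1e-5)
  expect_equal(mz(2933.482, 3), (2933.482 + 3 * 1.0072765) / 3)
  expect_equal(mz(2933.482, 4), 734.37778, tolerance = 1e-4)
  expect_error(mz(100, 0), "positive integer")
  expect_error(mz(100, -2), "positive integer")
  expect_error(mz(100, 1.5), "positive integer")
})

test_that("peptide_species recomputes mass from its parts", {
  sp <- peptide_species("VPCVS")
  expect_equal(sp$mono_mass, peptide_mono_mass("VPCVS"))
  # adduct link
  spa <- peptide_species(JM21, link = "Cys")
  expect_equal(spa$mono_mass,
               peptide_mono_mass(JM21) + adduct_delta("Cys")$delta,
               tolerance = 1e-6)
  # disulfide link to a partner species
  spx <- peptide_species("VPCVS", link = ALB_21_41)
  expect_equal(spx$mono_mass, disulfide_mass("VPCVS", ALB_21_41),
               tolerance = 1e-9)
  expect_error(peptide_species("AAAA", link = "Cys"), "cysteine")
  expect_error(peptide_species("VPCVS", link = "AAAA"), "cysteine")
})
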