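# Molecular-formula parsing and mass arithmetic

test_that("formula parsing handles plain, underscore and subscript dialects", {
  ref <- c(C = 16L, H = 32L, O = 2L)
  expect_identical(unclass(parse_formula("C16H32O2"))[names(ref)], ref)
  expect_identical(format(parse_formula("C_16_H_32_O_2_")), "C16H32O2")
  sub16 <- paste0("C", "₁₆", "H", "₃₂", "O", "₂")
  expect_identical(format(parse_formula(sub16)), "C16H32O2")
  expect_identical(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  expect_identical(format(parse_formula("")), "")
})

test_that("parse -> format -> parse round-trips", {
  for (f in c("C15H10O7", "C28H34O15", "H2O", "CH4", "C6H14N4O2", "C5H7NO3")) {
    expect_identical(unclass(parse_formula(format(parse_formula(f)))),
                     unclass(parse_formula(f)))
  }
})

test_that("malformed and unknown formulas are rejected", {
  expect_error(parse_formula("C16H32O2Xx"), "unknown element")
  expect_error(parse_formula("C16H32O2 extra!"), "malformed")
  expect_error(parse_formula("C0H2"), "zero")
  expect_error(mol_formula(c(C = -1L)), "negative")
})

test_that("nominal mass reproduces integer molecular weights", {
  expect_identical(nominal_mass("C16H32O2"), 256L) # palmitic acid
  expect_identical(nominal_mass("C30H50O2"), 442L) # betulin
  expect_identical(nominal_mass("C17H34O2"), 270L)
  expect_identical(nominal_mass(""), 0L)
  # against the independent token-sum oracle on all GC fixture rows
  gc <- bidens_gc_peaks()
  for (f in gc$formula) {
    expect_identical(nominal_mass(f), as.integer(oracle_nominal(f)))
  }
})

test_that("monoisotopic mass matches the independent isotope-table oracle", {
  expect_equal(monoisotopic_mass("C15H10O7"), 302.04265, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("H"), 1.00783, tolerance = 1e-5)
  expect_identical(monoisotopic_mass(""), 0)
  for (f in c("C21H20O12", "C6H14N4O2", "C11H12N2O2", "C32H54O2")) {
    expect_equal(monoisotopic_mass(f), oracle_mono(f), tolerance = 1e-10)
  }
})

test_that("mass additivity holds for formula sums", {
  set.seed(42)
  els <- c("C", "H", "N", "O", "S")
  for (i in 1:20) {
    f1 <- mol_formula(setNames(sample(0:12, 5, replace = TRUE), els))
    f2 <- mol_formula(setNames(sample(0:12, 5, replace = TRUE), els))
    fs <- formula_sum(f1, f2)
    expect_equal(monoisotopic_mass(fs),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
    expect_identical(nominal_mass(fs), nominal_mass(f1) + nominal_mass(f2))
  }
})

test_that("adduct m/z follows the proton-mass convention", {
  expect_equal(adduct_mz("C15H10O7", "[M-H]-"), 301.03537, tolerance = 1e-5)
  expect_equal(adduct_mz("C15H10O7", "[M-H]-"),
               oracle_mono("C15H10O7") - ORACLE_PROTON, tolerance = 1e-10)
  # polarity symmetry: two proton masses apart, for any composition
  for (f in c("C15H10O7", "C28H34O15", "C4H6O5")) {
    expect_equal(adduct_mz(f, "[M+H]+") - adduct_mz(f, "[M-H]-"),
                 2.014552, tolerance = 1e-5)
  }
  expect_error(adduct_spec("[M+2H]2+"), "unsupported")
  expect_error(adduct_spec("[M+Na]+"), "unsupported")
})

test_that("ppm error is the signed relative deviation", {
  expect_identical(ppm_error(463.0918, 463.0918), 0)
  for (t in c(100, 301.03537, 1000)) {
    expect_equal(ppm_error(t * (1 + 1e-5), t), 10, tolerance = 1e-9)
  }
  # the printed quercetin ion deviates far beyond its stated error
  expect_equal(ppm_error(301.0233, 301.03537), -40.1, tolerance = 0.2)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("ppm round-trip is exact", {
  f <- "C21H20O12"
  th <- adduct_mz(f, "[M-H]-")
  for (e in c(-15, -2, 0, 3.7, 19.9)) {
    expect_equal(ppm_error(th * (1 + e * 1e-6), th), e, tolerance = 1e-6)
  }
})

test_that("generate_formulas finds known compositions and validates input", {
  g <- generate_formulas(301.03537, "[M-H]-", 20,
                         bounds = c(C = 20, H = 30, N = 3, O = 10))
  expect_true("C15H10O7" %in% g$formula)
  expect_false(is.unsorted(abs(g$error_ppm)))
  # limiting case: zero tolerance recovers the exact-mass formulas only
  g0 <- generate_formulas(adduct_mz("C15H10O7", "[M-H]-"), "[M-H]-", 0,
                          bounds = c(C = 20, H = 30, N = 3, O = 10))
  expect_identical(g0$formula, "C15H10O7")
  expect_error(generate_formulas(-5, "[M-H]-", 20), "positive")
  expect_error(generate_formulas(301, "[M-H]-", 20, bounds = NULL), "bounds")
})

test_that("generate_formulas agrees with the brute-force enumerator", {
  set.seed(7)
  bounds <- c(C = 25, H = 40, N = 5, O = 12, S = 2)
  masses <- c(301.0354, runif(6, 80, 450))
  for (mz in masses) {
    for (ad in c("[M-H]-", "[M+H]+")) {
      shift <- if (ad == "[M-H]-") -ORACLE_PROTON else ORACLE_PROTON
      got <- sort(generate_formulas(mz, ad, 20, bounds = bounds)$formula)
      want <- oracle_enumerate(mz, shift, 20, bounds)
      expect_identical(got, want)
    }
  }
})
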