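test_that("residue mass table satisfies its structural invariants", {
  res <- amino_acid_masses()
  expect_true(all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in% names(res)))
  expect_identical(res[["L"]], res[["I"]])
  expect_true(all(res > 0))
  expect_equal(round(chem_constants()[["se_minus_s_delta"]], 2), 47.94)
})

test_that("peptide_mass reproduces worked examples", {
  expect_equal(peptide_mass(peptide("G")), 75.032, tolerance = 1e-3)
  expect_equal(round_half_up(peptide_mass(parse_peptide("FCSeH")), 3), 453.092)
  p <- peptide("MPGP", se_sites = 1, nterm_mod = "acetyl")
  expect_equal(round_half_up(peptide_mass(p), 3), 490.133)
  expect_error(peptide(""), "non-empty")
  expect_error(peptide("AZB"), "position 2")
})

test_that("mass_to_mz protonates correctly and rejects bad charge", {
  proton <- chem_constants()[["proton_mass"]]
  expect_equal(mass_to_mz(0, 1), proton)
  expect_equal(mass_to_mz(490.1331, 1), 491.1403, tolerance = 1e-4)
  expect_lt(mass_to_mz(500, 2), mass_to_mz(500, 1))
  expect_error(mass_to_mz(500, 0), ">= 1")
})

test_that("ppm_error reproduces reported values under the truncation convention", {
  p <- parse_peptide("Ac-CSeGF")
  theo <- mass_to_mz(peptide_mass(p), 1)
  expect_equal(ppm_error(theo, p, 1), 0)
  expect_equal(reported_ppm(ppm_error(416.0704, p, 1)), -3.6)
  q <- parse_peptide("Ac-CSeACL")
  expect_equal(reported_ppm(ppm_error(499.1052, q, 1)), -14.4)
  expect_error(ppm_error(-1, p, 1), "positive")
})

test_that("display names parse back to the same peptide", {
  p <- parse_peptide("MSePGP")
  expect_identical(p$residues, c("M", "P", "G", "P"))
  expect_identical(p$se_sites, 1L)
  q <- parse_peptide("CSeCPT")
  expect_identical(q$se_sites, 1L)
  expect_error(parse_peptide("ASeT"), "only follow C or M")
  expect_error(parse_peptide("BGT"), "unknown residue")
  set.seed(11)
  for (i in 1:50) {
    p <- random_test_peptide(sample(2:5, 1))
    expect_identical(parse_peptide(display_name(p))$residues, p$residues)
    expect_identical(parse_peptide(display_name(p))$se_sites, p$se_sites)
  }
})

test_that("mass arithmetic is additive and each Se site adds one fixed delta", {
  set.seed(7)
  water <- chem_constants()[["water_mass"]]
  for (i in 1:25) {
    a <- random_test_peptide(sample(2:4, 1), allow_se = FALSE)
    b <- random_test_peptide(sample(2:4, 1), allow_se = FALSE)
    ab <- peptide(c(a$residues, b$residues))
    expect_equal(peptide_mass(ab), peptide_mass(a) + peptide_mass(b) - water,
                 tolerance = 1e-9)
  }
  bare <- peptide("CMCA")
  for (sites in list(1L, c(1L, 2L), c(1L, 2L, 3L))) {
    sub <- peptide("CMCA", se_sites = sites)
    expect_equal(peptide_mass(sub) - peptide_mass(bare),
                 47.94445 * length(sites), tolerance = 1e-4)
  }
})

test_that("modification constraints are enforced", {
  expect_error(peptide("AGT", se_sites = 1), "restricted to C and M")
  expect_error(peptide("CGT", se_sites = 5), "bounds")
  expect_error(peptide("AGT", nterm_mod = "carbamidomethyl"), "N-terminal")
  expect_error(peptide("CGT", site_mods = c("1" = "acetyl")), "not allowed")
  expect_silent(peptide("CGT", site_mods = c("1" = "carbamidomethyl")))
})

test_that("chemistry defaults can be overridden from a flat config file", {
  cfgfile <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("residue_G: 60.5", "water_mass: 18.0"), cfgfile)
  chem <- load_chem_config(cfgfile)
  expect_equal(chem$residues[["G"]], 60.5)
  expect_equal(chem$constants[["water_mass"]], 18.0)
  expect_equal(peptide_mass(peptide("G", chem = chem), chem = chem), 78.5)
  writeLines("residue_B: 1.0", cfgfile)
  expect_error(load_chem_config(cfgfile), "unknown residue letter")
  writeLines("frag_tol: 0.3", cfgfile)
  expect_error(load_chem_config(cfgfile), "unknown chemistry config key")
})

test_that("every reference mass is reproduced by a discovered modification assignment", {
  ref <- resolve_reference_mods()
  expect_true(all(ref$mass_reproduced))
  expect_identical(ref$computed_mass_da, ref$mass_da)
  # acetylated and unmodified assignments both occur
  expect_true(any(ref$nterm_mod == "acetyl", na.rm = TRUE))
  expect_true(anyNA(ref$nterm_mod))
})
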