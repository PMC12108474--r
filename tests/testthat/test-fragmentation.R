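test_that("fragment ladders reproduce worked ion values", {
  p <- parse_peptide("MSePGP")
  lad <- fragment_ladder(p)
  y2 <- lad$mz[lad$series == "y" & lad$index == 2]
  expect_equal(y2, 173.092, tolerance = 1e-3)
  ac <- peptide("MPGP", se_sites = 1, nterm_mod = "acetyl")
  lad_ac <- fragment_ladder(ac)
  b2 <- lad_ac$mz[lad_ac$series == "b" & lad_ac$index == 2]
  expect_equal(b2, 319.056, tolerance = 1e-3)
  di <- fragment_ladder(peptide("AG"), z_max = 2)
  expect_equal(nrow(di), 4)  # b1, y1 at each of two charges
  expect_error(fragment_ladder(peptide("A")), "length >= 2")
})

test_that("b/y pairs are complementary and Se shifts propagate through the ladder", {
  proton <- chem_constants()[["proton_mass"]]
  set.seed(21)
  for (i in 1:100) {
    p <- random_test_peptide(sample(2:6, 1))
    lad <- fragment_ladder(p)
    n <- length(p$residues)
    b <- lad$mz[lad$series == "b"]
    y <- lad$mz[lad$series == "y"]
    expect_equal(b + rev(y), rep(peptide_mass(p) + 2 * proton, n - 1),
                 tolerance = 1e-4)
  }
  # single Se at position k shifts exactly the spanning fragments
  bare <- peptide("ACGMT")
  sub <- peptide("ACGMT", se_sites = 4)
  l0 <- fragment_ladder(bare)
  l1 <- fragment_ladder(sub)
  d <- l1$mz - l0$mz
  n <- 5; k <- 4
  shifted <- (l1$series == "b" & l1$index >= k) |
    (l1$series == "y" & l1$index >= n - k + 1)
  expect_equal(d[shifted], rep(47.94445, sum(shifted)), tolerance = 1e-9)
  expect_equal(d[!shifted], rep(0, sum(!shifted)), tolerance = 1e-9)
  expect_identical(l1$contains_se, shifted)
})

test_that("peak matching is one-to-one, self-consistent and tolerance-monotone", {
  p <- parse_peptide("CSeACL")
  spec <- simulate_spectrum(p, noiseless_sim())
  lad <- fragment_ladder(p)
  m <- match_peaks(lad, spec)
  expect_true(all(m$within_tolerance))
  expect_equal(sum(m$within_tolerance), 2 * (length(p$residues) - 1))
  # a different random peptide of the same length matches strictly fewer ions
  set.seed(33)
  for (i in 1:10) {
    q <- random_test_peptide(4)
    mq <- match_peaks(fragment_ladder(q), spec)
    expect_lt(sum(mq$within_tolerance), sum(m$within_tolerance))
  }
  empty <- spectrum("e", 400, 1)
  expect_equal(sum(match_peaks(lad, empty)$within_tolerance), 0)
  # monotonicity in the tolerance
  jit <- simulate_spectrum(p, sim_config(seed = 5, mz_jitter_ppm = 30,
                                         missing_fragment_rate = 0,
                                         noise_peaks = 0))
  tols <- c(0.001, 0.005, 0.02, 0.1)
  matched <- lapply(tols, function(t) {
    mm <- match_peaks(lad, jit, tol_da = t)
    mm$label[mm$within_tolerance]
  })
  for (k in 1:3) expect_true(all(matched[[k]] %in% matched[[k + 1]]))
})

test_that("selenium sites are localized from the fragment shift pattern", {
  s1 <- simulate_spectrum(parse_peptide("CSeCL"), noiseless_sim())
  expect_identical(localize_se(s1, peptide("CCL")), 1L)
  s0 <- simulate_spectrum(peptide("CCL"), noiseless_sim())
  expect_identical(localize_se(s0, peptide("CCL")), integer(0))
  s2 <- simulate_spectrum(parse_peptide("CSeCPT"), noiseless_sim())
  expect_identical(localize_se(s2, peptide("CCPT")), 1L)
  expect_error(localize_se(s1, peptide("AGL")), "impossible")
})
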