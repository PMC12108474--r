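test_that("the noiseless limit reproduces the theoretical ladder exactly", {
  p <- parse_peptide("Ac-MSePGP")
  s <- simulate_spectrum(p, noiseless_sim())
  lad <- fragment_ladder(p)
  expect_equal(sort(s$peaks$mz), sort(lad$mz), tolerance = 1e-12)
  expect_equal(s$precursor_mz, mass_to_mz(peptide_mass(p), 1),
               tolerance = 1e-12)
})

test_that("spectra are deterministic in (peptide, config) and vary with the seed", {
  p <- parse_peptide("CSeGF")
  cfg <- sim_config(seed = 9)
  s1 <- simulate_spectrum(p, cfg)
  s2 <- simulate_spectrum(p, cfg)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$precursor_mz, s2$precursor_mz)
  s3 <- simulate_spectrum(p, sim_config(seed = 10))
  expect_false(identical(s1$peaks, s3$peaks))
  # datasets inherit determinism
  d1 <- simulate_dataset(sim_config(seed = 3, decoy_count = 2))
  d2 <- simulate_dataset(sim_config(seed = 3, decoy_count = 2))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$proteins, d2$proteins)
  d3 <- simulate_dataset(sim_config(seed = 4, decoy_count = 2))
  expect_false(identical(d1$proteins, d3$proteins))
})

test_that("m/z jitter is calibrated in ppm", {
  p <- parse_peptide("FCSeH")
  lad <- fragment_ladder(p)
  rel <- unlist(lapply(1:1000, function(seed) {
    s <- simulate_spectrum(p, sim_config(seed = seed, mz_jitter_ppm = 5,
                                         missing_fragment_rate = 0,
                                         noise_peaks = 0))
    m <- match_peaks(lad, s, tol_da = 1)
    1e6 * m$delta_mz / m$mz
  }))
  expect_equal(sd(rel), 5, tolerance = 0.1 * 5)
})

test_that("the bundled dataset matches the acquisition regime and its own truth", {
  ds <- simulate_dataset()
  expect_equal(sum(ds$truth$is_se & ds$truth$arm == "sample"), 16)
  expect_equal(sum(ds$truth$is_se & ds$truth$arm == "control"), 3)
  prec <- vapply(c(ds$sample, ds$control), function(s) s$precursor_mz,
                 numeric(1))
  expect_true(all(prec >= 350 & prec <= 2000))
  # every true de-selenized sequence occurs in the protein set
  truth_names <- ds$truth$display_name[ds$truth$is_se]
  for (nm in truth_names) {
    bare <- bare_sequence(parse_peptide(nm))
    expect_true(any(grepl(bare, ds$proteins, fixed = TRUE)))
  }
})

test_that("noiseless end-to-end identification returns exactly the truth set", {
  cfg <- noiseless_sim(decoy_count = 0)
  ds <- simulate_dataset(cfg)
  set <- identify_dataset(ds$sample, fasta = ds$proteins, label = "sample")
  truth <- sort(ds$truth$display_name[ds$truth$arm == "sample" & ds$truth$is_se])
  expect_identical(sort(set$members$display_name), truth)
})
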