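test_that("candidate enumeration honours the precursor window", {
  cfg1 <- search_config(precursor_tol_ppm = 10, max_length = 2, min_length = 1,
                        variable_mods = character(0))
  got <- enumerate_candidates(75.0320, cfg1)
  expect_identical(candidate_keys(got), "G|")
  expect_length(enumerate_candidates(30, cfg1), 0)

  # Ac-MSePGP and all residue permutations of {SeMet, Pro, Pro, Gly} appear
  cfg4 <- search_config(precursor_tol_ppm = 20, max_length = 4)
  cands <- enumerate_candidates(490.1331, cfg4)
  keys <- candidate_keys(cands)
  perms <- unique(apply(
    expand.grid(rep(list(1:4), 4))[apply(expand.grid(rep(list(1:4), 4)), 1,
                                         function(x) all(sort(x) == 1:4)), ],
    1, function(ord) paste(c("MSe", "P", "G", "P")[ord], collapse = "")))
  expect_length(perms, 12)
  expect_true(all(paste0(perms, "|nterm:acetyl") %in% keys))
})

test_that("pruned enumeration equals the exhaustive oracle", {
  cfg <- search_config(precursor_tol_ppm = 20, max_length = 3, min_length = 1)
  set.seed(99)
  masses <- runif(12, 150, 480)
  for (m in masses) {
    expect_identical(candidate_keys(enumerate_candidates(m, cfg)),
                     exhaustive_candidate_keys(m, cfg))
  }
})

test_that("scoring separates a peptide from its positional isomer", {
  p <- parse_peptide("CSeFA")
  spec <- simulate_spectrum(p, noiseless_sim())
  self <- score_match(p, spec)
  expect_equal(self$coverage, 1.0)
  iso <- score_match(parse_peptide("CSeAF"), spec)
  expect_lt(iso$coverage, 1.0)
  bare <- spectrum(spec$id, spec$precursor_mz, 1)  # all fragment peaks removed
  expect_equal(score_match(p, bare)$coverage, 0)
})

test_that("search_spectrum ranks the true peptide first and validates against FASTA", {
  p <- peptide("MPGP", se_sites = 1, nterm_mod = "acetyl")
  spec <- simulate_spectrum(p, noiseless_sim())
  m <- search_spectrum(spec)
  expect_equal(m$display_name[1], "MSePGP")
  expect_equal(m$mods[1], "nterm:acetyl")
  fasta <- c(prot1 = "GAVTMPGPKKE")
  mf <- search_spectrum(spec, fasta = fasta)
  expect_true(mf$fasta_validated[mf$rank == 1])
  # a decoy without C or M can never yield a selenium-containing match
  d <- peptide("GAVT")
  md <- search_spectrum(simulate_spectrum(d, noiseless_sim()))
  expect_equal(md$display_name[1], "GAVT")
  expect_true(md$n_se[md$rank == 1] == 0)
})

test_that("identify_dataset deduplicates and reports internally consistent matches", {
  p <- parse_peptide("FCSeH")
  spec1 <- simulate_spectrum(p, noiseless_sim(), id = "a")
  spec2 <- simulate_spectrum(p, noiseless_sim(), id = "b")
  set <- identify_dataset(list(spec1, spec2))
  expect_equal(nrow(set$members), 1)
  # decoys only: no selenium-containing identifications
  set.seed(4)
  decoys <- random_decoy_peptides(5, seed = 77)
  dec_set <- identify_dataset(lapply(decoys, simulate_spectrum,
                                     cfg = noiseless_sim()))
  expect_equal(sum(dec_set$members$n_se > 0), 0)
  # every reported match satisfies its own arithmetic
  ds <- simulate_dataset(sim_config(decoy_count = 2))
  s <- identify_dataset(ds$sample[1:6], fasta = ds$proteins)
  for (i in seq_len(nrow(s$members))) {
    pep <- parse_peptide(s$members$display_name[i])
    if (s$members$mods[i] == "nterm:acetyl") {
      pep <- peptide(pep$residues, pep$se_sites, nterm_mod = "acetyl")
    }
    expect_equal(peptide_mass(pep), s$members$mass[i], tolerance = 1e-9)
    expect_equal(ppm_error(s$members$observed_mz[i], pep, s$members$z[i]),
                 s$members$ppm[i], tolerance = 1e-9)
  }
})
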