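ref_set <- function() {
  ref <- reference_selenopeptides()
  peptide_set("sample", data.frame(
    display_name = ref$display_name, mods = "", mass = ref$mass_da,
    stringsAsFactors = FALSE
  ))
}

ctrl_set <- function(names = control_shared_selenopeptides()) {
  peptide_set("control", data.frame(
    display_name = names, mods = "", stringsAsFactors = FALSE
  ))
}

test_that("control-shared selenopeptides are excluded, others retained", {
  rep <- exclude_shared(ref_set(), ctrl_set())
  expect_equal(nrow(rep$shared$members), 3)
  expect_equal(nrow(rep$unique_to_sample$members), 13)
  expect_setequal(rep$shared$members$display_name,
                  c("CSePY", "CSeCPT", "FDGCSe"))
  # identical sets leave nothing unique; disjoint sets share nothing
  all_shared <- exclude_shared(ref_set(),
                               ctrl_set(reference_selenopeptides()$display_name))
  expect_equal(nrow(all_shared$unique_to_sample$members), 0)
  none <- exclude_shared(ref_set(), ctrl_set("AGAG"))
  expect_equal(nrow(none$shared$members), 0)
})

test_that("exclusion conserves membership and is idempotent", {
  set.seed(12)
  pool <- vapply(1:40, function(i) display_name(random_se_peptides(1, i)[[1]]),
                 character(1))
  for (i in 1:10) {
    s <- peptide_set("s", data.frame(display_name = sample(pool, 15), mods = ""))
    ctl <- peptide_set("c", data.frame(display_name = sample(pool, 8), mods = ""))
    rep <- exclude_shared(s, ctl)
    expect_equal(nrow(rep$unique_to_sample$members) + nrow(rep$shared$members),
                 sum(s$members$n_se > 0))
    again <- exclude_shared(rep$unique_to_sample, ctl)
    expect_identical(again$unique_to_sample$members$display_name,
                     rep$unique_to_sample$members$display_name)
  }
})

test_that("selenium site types are classified per carrying residue", {
  expect_identical(classify_se_type(ref_set()), c(sec = 13L, semet = 3L))
  one <- peptide_set("x", data.frame(display_name = "YGMSeT", mods = ""))
  expect_identical(classify_se_type(one), c(sec = 0L, semet = 1L))
  empty <- peptide_set("e", data.frame(display_name = character(0),
                                       mods = character(0)))
  expect_identical(classify_se_type(empty), c(sec = 0L, semet = 0L))
  # ordering of members does not change the counts
  ref <- ref_set()
  shuffled <- peptide_set("s", ref$members[rev(seq_len(nrow(ref$members))), ])
  expect_identical(classify_se_type(shuffled), classify_se_type(ref))
})

test_that("length distribution tabulates residue counts", {
  expect_identical(length_distribution(ref_set()), c(`3` = 7L, `4` = 9L))
  empty <- peptide_set("e", data.frame(display_name = character(0),
                                       mods = character(0)))
  expect_length(length_distribution(empty), 0)
  tri <- peptide_set("t", data.frame(display_name = "CSeGF", mods = ""))
  expect_identical(length_distribution(tri), c(`3` = 1L))
})
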