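sepep_path <- system.file("extdata", "composition_sepep.tsv",
                          package = "selenopept")
pep_path <- system.file("extdata", "composition_pep.tsv",
                        package = "selenopept")

test_that("group sums follow their definitions", {
  empty <- composition_table("empty", numeric(0))
  expect_equal(unname(summarize_composition(empty)), c(0, 0, 0))
  single <- composition_table("cys", c(C = 0.9))
  expect_equal(unname(summarize_composition(single)), c(0.9, 0, 0))
  # direct-summation oracle on the selenium-enriched sample's table
  df <- read.delim(sepep_path)
  t <- read_composition(sepep_path, "SePEP")
  s <- summarize_composition(t)
  expect_equal(s[["total"]], sum(df$amount_mg_per_g))
  ess <- c("H", "I", "L", "K", "M", "F", "T", "W", "V")
  hyd <- c("G", "A", "V", "L", "I", "P", "F", "M", "W")
  expect_equal(s[["essential"]],
               sum(df$amount_mg_per_g[df$amino_acid %in% ess]))
  expect_equal(s[["hydrophobic"]],
               sum(df$amount_mg_per_g[df$amino_acid %in% hyd]))
  # hydrophobic + non-hydrophobic == total, exactly
  non_h <- sum(t$amounts[!names(t$amounts) %in% hyd])
  expect_identical(s[["hydrophobic"]] + non_h, s[["total"]])
  expect_error(composition_table("bad", c(B = 1)), "unknown amino-acid")
})

test_that("sample-vs-control comparison is signed and antisymmetric", {
  a <- read_composition(sepep_path, "SePEP")
  b <- read_composition(pep_path, "PEP")
  cmp <- compare_tables(a, b)
  expect_equal(cmp$per_acid[["C"]], -0.69)
  # selenium-enriched sample is higher in all three group sums
  expect_true(all(cmp$groups > 0))
  self <- compare_tables(a, a)
  expect_true(all(self$per_acid == 0) && all(self$groups == 0))
  rev_cmp <- compare_tables(b, a)
  expect_equal(rev_cmp$per_acid, -cmp$per_acid)
  expect_equal(rev_cmp$groups, -cmp$groups)
  # a missing acid is treated as zero
  partial <- composition_table("p", c(C = 1))
  expect_message(cmp2 <- compare_tables(partial, b), "missing")
  expect_equal(cmp2$per_acid[["C"]], 1 - 1.59)
})
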