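Package: selenopept
Title: Selenopeptide Identification from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of selenium-containing peptides from centroided
    LC-MS/MS spectra of protein hydrolysates, built around the diagnostic
    monoisotopic mass shift of 47.944 Da that selenium-for-sulfur substitution
    adds to cysteine and methionine. Provides monoisotopic peptide mass
    arithmetic with variable modifications, theoretical b/y fragment ladders
    and peak matching with selenium-site localization, de novo candidate
    enumeration under a precursor mass constraint with branch-and-bound
    pruning, protein FASTA back-validation, differential exclusion of peptides
    shared with a selenium-free control, amino-acid composition summaries, a
    seeded synthetic MS/MS spectrum generator, and MGF/FASTA/TSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
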