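#' Run the end-to-end selenopeptide analysis
#'
#' Ties the stages into the full analysis: identify the selenium-enriched
#' sample arm, identify the selenium-free control arm, exclude the
#' selenopeptides shared with the control, classify the remainder by selenium
#' site type and tabulate lengths. Writes, under `out_dir`:
#' `identifications_sample.tsv`, `identifications_control.tsv`,
#' `selenopeptides_unique.tsv` (the post-exclusion set, reference-table
#' style) and `summary.txt` (one-line counts). All numeric formatting is
#' pinned, so two runs with equal inputs produce byte-identical files; on any
#' fatal stage error, partial outputs are removed before the error
#' propagates.
#'
#' @param sample_mgf,control_mgf Paths to the two MGF files.
#' @param fasta Path to the validation FASTA (required).
#' @param out_dir Output directory, created if needed.
#' @param cfg A [search_config()].
#' @param chem Chemistry object.
#' @return Invisibly, a list with `sample_set`, `control_set`, `report`
#'   (the [exclude_shared()] result) and `paths`.
#' @export
run_pipeline <- function(sample_mgf, control_mgf, fasta, out_dir,
                         cfg = search_config(), chem = chem_defaults()) {
  if (!file.exists(fasta)) stop("validation FASTA not found: ", fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sample = file.path(out_dir, "identifications_sample.tsv"),
    control = file.path(out_dir, "identifications_control.tsv"),
    unique = file.path(out_dir, "selenopeptides_unique.tsv"),
    summary = file.path(out_dir, "summary.txt")
  )
  tryCatch({
    proteins <- read_fasta(fasta)
    sample_set <- identify_dataset(read_mgf(sample_mgf), cfg, proteins,
                                   label = "sample", chem = chem)
    control_set <- identify_dataset(read_mgf(control_mgf), cfg, proteins,
                                    label = "control", chem = chem)
    report <- exclude_shared(sample_set, control_set)
    write_identification_tsv(sample_set, paths[["sample"]])
    write_identification_tsv(control_set, paths[["control"]])
    write_identification_tsv(report$unique_to_sample, paths[["unique"]])
    writeLines(paste0(
      report$counts$total, " Se-peptides; ",
      nrow(report$shared$members), " shared excluded; Sec/SeMet = ",
      report$counts$sec, "/", report$counts$semet
    ), paths[["summary"]])
    invisible(list(sample_set = sample_set, control_set = control_set,
                   report = report, paths = paths))
  }, error = function(e) {
    unlink(paths[file.exists(paths)])
    stop(e)
  })
}
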