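#!/usr/bin/env Rscript
# Generate the two-arm synthetic dataset: sample-arm spectra for the 16
# reference selenopeptides plus 20 selenium-free decoys, control-arm spectra
# for the 3 control-shared selenopeptides plus decoys, a validation protein
# FASTA embedding every true de-selenized sequence, and the truth table.
# Defaults: seed 42, 5 ppm m/z jitter, 10% missing fragments, 10 noise peaks.
# Writes results/simdata/{sample.mgf,control.mgf,proteins.fasta,truth.tsv}.

suppressPackageStartupMessages(library(selenopept))

ds <- simulate_dataset(sim_config())
paths <- write_simulated_dataset(ds, "results/simdata")

cat("sample arm:", length(ds$sample), "spectra (",
    sum(ds$truth$is_se & ds$truth$arm == "sample"), "selenopeptides );",
    "control arm:", length(ds$control), "spectra (",
    sum(ds$truth$is_se & ds$truth$arm == "control"), "selenopeptides )\n")
cat("proteins:", length(ds$proteins), "synthetic sequences\n")
cat("written:", paste(basename(paths), collapse = ", "), "\n")
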