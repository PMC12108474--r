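#' Read and write Mascot Generic Format (MGF) spectra
#'
#' `read_mgf()` parses `BEGIN IONS`/`END IONS` blocks: `TITLE` becomes the
#' spectrum identifier, the first token of `PEPMASS` the precursor m/z (a
#' second intensity token is accepted and ignored), `CHARGE` accepts the
#' `"1+"` dialect, `RTINSECONDS` is optional, and peak lines are
#' `mz intensity`. A block without a `CHARGE` line is assumed singly charged
#' with a warning. Malformed blocks (no parsable precursor, or no peaks) are
#' skipped and counted in a single warning; a file with zero valid blocks is
#' a fatal error.
#'
#' @param path Path to an MGF file.
#' @return List of `ms2_spectrum` objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) == 0 || length(starts) != length(ends)) {
    stop("no valid BEGIN IONS/END IONS blocks in ", path)
  }
  skipped <- 0L
  missing_charge <- 0L
  spectra <- list()
  for (b in seq_along(starts)) {
    body <- lines[(starts[b] + 1):(ends[b] - 1)]
    title <- sub("^TITLE=", "", grep("^TITLE=", body, value = TRUE)[1])
    pepmass_line <- grep("^PEPMASS=", body, value = TRUE)
    charge_line <- grep("^CHARGE=", body, value = TRUE)
    rt_line <- grep("^RTINSECONDS=", body, value = TRUE)
    peak_lines <- body[!grepl("=", body, fixed = TRUE) & nzchar(trimws(body))]
    pep_mz <- if (length(pepmass_line) > 0) {
      suppressWarnings(as.numeric(strsplit(
        sub("^PEPMASS=", "", pepmass_line[1]), "[ \t]+")[[1]][1]))
    } else NA_real_
    if (is.na(pep_mz) || pep_mz <= 0 || length(peak_lines) == 0) {
      skipped <- skipped + 1L
      next
    }
    z <- if (length(charge_line) > 0) {
      zc <- sub("^CHARGE=", "", charge_line[1])
      suppressWarnings(as.integer(gsub("[+ ]", "", zc)))
    } else {
      missing_charge <- missing_charge + 1L
      1L
    }
    if (is.na(z) || z < 1) z <- 1L
    fields <- strsplit(trimws(peak_lines), "[ \t]+")
    mz <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 1)))
    int <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= 2) f[2] else "1"
    }, character(1))))
    ok <- !is.na(mz) & !is.na(int)
    if (!any(ok)) {
      skipped <- skipped + 1L
      next
    }
    rt <- if (length(rt_line) > 0) {
      suppressWarnings(as.numeric(sub("^RTINSECONDS=", "", rt_line[1])))
    } else NA_real_
    spectra[[length(spectra) + 1]] <- spectrum(
      id = if (is.na(title)) paste0("index_", b) else title,
      precursor_mz = pep_mz, precursor_z = z,
      peaks = data.frame(mz = mz[ok], intensity = int[ok]), rt = rt
    )
  }
  if (length(spectra) == 0) stop("no valid spectra in ", path)
  if (skipped > 0) warning(skipped, " malformed MGF block(s) skipped")
  if (missing_charge > 0) {
    warning(missing_charge, " block(s) without CHARGE; assumed 1+")
  }
  spectra
}

#' @rdname read_mgf
#' @param spectra List of `ms2_spectrum` objects.
#' @return `write_mgf()`: invisibly, the path written. Numeric formatting is
#'   pinned (m/z 5 decimals, intensity 1 decimal) so equal inputs produce
#'   byte-identical files.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      paste0("PEPMASS=", sprintf("%.5f", s$precursor_mz)),
      paste0("CHARGE=", s$precursor_z, "+"),
      if (!is.na(s$rt)) paste0("RTINSECONDS=", sprintf("%.2f", s$rt)),
      sprintf("%.5f %.1f", s$peaks$mz, s$peaks$intensity),
      "END IONS"
    ), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read a protein FASTA for back-validation
#'
#' Sequences are uppercased; letters outside the 20-residue alphabet (e.g.
#' `X`) are retained but can never match a peptide letter. A file with no
#' records is a fatal error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(aa))
  odd <- grepl(paste0("[^", paste(names(amino_acid_masses()), collapse = ""),
                      "]"), seqs)
  if (any(odd)) {
    message(sum(odd), " protein(s) contain non-standard letters; ",
            "those positions never match")
  }
  seqs
}

#' Write an identification report as TSV
#'
#' Columns mirror the reference identification table: `No.`, `Peptide`
#' (display name), `Mass_Da` (3 decimals, half-up), `Length`, `ppm`
#' (1 decimal, truncated toward zero), `mz` (4 decimals), `z`, plus the
#' modification signature, fragment coverage and score. Formatting is pinned
#' so byte-identity between runs is meaningful.
#'
#' @param s A [peptide_set()] (or a `differential_report` member set).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_identification_tsv <- function(s, path) {
  stopifnot(inherits(s, "peptide_set"))
  m <- s$members
  out <- data.frame(
    No. = seq_len(nrow(m)),
    Peptide = m$display_name,
    Mass_Da = sprintf("%.3f", round_half_up(m$mass, 3)),
    Length = m$length,
    ppm = sprintf("%.1f", reported_ppm(m$ppm)),
    mz = sprintf("%.4f", round_half_up(m$observed_mz, 4)),
    z = m$z,
    Modifications = m$mods,
    Coverage = sprintf("%.3f", m$coverage),
    Score = sprintf("%.4f", m$score),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
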