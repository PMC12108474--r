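#' Configuration for the synthetic MS/MS spectrum generator
#'
#' The generator emulates centroided, singly charged MS/MS spectra of short
#' (3-4 residue) non-tryptic peptides as acquired on an Orbitrap at
#' resolution 60,000 over m/z 350-2000: singly charged b/y ladders with
#' Gaussian ppm-scale m/z jitter, independently dropped fragments, uniform
#' noise peaks and information-free lognormal intensities. The seed fully
#' determines the output; the defaults are the study conditions used by the
#' bundled dataset and the end-to-end checks.
#'
#' @param seed Integer seed; fully determines every generated spectrum.
#' @param mz_jitter_ppm Standard deviation of the relative m/z error, in ppm,
#'   applied to fragment and precursor m/z (default 5, comfortably inside a
#'   20 ppm precursor window).
#' @param missing_fragment_rate Probability that each fragment peak is
#'   dropped (default 0.1).
#' @param noise_peaks Number of uniform noise peaks per spectrum (default 10).
#' @param noise_mz_range Range the noise peaks are drawn from (default
#'   c(100, 1000), covering the fragment region of short peptides).
#' @param base_intensity Base peak intensity (arbitrary units, default 1e4).
#' @param intensity_sigma Sigma of the multiplicative lognormal intensity
#'   model (default 0.3). Intensities carry no sequence information.
#' @param decoy_count Number of selenium-free decoy peptides per arm
#'   (default 20).
#' @param decoy_length_range Decoy length range (default c(3, 4)).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, mz_jitter_ppm = 5,
                       missing_fragment_rate = 0.1, noise_peaks = 10L,
                       noise_mz_range = c(100, 1000), base_intensity = 1e4,
                       intensity_sigma = 0.3, decoy_count = 20L,
                       decoy_length_range = c(3L, 4L)) {
  if (missing_fragment_rate < 0 || missing_fragment_rate > 1) {
    stop("missing_fragment_rate must be in [0, 1]")
  }
  if (mz_jitter_ppm < 0 || noise_peaks < 0 || decoy_count < 0) {
    stop("rates and counts must be non-negative")
  }
  structure(
    list(seed = as.integer(seed), mz_jitter_ppm = mz_jitter_ppm,
         missing_fragment_rate = missing_fragment_rate,
         noise_peaks = as.integer(noise_peaks),
         noise_mz_range = noise_mz_range, base_intensity = base_intensity,
         intensity_sigma = intensity_sigma,
         decoy_count = as.integer(decoy_count),
         decoy_length_range = as.integer(decoy_length_range)),
    class = "sim_config"
  )
}

# Run expr with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-peptide seed so simulate_spectrum(p, cfg) is a pure
# function of (p, cfg); kept well below 2^31.
peptide_seed <- function(p, cfg) {
  txt <- paste0(display_name(p), "|", mod_signature(p))
  h <- sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 100003L
  (cfg$seed %% 20011L) * 100003L + h
}

#' Simulate one centroided MS/MS spectrum of a peptide
#'
#' Peaks are the singly charged b/y ladder with Gaussian ppm jitter, each
#' fragment independently dropped at the configured rate, plus uniform noise
#' peaks; the precursor m/z is the theoretical `[M+H]+` with the same jitter.
#' The output is a deterministic function of the peptide and configuration.
#'
#' @param p An `se_peptide` of length >= 2.
#' @param cfg A [sim_config()].
#' @param id Spectrum identifier (defaults to the display name).
#' @param chem Chemistry object.
#' @return An `ms2_spectrum`.
#' @export
simulate_spectrum <- function(p, cfg = sim_config(), id = display_name(p),
                              chem = chem_defaults()) {
  stopifnot(inherits(p, "se_peptide"))
  if (length(p$residues) < 2) stop("peptide length must be >= 2")
  with_seed(peptide_seed(p, cfg), {
    ladder <- fragment_ladder(p, z_max = 1L, chem = chem)
    n <- nrow(ladder)
    jitter <- stats::rnorm(n, 0, cfg$mz_jitter_ppm) * 1e-6
    mz <- ladder$mz * (1 + jitter)
    keep <- stats::runif(n) >= cfg$missing_fragment_rate
    intensity <- cfg$base_intensity *
      exp(stats::rnorm(n, 0, cfg$intensity_sigma))
    peaks <- data.frame(mz = mz[keep], intensity = intensity[keep])
    if (cfg$noise_peaks > 0) {
      noise <- data.frame(
        mz = stats::runif(cfg$noise_peaks, cfg$noise_mz_range[1],
                          cfg$noise_mz_range[2]),
        intensity = 0.2 * cfg$base_intensity *
          exp(stats::rnorm(cfg$noise_peaks, 0, cfg$intensity_sigma))
      )
      peaks <- rbind(peaks, noise)
    }
    prec_jitter <- stats::rnorm(1, 0, cfg$mz_jitter_ppm) * 1e-6
    prec <- mass_to_mz(peptide_mass(p, chem), 1L, chem) * (1 + prec_jitter)
    spectrum(id, precursor_mz = prec, precursor_z = 1L, peaks = peaks)
  })
}

#' Random selenium-free decoy peptides
#'
#' Decoys are drawn uniformly over the 18 letters excluding C and M, so a
#' decoy can never legitimately carry a selenium substitution; any
#' selenium-containing identification from a decoy spectrum is therefore a
#' false positive by construction.
#'
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @param length_range Length range, inclusive.
#' @param mz_range Acquisition m/z range; decoys are redrawn until their
#'   singly protonated precursor falls inside it (default c(350, 2000)).
#' @return List of `se_peptide` objects.
#' @export
random_decoy_peptides <- function(n, seed, length_range = c(3L, 4L),
                                  mz_range = c(350, 2000)) {
  letters18 <- setdiff(names(amino_acid_masses()), c("C", "M"))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        len <- sample(seq(length_range[1], length_range[2]), 1)
        p <- peptide(sample(letters18, len, replace = TRUE))
        mz <- mass_to_mz(peptide_mass(p), 1L)
        if (mz >= mz_range[1] && mz <= mz_range[2]) return(p)
      }
    })
  })
}

#' Random selenium-containing peptides for recovery studies
#'
#' Each peptide is 3-4 residues over the 19 letters excluding Ile (sequences
#' are generated in canonical Leu form, matching how the search folds the
#' isobaric pair), carries exactly one selenium site on a C or M, and is
#' N-terminally acetylated with the given probability.
#'
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param length_range Length range, inclusive.
#' @param acetyl_prob Probability of N-terminal acetylation.
#' @return List of `se_peptide` objects.
#' @export
random_se_peptides <- function(n, seed, length_range = c(3L, 4L),
                               acetyl_prob = 0.3) {
  letters19 <- setdiff(names(amino_acid_masses()), "I")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      residues <- sample(letters19, len, replace = TRUE)
      se_pos <- sample(len, 1)
      residues[se_pos] <- sample(c("C", "M"), 1)
      nterm <- if (stats::runif(1) < acetyl_prob) "acetyl" else NULL
      peptide(residues, se_sites = se_pos, nterm_mod = nterm)
    })
  })
}

#' Simulate the full two-arm dataset
#'
#' The sample arm holds one spectrum per reference selenopeptide (with the
#' modification assignment that reproduces its published mass) plus
#' selenium-free decoys; the control arm holds the three selenopeptides shared
#' with the selenium-free preparation plus its own decoys. The protein set
#' embeds every true de-selenized sequence (so FASTA back-validation of every
#' truth peptide succeeds) inside selenium-free flanking sequence; decoy
#' peptides are deliberately not embedded. The truth table records every
#' generated spectrum's source.
#'
#' @param cfg A [sim_config()].
#' @param chem Chemistry object.
#' @return List with elements `sample` and `control` (lists of
#'   `ms2_spectrum`), `proteins` (named character vector) and `truth`
#'   (data frame: `spectrum_id`, `arm`, `display_name`, `mods`, `mass`,
#'   `is_se`).
#' @export
simulate_dataset <- function(cfg = sim_config(), chem = chem_defaults()) {
  ref <- resolve_reference_mods(chem = chem)
  sample_true <- ref$peptide
  control_names <- control_shared_selenopeptides()
  control_true <- ref$peptide[match(control_names, ref$display_name)]

  sample_decoys <- random_decoy_peptides(cfg$decoy_count, cfg$seed + 1L,
                                         cfg$decoy_length_range)
  control_decoys <- random_decoy_peptides(cfg$decoy_count, cfg$seed + 2L,
                                          cfg$decoy_length_range)

  make_arm <- function(true_peps, decoys, arm) {
    peps <- c(true_peps, decoys)
    ids <- sprintf("%s_%02d_%s", arm, seq_along(peps),
                   vapply(peps, display_name, character(1)))
    spectra <- mapply(function(p, id) simulate_spectrum(p, cfg, id = id,
                                                        chem = chem),
                      peps, ids, SIMPLIFY = FALSE)
    truth <- data.frame(
      spectrum_id = ids,
      arm = arm,
      display_name = vapply(peps, display_name, character(1)),
      mods = vapply(peps, mod_signature, character(1)),
      mass = vapply(peps, peptide_mass, numeric(1), chem = chem),
      is_se = vapply(peps, function(p) length(p$se_sites) > 0, logical(1)),
      stringsAsFactors = FALSE
    )
    list(spectra = spectra, truth = truth, peptides = peps)
  }
  sample_arm <- make_arm(sample_true, sample_decoys, "sample")
  control_arm <- make_arm(control_true, control_decoys, "control")

  embed <- unique(vapply(c(sample_true, control_true), bare_sequence,
                         character(1)))
  proteins <- with_seed(cfg$seed + 3L, {
    letters18 <- setdiff(names(amino_acid_masses()), c("C", "M"))
    prot <- vapply(embed, function(s) {
      paste0(paste(sample(letters18, sample(5:12, 1), replace = TRUE),
                   collapse = ""),
             s,
             paste(sample(letters18, sample(5:12, 1), replace = TRUE),
                   collapse = ""))
    }, character(1))
    names(prot) <- sprintf("synthetic_protein_%02d", seq_along(prot))
    prot
  })

  list(
    sample = sample_arm$spectra,
    control = control_arm$spectra,
    proteins = proteins,
    truth = rbind(sample_arm$truth, control_arm$truth)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes `sample.mgf`, `control.mgf`, `proteins.fasta` and `truth.tsv` under
#' `dir`. All formats are plain text and byte-deterministic for a given
#' configuration.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sample = file.path(dir, "sample.mgf"),
    control = file.path(dir, "control.mgf"),
    fasta = file.path(dir, "proteins.fasta"),
    truth = file.path(dir, "truth.tsv")
  )
  write_mgf(ds$sample, paths[["sample"]])
  write_mgf(ds$control, paths[["control"]])
  writeLines(
    as.vector(rbind(paste0(">", names(ds$proteins)), unname(ds$proteins))),
    paths[["fasta"]]
  )
  truth <- ds$truth
  truth$mass <- sprintf("%.5f", truth$mass)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
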