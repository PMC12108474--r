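# Independent oracles used by the property tests.

# Exhaustive candidate enumeration: generate every symbol sequence of length
# min_length..max_length over the search alphabet, with and without an
# N-terminal acetyl, compute all masses directly and filter by the ppm
# window. No pruning, no shared code path with enumerate_candidates() beyond
# the alphabet definition itself.
exhaustive_candidate_keys <- function(target_mass, cfg, chem = chem_defaults()) {
  alphabet <- selenopept:::search_alphabet(cfg, chem)
  water <- chem_constants()[["water_mass"]]
  acetyl <- 42.01057
  lo <- target_mass * (1 - cfg$precursor_tol_ppm * 1e-6)
  hi <- target_mass * (1 + cfg$precursor_tol_ppm * 1e-6)
  keys <- character(0)
  for (len in seq(cfg$min_length, cfg$max_length)) {
    grids <- expand.grid(rep(list(seq_len(nrow(alphabet))), len))
    seq_mass <- rowSums(matrix(alphabet$mass[as.matrix(grids)], ncol = len))
    nvar <- rowSums(matrix(alphabet$nvar[as.matrix(grids)], ncol = len))
    for (acet in c(FALSE, TRUE)) {
      if (acet && !"acetyl" %in% cfg$variable_mods) next
      total <- seq_mass + water + if (acet) acetyl else 0
      tot_var <- nvar + as.integer(acet)
      hit <- which(total >= lo & total <= hi & tot_var <= cfg$max_var_mods)
      for (h in hit) {
        syms <- alphabet$symbol[as.integer(grids[h, ])]
        p <- selenopept:::symbols_to_peptide(
          syms, alphabet, if (acet) "acetyl" else NULL, chem)
        keys <- c(keys, paste(display_name(p),
                              selenopept:::mod_signature(p), sep = "|"))
      }
    }
  }
  sort(keys)
}

candidate_keys <- function(cands) {
  sort(vapply(cands, function(p) {
    paste(display_name(p), selenopept:::mod_signature(p), sep = "|")
  }, character(1)))
}

# Noise-free simulator configuration, used wherever a spectrum must equal its
# theoretical ladder exactly.
noiseless_sim <- function(seed = 1L, ...) {
  sim_config(seed = seed, mz_jitter_ppm = 0, missing_fragment_rate = 0,
             noise_peaks = 0, ...)
}

random_test_peptide <- function(len, allow_se = TRUE) {
  letters19 <- setdiff(names(amino_acid_masses()), "I")
  residues <- sample(letters19, len, replace = TRUE)
  se <- integer(0)
  if (allow_se) {
    cm <- which(residues %in% c("C", "M"))
    if (length(cm) > 0 && runif(1) < 0.5) {
      se <- cm[sample.int(length(cm), 1)]
    }
  }
  peptide(residues, se_sites = se)
}
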