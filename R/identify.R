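#' Search configuration for de novo identification
#'
#' Candidate peptides are enumerated de novo under the precursor mass
#' constraint rather than from a protein digest: the hydrolysate is cleaved
#' non-specifically, so no enzyme rule applies and the protein database is
#' used for back-validation only. Defaults follow the acquisition regime of
#' the reference data: a 20 ppm precursor window (the reported identifications
#' span -17.2 to +13.9 ppm), a 0.02 Da fragment tolerance and peptide lengths
#' up to 4 residues.
#'
#' @param precursor_tol_ppm Precursor mass tolerance in ppm (> 0).
#' @param fragment_tol_da Fragment match tolerance in Da.
#' @param max_length Maximum candidate length in residues (2..6).
#' @param variable_mods Character vector of variable modification names drawn
#'   from the chemistry object's vocabulary. The selenium substitution is part
#'   of the search alphabet (substituted C/M residues), not counted here.
#' @param max_var_mods Maximum number of variable modifications per candidate.
#' @param min_fragment_coverage Minimum fraction of the b/y ladder that must
#'   be matched for a candidate to be reported.
#' @param min_length Minimum candidate length (default 2; single residues are
#'   allowed by setting 1).
#' @return A list of class `search_config`.
#' @export
search_config <- function(precursor_tol_ppm = 20, fragment_tol_da = 0.02,
                          max_length = 4L, variable_mods = c("acetyl", "carbamidomethyl"),
                          max_var_mods = 2L, min_fragment_coverage = 0.5,
                          min_length = 2L) {
  if (precursor_tol_ppm <= 0) stop("precursor_tol_ppm must be > 0")
  max_length <- as.integer(max_length)
  if (max_length < 2 || max_length > 6) stop("max_length must be in 2..6")
  structure(
    list(precursor_tol_ppm = precursor_tol_ppm,
         fragment_tol_da = fragment_tol_da,
         max_length = max_length,
         min_length = as.integer(min_length),
         variable_mods = variable_mods,
         max_var_mods = as.integer(max_var_mods),
         min_fragment_coverage = min_fragment_coverage),
    class = "search_config"
  )
}

# Search alphabet: one row per extendable symbol. I is folded into the
# isobaric canonical L and re-expanded only at FASTA validation; substituted
# C/M ("CSe"/"MSe") are first-class symbols; a carbamidomethylated C counts
# as one variable modification.
search_alphabet <- function(cfg, chem) {
  letters20 <- setdiff(names(chem$residues), "I")
  sym <- data.frame(
    symbol = letters20,
    residue = letters20,
    mass = unname(chem$residues[letters20]),
    se = FALSE,
    mod = NA_character_,
    nvar = 0L,
    stringsAsFactors = FALSE
  )
  delta <- chem$constants[["se_minus_s_delta"]]
  sym <- rbind(sym, data.frame(
    symbol = c("CSe", "MSe"),
    residue = c("C", "M"),
    mass = unname(chem$residues[c("C", "M")]) + delta,
    se = TRUE, mod = NA_character_, nvar = 0L,
    stringsAsFactors = FALSE
  ))
  if ("carbamidomethyl" %in% cfg$variable_mods && cfg$max_var_mods >= 1) {
    sym <- rbind(sym, data.frame(
      symbol = "Ccam", residue = "C",
      mass = unname(chem$residues[["C"]]) + mod_delta("carbamidomethyl", chem),
      se = FALSE, mod = "carbamidomethyl", nvar = 1L,
      stringsAsFactors = FALSE
    ))
  }
  sym
}

symbols_to_peptide <- function(symbols, alphabet, nterm_mod, chem) {
  rows <- match(symbols, alphabet$symbol)
  residues <- alphabet$residue[rows]
  se_sites <- which(alphabet$se[rows])
  modded <- which(!is.na(alphabet$mod[rows]))
  site_mods <- if (length(modded) > 0) {
    stats::setNames(alphabet$mod[rows][modded], modded)
  } else NULL
  peptide(residues, se_sites = se_sites, nterm_mod = nterm_mod,
          site_mods = site_mods, chem = chem)
}

#' Enumerate candidate modified peptides under a precursor mass constraint
#'
#' Depth-first extension over prefix masses with branch-and-bound pruning:
#' prefixes are grown one residue symbol at a time (layer by layer, each layer
#' vectorized) and a branch is cut as soon as its prefix mass exceeds the
#' upper precursor bound, since every completion only adds mass. The result is
#' exactly the set of modified peptides of length `min_length..max_length`
#' over the search alphabet, with at most `max_var_mods` variable
#' modifications, whose neutral mass lies within `precursor_tol_ppm` of
#' `target_mass`.
#'
#' @param target_mass Neutral precursor mass in Da.
#' @param cfg A [search_config()].
#' @param chem Chemistry object.
#' @return List of `se_peptide` candidates, ordered by length, display name
#'   and modification signature. A mass below the smallest achievable peptide
#'   returns an empty list.
#' @export
enumerate_candidates <- function(target_mass, cfg = search_config(),
                                 chem = chem_defaults()) {
  water <- chem$constants[["water_mass"]]
  if (target_mass <= water) return(list())
  lo <- target_mass * (1 - cfg$precursor_tol_ppm * 1e-6)
  hi <- target_mass * (1 + cfg$precursor_tol_ppm * 1e-6)
  alphabet <- search_alphabet(cfg, chem)
  nsym <- nrow(alphabet)

  nterm_opts <- list(NULL)
  if ("acetyl" %in% cfg$variable_mods && cfg$max_var_mods >= 1) {
    nterm_opts <- c(nterm_opts, list("acetyl"))
  }

  out <- list()
  for (nterm in nterm_opts) {
    base_nvar <- if (is.null(nterm)) 0L else 1L
    base <- water + if (is.null(nterm)) 0 else mod_delta(nterm, chem)
    res_lo <- lo - base
    res_hi <- hi - base
    if (res_hi <= 0) next

    # layer state: symbol-index matrix, prefix mass, variable-mod count
    idx <- matrix(integer(0), nrow = 1, ncol = 0)
    mass <- 0
    nvar <- base_nvar
    for (depth in seq_len(cfg$max_length)) {
      nprev <- length(mass)
      if (nprev == 0) break
      new_idx <- cbind(idx[rep(seq_len(nprev), each = nsym), , drop = FALSE],
                       rep(seq_len(nsym), times = nprev))
      new_mass <- rep(mass, each = nsym) + alphabet$mass[new_idx[, depth]]
      new_nvar <- rep(nvar, each = nsym) + alphabet$nvar[new_idx[, depth]]
      keep <- new_mass <= res_hi & new_nvar <= cfg$max_var_mods
      idx <- new_idx[keep, , drop = FALSE]
      mass <- new_mass[keep]
      nvar <- new_nvar[keep]
      if (depth >= cfg$min_length) {
        hit <- which(mass >= res_lo)
        for (h in hit) {
          out[[length(out) + 1]] <- symbols_to_peptide(
            alphabet$symbol[idx[h, ]], alphabet, nterm, chem)
        }
      }
    }
  }
  if (length(out) == 0) return(out)
  key <- vapply(out, function(p) {
    paste(length(p$residues), display_name(p), mod_signature(p), sep = "|")
  }, character(1))
  out[order(key)]
}

# Compact textual modification signature, used for deduplication and reports.
mod_signature <- function(p) {
  parts <- c(
    if (!is.null(p$nterm_mod)) paste0("nterm:", p$nterm_mod),
    if (!is.null(p$site_mods)) paste0(names(p$site_mods), ":", p$site_mods)
  )
  paste(parts, collapse = ";")
}

#' Score one candidate against a spectrum
#'
#' Coverage is the fraction of the theoretical b/y ladder (charges 1 up to the
#' precursor charge) matched within the fragment tolerance; the score adds an
#' intensity-weighted bonus, `0.7 * coverage + 0.3 * matched-intensity
#' fraction`, both terms in \[0, 1\]. The score is a deterministic ranking
#' device, not a probability.
#'
#' @param p An `se_peptide` candidate.
#' @param spec An `ms2_spectrum`.
#' @param cfg A [search_config()].
#' @param chem Chemistry object.
#' @return One-row data frame with columns `display_name`, `mods`, `mass`,
#'   `ppm`, `length`, `n_se`, `se_residues`, `coverage`,
#'   `intensity_fraction`, `score`, `n_mods`.
#' @export
score_match <- function(p, spec, cfg = search_config(), chem = chem_defaults()) {
  ladder <- fragment_ladder(p, z_max = spec$precursor_z, chem = chem)
  m <- match_peaks(ladder, spec, tol_da = cfg$fragment_tol_da)
  coverage <- if (nrow(m) == 0) 0 else sum(m$within_tolerance) / nrow(m)
  total_int <- sum(spec$peaks$intensity)
  int_frac <- if (total_int > 0) {
    sum(m$intensity[m$within_tolerance], na.rm = TRUE) / total_int
  } else 0
  mass <- peptide_mass(p, chem)
  data.frame(
    display_name = display_name(p),
    mods = mod_signature(p),
    mass = mass,
    observed_mz = spec$precursor_mz,
    ppm = ppm_error(spec$precursor_mz, p, spec$precursor_z, chem),
    z = spec$precursor_z,
    length = length(p$residues),
    n_se = length(p$se_sites),
    se_residues = paste(se_residues(p), collapse = ""),
    coverage = coverage,
    intensity_fraction = int_frac,
    score = 0.7 * coverage + 0.3 * int_frac,
    n_mods = (!is.null(p$nterm_mod)) + length(p$site_mods),
    stringsAsFactors = FALSE
  )
}

# Expand the canonical (I folded into L) bare sequence of a peptide into all
# I/L variants and return those occurring as substrings of any protein.
fasta_expansions <- function(p, proteins) {
  seqs <- bare_sequence(p)
  lpos <- which(p$residues == "L")
  if (length(lpos) > 0) {
    combos <- expand.grid(rep(list(c("L", "I")), length(lpos)),
                          stringsAsFactors = FALSE)
    seqs <- apply(combos, 1, function(letters) {
      r <- p$residues
      r[lpos] <- letters
      paste(r, collapse = "")
    })
  }
  seqs <- unique(seqs)
  hits <- seqs[vapply(seqs, function(s) any(grepl(s, proteins, fixed = TRUE)),
                      logical(1))]
  sort(hits)
}

# Rebuild a display name for an I/L-expanded variant of a canonical peptide.
expanded_display <- function(p, expanded_seq) {
  residues <- strsplit(expanded_seq, "")[[1]]
  display_name(peptide(residues, se_sites = p$se_sites,
                       nterm_mod = p$nterm_mod, site_mods = p$site_mods))
}

#' Search one spectrum for selenopeptide candidates
#'
#' Enumerates candidates within the precursor tolerance, scores each by
#' fragment evidence, drops candidates below the minimum fragment coverage
#' and ranks the rest by descending score (ties: fewer modifications first,
#' then lexicographic display name — positional isomers with identical
#' fragment evidence therefore tie on score and are both reported). When a
#' protein set is given, each candidate's de-selenized bare sequence (selenium
#' sites mapped back to C/M, the canonical L expanded to both Leu and Ile) is
#' looked up as a substring; `fasta_validated` records whether any variant
#' occurs.
#'
#' @param spec An `ms2_spectrum`.
#' @param cfg A [search_config()].
#' @param fasta Optional named character vector of protein sequences, as
#'   returned by [read_fasta()].
#' @param chem Chemistry object.
#' @return Data frame of ranked matches (columns of [score_match()] plus
#'   `rank`, `fasta_validated`, `fasta_hits` and `spectrum_id`), empty when
#'   nothing passes.
#' @export
search_spectrum <- function(spec, cfg = search_config(), fasta = NULL,
                            chem = chem_defaults()) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  cands <- enumerate_candidates(precursor_mass(spec, chem), cfg, chem)
  empty <- data.frame(
    display_name = character(0), mods = character(0), mass = numeric(0),
    observed_mz = numeric(0), ppm = numeric(0), z = integer(0),
    length = integer(0), n_se = integer(0),
    se_residues = character(0), coverage = numeric(0),
    intensity_fraction = numeric(0), score = numeric(0), n_mods = integer(0),
    rank = integer(0), fasta_validated = logical(0), fasta_hits = character(0),
    spectrum_id = character(0), stringsAsFactors = FALSE
  )
  if (length(cands) == 0) return(empty)
  rows <- do.call(rbind, lapply(cands, score_match, spec = spec, cfg = cfg,
                                chem = chem))
  keep <- rows$coverage >= cfg$min_fragment_coverage
  rows <- rows[keep, , drop = FALSE]
  cands <- cands[keep]
  if (nrow(rows) == 0) return(empty)
  ord <- order(-rows$score, rows$n_mods, rows$display_name)
  rows <- rows[ord, , drop = FALSE]
  cands <- cands[ord]
  rows$rank <- seq_len(nrow(rows))
  if (!is.null(fasta)) {
    hits <- lapply(cands, fasta_expansions, proteins = fasta)
    rows$fasta_validated <- lengths(hits) > 0
    rows$fasta_hits <- vapply(hits, paste, character(1), collapse = ",")
  } else {
    rows$fasta_validated <- NA
    rows$fasta_hits <- ""
  }
  rows$spectrum_id <- spec$id
  rownames(rows) <- NULL
  attr(rows, "peptides") <- cands
  rows
}

#' Identify a set of peptides from a collection of spectra
#'
#' Pools, across spectra, every top-ranked match (all matches tied at the
#' best score of their spectrum) that passes the coverage filter and — when a
#' protein set is supplied — FASTA validation. A validated canonical match
#' whose Leu/Ile variants both occur in the proteins contributes one
#' identification per variant, mirroring how isobaric residues can only be
#' told apart by the database. Identifications are de-duplicated by
#' (display name, modification set), each keeping its best (smallest
#' absolute) ppm and best score.
#'
#' @param spectra List of `ms2_spectrum` objects.
#' @param cfg A [search_config()].
#' @param fasta Optional named character vector of protein sequences; when
#'   given, unvalidated matches are discarded.
#' @param label Sample label for the returned set.
#' @param chem Chemistry object.
#' @return A [peptide_set()].
#' @export
identify_dataset <- function(spectra, cfg = search_config(), fasta = NULL,
                             label = "sample", chem = chem_defaults()) {
  members <- list()
  for (spec in spectra) {
    matches <- search_spectrum(spec, cfg, fasta, chem)
    if (nrow(matches) == 0) next
    cands <- attr(matches, "peptides")
    top <- which(matches$score >= max(matches$score) - 1e-12)
    for (i in top) {
      if (!is.null(fasta) && !isTRUE(matches$fasta_validated[i])) next
      names_out <- matches$display_name[i]
      if (!is.null(fasta) && nzchar(matches$fasta_hits[i])) {
        hits <- strsplit(matches$fasta_hits[i], ",", fixed = TRUE)[[1]]
        names_out <- vapply(hits, expanded_display, character(1),
                            p = cands[[i]])
      }
      for (nm in names_out) {
        row <- matches[i, c("mods", "mass", "observed_mz", "ppm", "z",
                            "length", "n_se", "se_residues", "coverage",
                            "score", "spectrum_id"), drop = FALSE]
        row <- cbind(data.frame(display_name = nm, stringsAsFactors = FALSE),
                     row)
        members[[length(members) + 1]] <- row
      }
    }
  }
  if (length(members) == 0) {
    return(peptide_set(label, empty_members()))
  }
  all_rows <- do.call(rbind, members)
  key <- paste(all_rows$display_name, all_rows$mods, sep = "\r")
  split_rows <- split(all_rows, key)
  dedup <- do.call(rbind, lapply(split_rows, function(g) {
    g <- g[order(abs(g$ppm), -g$score), , drop = FALSE]
    best <- g[1, , drop = FALSE]
    best$score <- max(g$score)
    best
  }))
  dedup <- dedup[order(dedup$display_name, dedup$mods), , drop = FALSE]
  rownames(dedup) <- NULL
  peptide_set(label, dedup)
}
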