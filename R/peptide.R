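#' Modified peptides: construction, display names and parsing
#'
#' The unit of identification is a short peptide with optional selenium
#' substitutions (on Cys or Met only), at most one N-terminal modification and
#' at most one modification per residue site. Selenium sites are written in
#' display names with the field's convention of `"Se"` immediately after the
#' substituted letter, e.g. `"MSePGP"` for Met(Se)-Pro-Gly-Pro; parsing a
#' display name reconstructs the sequence and Se sites exactly.
#'
#' @param sequence Residue sequence, either a single string of one-letter
#'   codes or a character vector of single letters.
#' @param se_sites Integer positions carrying a selenium-for-sulfur
#'   substitution; each must point at a C or M.
#' @param nterm_mod Name of an N-terminal modification (e.g. `"acetyl"`) or
#'   `NULL`.
#' @param site_mods Named character vector mapping position (as names) to a
#'   residue modification name (e.g. `c("2" = "carbamidomethyl")`), or `NULL`.
#' @param chem Chemistry object, see [chem_defaults()].
#' @return An object of class `se_peptide`: a list with elements `residues`
#'   (character vector), `se_sites` (integer vector), `nterm_mod`
#'   (character or `NULL`) and `site_mods` (named character or `NULL`).
#' @examples
#' p <- peptide("MPGP", se_sites = 1, nterm_mod = "acetyl")
#' display_name(p)          # "MSePGP"
#' peptide_mass(p)          # 490.133 at 3 decimals
#' @export
peptide <- function(sequence, se_sites = integer(), nterm_mod = NULL,
                    site_mods = NULL, chem = chem_defaults()) {
  residues <- if (length(sequence) == 1 && nchar(sequence[1]) != 1) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  if (length(residues) == 0) stop("peptide sequence must be non-empty")
  bad <- which(!residues %in% names(chem$residues))
  if (length(bad) > 0) {
    stop("unknown residue letter '", residues[bad[1]], "' at position ", bad[1])
  }
  se_sites <- sort(unique(as.integer(se_sites)))
  if (length(se_sites) > 0) {
    if (any(se_sites < 1 | se_sites > length(residues))) {
      stop("selenium site out of sequence bounds")
    }
    off <- se_sites[!residues[se_sites] %in% c("C", "M")]
    if (length(off) > 0) {
      stop("selenium substitution restricted to C and M; position ", off[1],
           " is '", residues[off[1]], "'")
    }
  }
  if (!is.null(nterm_mod)) {
    if (length(nterm_mod) != 1) stop("at most one terminal modification")
    i <- match(nterm_mod, chem$mods$name)
    if (is.na(i) || chem$mods$site[i] != "nterm") {
      stop("'", nterm_mod, "' is not a known N-terminal modification")
    }
  }
  if (!is.null(site_mods) && length(site_mods) > 0) {
    pos <- as.integer(names(site_mods))
    if (anyNA(pos) || any(pos < 1 | pos > length(residues))) {
      stop("site modification position out of bounds")
    }
    if (anyDuplicated(pos)) stop("at most one modification per residue site")
    if (any(pos %in% se_sites)) {
      stop("a selenium-substituted site cannot carry a second modification")
    }
    for (k in seq_along(site_mods)) {
      i <- match(site_mods[[k]], chem$mods$name)
      if (is.na(i)) stop("unknown modification: '", site_mods[[k]], "'")
      allowed <- strsplit(chem$mods$site[i], "")[[1]]
      if (!residues[pos[k]] %in% allowed) {
        stop("modification '", site_mods[[k]], "' not allowed on '",
             residues[pos[k]], "' at position ", pos[k])
      }
    }
    site_mods <- site_mods[order(pos)]
  } else {
    site_mods <- NULL
  }
  structure(
    list(residues = residues, se_sites = se_sites,
         nterm_mod = nterm_mod, site_mods = site_mods),
    class = "se_peptide"
  )
}

#' @rdname peptide
#' @param p An `se_peptide` object.
#' @export
display_name <- function(p) {
  stopifnot(inherits(p, "se_peptide"))
  out <- p$residues
  if (length(p$se_sites) > 0) {
    out[p$se_sites] <- paste0(out[p$se_sites], "Se")
  }
  paste(out, collapse = "")
}

#' @rdname peptide
#' @param text A display name, one-letter codes with `"Se"` marking a
#'   substituted C or M; an optional `"Ac-"` prefix marks N-terminal
#'   acetylation.
#' @export
parse_peptide <- function(text, chem = chem_defaults()) {
  stopifnot(is.character(text), length(text) == 1)
  nterm <- NULL
  if (startsWith(text, "Ac-")) {
    nterm <- "acetyl"
    text <- sub("^Ac-", "", text)
  }
  chars <- strsplit(text, "")[[1]]
  if (length(chars) == 0) stop("empty peptide display name")
  residues <- character(0)
  se_sites <- integer(0)
  i <- 1
  while (i <= length(chars)) {
    letter <- chars[i]
    if (!letter %in% names(amino_acid_masses())) {
      stop("unknown residue letter '", letter, "' at character ", i)
    }
    residues <- c(residues, letter)
    if (i + 1 <= length(chars) && chars[i + 1] == "S" &&
        i + 2 <= length(chars) && chars[i + 2] == "e") {
      if (!letter %in% c("C", "M")) {
        stop("'Se' may only follow C or M, found after '", letter, "'")
      }
      se_sites <- c(se_sites, length(residues))
      i <- i + 3
    } else {
      i <- i + 1
    }
  }
  peptide(residues, se_sites = se_sites, nterm_mod = nterm, chem = chem)
}

#' @export
print.se_peptide <- function(x, ...) {
  mods <- c(
    if (!is.null(x$nterm_mod)) paste0("nterm:", x$nterm_mod),
    if (!is.null(x$site_mods)) paste0(names(x$site_mods), ":", x$site_mods)
  )
  cat("<se_peptide> ", display_name(x),
      if (length(mods) > 0) paste0(" [", paste(mods, collapse = ", "), "]"),
      "  ", format(peptide_mass(x), nsmall = 3), " Da\n", sep = "")
  invisible(x)
}

#' Monoisotopic peptide mass, m/z and ppm error
#'
#' `peptide_mass()` sums the residue masses, adds one water, every
#' modification delta and one Se-S shift (47.94445 Da) per selenium site.
#' `mass_to_mz()` protonates: (mass + z * proton) / z. `ppm_error()` is the
#' relative deviation of an observed m/z from the theoretical value of the
#' peptide's `[M + zH]z+` ion, in parts per million, signed
#' (observed - theoretical) / theoretical.
#'
#' @param p An `se_peptide` object.
#' @param chem Chemistry object, see [chem_defaults()].
#' @return `peptide_mass()`: neutral monoisotopic mass in Da.
#' @examples
#' mass_to_mz(peptide_mass(parse_peptide("FCSeH")), z = 1)
#' ppm_error(416.0704, parse_peptide("Ac-CSeGF"), z = 1)  # about -3.65
#' @export
peptide_mass <- function(p, chem = chem_defaults()) {
  stopifnot(inherits(p, "se_peptide"))
  bad <- which(!p$residues %in% names(chem$residues))
  if (length(bad) > 0) {
    stop("unknown residue letter '", p$residues[bad[1]],
         "' at position ", bad[1])
  }
  mass <- sum(chem$residues[p$residues]) + chem$constants[["water_mass"]] +
    length(p$se_sites) * chem$constants[["se_minus_s_delta"]]
  if (!is.null(p$nterm_mod)) mass <- mass + mod_delta(p$nterm_mod, chem)
  if (!is.null(p$site_mods)) {
    mass <- mass + sum(vapply(p$site_mods, mod_delta, numeric(1), chem = chem))
  }
  unname(mass)
}

#' @rdname peptide_mass
#' @param mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @export
mass_to_mz <- function(mass, z = 1, chem = chem_defaults()) {
  z <- as.integer(z)
  if (any(z < 1)) stop("charge z must be >= 1")
  (mass + z * chem$constants[["proton_mass"]]) / z
}

#' @rdname peptide_mass
#' @param observed_mz Observed m/z (must be positive).
#' @return `ppm_error()`: signed ppm error, unrounded; pass through
#'   [reported_ppm()] for the 1-decimal reporting convention.
#' @export
ppm_error <- function(observed_mz, p, z = 1, chem = chem_defaults()) {
  if (any(observed_mz <= 0)) stop("observed m/z must be positive")
  theo <- mass_to_mz(peptide_mass(p, chem), z, chem)
  1e6 * (observed_mz - theo) / theo
}

#' Count of selenium sites and the residues that carry them
#'
#' @param p An `se_peptide` object.
#' @return `se_residues()`: character vector of the original (sulfur)
#'   residue letters at the selenium sites, e.g. `"C"` for selenocysteine.
#' @export
se_residues <- function(p) {
  stopifnot(inherits(p, "se_peptide"))
  p$residues[p$se_sites]
}

#' De-selenized bare sequence for database validation
#'
#' Maps selenium sites back to their sulfur residues (the form in which the
#' sequence occurs in a protein database) and returns the plain string.
#'
#' @param p An `se_peptide` object.
#' @return Character string of one-letter codes.
#' @export
bare_sequence <- function(p) {
  stopifnot(inherits(p, "se_peptide"))
  paste(p$residues, collapse = "")
}
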