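#' Monoisotopic residue masses, constants and the modification vocabulary
#'
#' High-resolution MS measures monoisotopic masses, so every mass in this
#' package is computed from monoisotopic residue masses fixed at five decimal
#' places. Leucine and isoleucine are isobaric and share one value. The
#' selenium-for-sulfur substitution shift is the monoisotopic difference
#' between Se-80 and S-32, 79.91652 - 31.97207 = 47.94445 Da, the diagnostic
#' delta for selenocysteine and selenomethionine.
#'
#' `chem_defaults()` bundles the residue table, the physical constants and the
#' default variable-modification vocabulary into the single chemistry object
#' that every mass-aware function takes as its `chem` argument. Defaults are
#' embedded; [load_chem_config()] overrides individual values from a flat
#' key-value file.
#'
#' @return `amino_acid_masses()`: a named numeric vector, one-letter residue
#'   code to monoisotopic residue mass in Da. `chem_constants()`: named numeric
#'   vector with `water_mass`, `proton_mass` and `se_minus_s_delta` (Da).
#'   `default_modifications()`: data frame with columns `name`, `delta_mass`
#'   (Da), `site` (residue letters, or `"nterm"`) and `kind`.
#'   `chem_defaults()`: list with elements `residues`, `constants`, `mods`.
#' @examples
#' chem_constants()[["se_minus_s_delta"]]  # 47.94445
#' @export
amino_acid_masses <- function() {
  c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

#' @rdname amino_acid_masses
#' @export
chem_constants <- function() {
  c(
    water_mass = 18.01056,
    proton_mass = 1.00728,
    se_minus_s_delta = 47.94445
  )
}

#' @rdname amino_acid_masses
#' @export
default_modifications <- function() {
  data.frame(
    name = c("se", "acetyl", "carbamidomethyl"),
    delta_mass = c(47.94445, 42.01057, 57.02146),
    site = c("CM", "nterm", "C"),
    kind = c("variable", "variable", "variable"),
    stringsAsFactors = FALSE
  )
}

#' @rdname amino_acid_masses
#' @export
chem_defaults <- function() {
  chem <- list(
    residues = amino_acid_masses(),
    constants = chem_constants(),
    mods = default_modifications()
  )
  class(chem) <- "chem_table"
  validate_chem(chem)
}

validate_chem <- function(chem) {
  res <- chem$residues
  if (!all(strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]] %in% names(res))) {
    stop("residue mass table must contain all 20 standard residues")
  }
  if (res[["L"]] != res[["I"]]) stop("Leu and Ile must share one mass")
  if (any(res <= 0) || any(chem$constants <= 0)) {
    stop("all masses must be strictly positive")
  }
  chem
}

#' Override chemistry defaults from a flat configuration file
#'
#' Reads a flat key-value file (YAML scalars, no nesting) and returns a
#' chemistry object with the listed values replaced. Recognised keys:
#' `residue_<X>` for any one-letter residue code, the three constants
#' (`water_mass`, `proton_mass`, `se_minus_s_delta`) and `mod_<name>_delta`
#' for a modification's delta mass. Unknown keys fail fast so typos cannot
#' silently leave a default in place.
#'
#' @param path Path to the configuration file.
#' @param chem Chemistry object to start from, by default [chem_defaults()].
#' @return A chemistry object (see [chem_defaults()]).
#' @export
load_chem_config <- function(path, chem = chem_defaults()) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) return(chem)
  if (is.null(names(cfg)) || any(names(cfg) == "")) {
    stop("chemistry config must be a flat key: value mapping")
  }
  for (key in names(cfg)) {
    val <- cfg[[key]]
    if (!is.numeric(val) || length(val) != 1) {
      stop("config key '", key, "' must be a single number")
    }
    if (grepl("^residue_[A-Z]$", key)) {
      letter <- sub("^residue_", "", key)
      if (!letter %in% names(chem$residues)) {
        stop("config key '", key, "': unknown residue letter")
      }
      chem$residues[[letter]] <- val
      if (letter %in% c("L", "I")) {
        chem$residues[["L"]] <- val
        chem$residues[["I"]] <- val
      }
    } else if (key %in% names(chem$constants)) {
      chem$constants[[key]] <- val
    } else if (grepl("^mod_.+_delta$", key)) {
      name <- sub("^mod_", "", sub("_delta$", "", key))
      if (!name %in% chem$mods$name) {
        stop("config key '", key, "': unknown modification")
      }
      chem$mods$delta_mass[chem$mods$name == name] <- val
    } else {
      stop("unknown chemistry config key: '", key, "'")
    }
  }
  validate_chem(chem)
}

mod_delta <- function(name, chem) {
  i <- match(name, chem$mods$name)
  if (is.na(i)) stop("unknown modification: '", name, "'")
  chem$mods$delta_mass[i]
}

#' Round half away from zero at a fixed number of decimals
#'
#' Reported masses follow the half-up convention (3 decimals for Da, 4 for
#' m/z) rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate toward zero at one decimal, the reported-ppm convention
#'
#' Reported ppm errors are cut, not rounded, at one decimal: this convention
#' reproduces the reference identifications' printed ppm column from their own
#' observed m/z values (e.g. a computed -17.26 ppm is reported as -17.2).
#'
#' @param x Numeric vector of ppm values.
#' @return Numeric vector truncated toward zero at one decimal.
#' @export
reported_ppm <- function(x) {
  trunc(x * 10) / 10
}
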