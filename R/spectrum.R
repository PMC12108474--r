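#' Centroided MS/MS spectrum
#'
#' A spectrum is the unit of evidence: a precursor (m/z, charge) plus a
#' centroided peak list. Peaks are stored sorted by m/z with non-negative
#' coordinates.
#'
#' @param id Spectrum identifier (MGF TITLE).
#' @param precursor_mz Precursor m/z (positive).
#' @param precursor_z Precursor charge, a positive integer.
#' @param peaks Data frame with numeric columns `mz` and `intensity`, or a
#'   two-column matrix.
#' @param rt Retention time in seconds, optional.
#' @return An object of class `ms2_spectrum`.
#' @export
spectrum <- function(id, precursor_mz, precursor_z = 1L, peaks = NULL,
                     rt = NA_real_) {
  if (!is.numeric(precursor_mz) || precursor_mz <= 0) {
    stop("precursor m/z must be positive")
  }
  precursor_z <- as.integer(precursor_z)
  if (is.na(precursor_z) || precursor_z < 1) stop("precursor charge must be >= 1")
  if (is.null(peaks)) {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  }
  peaks <- as.data.frame(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    names(peaks) <- c("mz", "intensity")[seq_len(ncol(peaks))]
  }
  if (nrow(peaks) > 0) {
    if (any(peaks$mz < 0) || any(peaks$intensity < 0)) {
      stop("peak m/z and intensity must be non-negative")
    }
    peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(
    list(id = as.character(id), precursor_mz = precursor_mz,
         precursor_z = precursor_z, peaks = peaks, rt = rt),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", x$id, "  precursor ",
      format(x$precursor_mz, nsmall = 4), " m/z (", x$precursor_z, "+), ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Neutral precursor mass of a spectrum
#'
#' @param s An `ms2_spectrum`.
#' @param chem Chemistry object.
#' @return Neutral mass in Da: `precursor_mz * z - z * proton`.
#' @export
precursor_mass <- function(s, chem = chem_defaults()) {
  stopifnot(inherits(s, "ms2_spectrum"))
  s$precursor_mz * s$precursor_z -
    s$precursor_z * chem$constants[["proton_mass"]]
}
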