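#' Identified peptide collections and sample-vs-control comparison
#'
#' A `peptide_set` holds the identifications of one sample arm, unique by
#' (display name, modification set). The differential step mirrors how a
#' selenium-free control is used: any selenium-containing peptide that also
#' appears in the control cannot be attributed to selenium enrichment and is
#' excluded from further analysis. Sharing is judged on the display name
#' alone, ignoring terminal modifications, since the control-side modification
#' state is not informative for identity.
#'
#' @param label Sample name.
#' @param members Data frame with at least columns `display_name` and `mods`;
#'   typically the output of [identify_dataset()].
#' @return An object of class `peptide_set`.
#' @export
peptide_set <- function(label, members) {
  members <- as.data.frame(members)
  if (!all(c("display_name", "mods") %in% names(members))) {
    stop("members need 'display_name' and 'mods' columns")
  }
  if (anyDuplicated(paste(members$display_name, members$mods, sep = "\r"))) {
    stop("members must be unique by (display_name, modification set)")
  }
  if (!"n_se" %in% names(members)) {
    members$n_se <- vapply(members$display_name, function(d) {
      length(parse_peptide(d)$se_sites)
    }, integer(1))
  }
  if (!"se_residues" %in% names(members)) {
    members$se_residues <- vapply(members$display_name, function(d) {
      paste(se_residues(parse_peptide(d)), collapse = "")
    }, character(1))
  }
  if (!"length" %in% names(members)) {
    members$length <- vapply(members$display_name, function(d) {
      length(parse_peptide(d)$residues)
    }, integer(1))
  }
  rownames(members) <- NULL
  structure(list(label = label, members = members), class = "peptide_set")
}

empty_members <- function() {
  data.frame(
    display_name = character(0), mods = character(0), mass = numeric(0),
    observed_mz = numeric(0), ppm = numeric(0), z = integer(0),
    length = integer(0), n_se = integer(0),
    se_residues = character(0), coverage = numeric(0), score = numeric(0),
    spectrum_id = character(0), stringsAsFactors = FALSE
  )
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("<peptide_set> '", x$label, "': ", nrow(x$members), " peptides (",
      sum(x$members$n_se > 0), " selenium-containing)\n", sep = "")
  invisible(x)
}

se_subset <- function(s) {
  s$members[s$members$n_se > 0, , drop = FALSE]
}

#' Exclude selenopeptides shared with a selenium-free control
#'
#' Partitions the sample's selenium-containing peptides into those unique to
#' the sample and those whose display name also occurs in the control set.
#' Counts (total, selenocysteine-type, selenomethionine-type) and the length
#' histogram are computed on the full sample set *before* exclusion, matching
#' how identifications are tallied before the control comparison.
#'
#' @param sample,control `peptide_set` objects.
#' @return A list of class `differential_report` with elements
#'   `unique_to_sample` and `shared` (both `peptide_set`), `counts`
#'   (`total`, `sec`, `semet`) and `length_histogram`.
#' @export
exclude_shared <- function(sample, control) {
  stopifnot(inherits(sample, "peptide_set"), inherits(control, "peptide_set"))
  se_members <- se_subset(sample)
  shared_mask <- se_members$display_name %in% control$members$display_name
  cls <- classify_se_type(sample)
  structure(
    list(
      unique_to_sample = peptide_set(
        paste0(sample$label, "_unique"),
        se_members[!shared_mask, , drop = FALSE]),
      shared = peptide_set(
        paste0(sample$label, "_shared"),
        se_members[shared_mask, , drop = FALSE]),
      counts = list(total = nrow(se_members),
                    sec = cls[["sec"]], semet = cls[["semet"]]),
      length_histogram = length_distribution(sample)
    ),
    class = "differential_report"
  )
}

#' @export
print.differential_report <- function(x, ...) {
  cat(x$counts$total, " Se-peptides; ", nrow(x$shared$members),
      " shared excluded; Sec/SeMet = ", x$counts$sec, "/", x$counts$semet,
      "\n", sep = "")
  invisible(x)
}

#' Classify selenopeptides as selenocysteine- or selenomethionine-type
#'
#' A peptide counts as selenocysteine-type if any selenium site sits on a
#' cysteine and as selenomethionine-type if any sits on a methionine; a
#' hypothetical peptide carrying both site types counts in both classes, so
#' the two counts need not sum to the total.
#'
#' @param s A `peptide_set`.
#' @return Named integer vector `c(sec = ..., semet = ...)`.
#' @export
classify_se_type <- function(s) {
  stopifnot(inherits(s, "peptide_set"))
  se <- se_subset(s)
  c(sec = sum(grepl("C", se$se_residues, fixed = TRUE)),
    semet = sum(grepl("M", se$se_residues, fixed = TRUE)))
}

#' Length distribution of the selenium-containing peptides in a set
#'
#' @param s A `peptide_set`.
#' @return Named integer vector, residue count to number of peptides; empty
#'   for an empty set.
#' @export
length_distribution <- function(s) {
  stopifnot(inherits(s, "peptide_set"))
  se <- se_subset(s)
  if (nrow(se) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(se$length)
  stats::setNames(as.integer(tab), names(tab))
}
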