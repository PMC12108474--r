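#' Amino-acid composition tables and group summaries
#'
#' Acid-hydrolysis amino-acid analysis reports amounts in mg per g of sample
#' for the recoverable amino acids (17 of the 20; Trp is destroyed by acid
#' hydrolysis and Asn/Gln are deamidated into Asp/Glu). The groups summarized
#' are the conventional ones in the antioxidant-peptide literature and are
#' overridable: essential = \{H, I, L, K, M, F, T, W, V\}; hydrophobic =
#' \{G, A, V, L, I, P, F, M, W\}.
#'
#' @param label Sample name.
#' @param amounts Named numeric vector, one-letter amino-acid code to amount
#'   in mg/g; all values non-negative.
#' @return An object of class `composition_table`.
#' @export
composition_table <- function(label, amounts) {
  if (length(amounts) == 0) {
    amounts <- stats::setNames(numeric(0), character(0))
  }
  if (length(amounts) > 0 &&
      (is.null(names(amounts)) || any(names(amounts) == ""))) {
    stop("amounts must be named by one-letter amino-acid codes")
  }
  bad <- which(!names(amounts) %in% names(amino_acid_masses()))
  if (length(bad) > 0) {
    stop("unknown amino-acid letter '", names(amounts)[bad[1]],
         "' at entry ", bad[1])
  }
  if (any(amounts < 0)) stop("amounts must be non-negative")
  if (anyDuplicated(names(amounts))) stop("duplicate amino-acid entries")
  structure(list(label = label, amounts = amounts),
            class = "composition_table")
}

#' @rdname composition_table
#' @param path TSV file with columns `amino_acid` (one-letter code) and
#'   `amount_mg_per_g`.
#' @export
read_composition <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "amount_mg_per_g") %in% names(df))) {
    stop("composition TSV needs columns amino_acid, amount_mg_per_g")
  }
  composition_table(label,
                    stats::setNames(df$amount_mg_per_g, df$amino_acid))
}

#' @export
print.composition_table <- function(x, ...) {
  s <- summarize_composition(x)
  cat("<composition_table> '", x$label, "': ", length(x$amounts),
      " amino acids, total ", format(s[["total"]], nsmall = 2), " mg/g\n",
      sep = "")
  invisible(x)
}

default_essential_set <- function() c("H", "I", "L", "K", "M", "F", "T", "W", "V")
default_hydrophobic_set <- function() c("G", "A", "V", "L", "I", "P", "F", "M", "W")

#' Group sums of an amino-acid composition table
#'
#' @param t A [composition_table()].
#' @param essential,hydrophobic Character vectors of one-letter codes
#'   defining the groups.
#' @return Named numeric vector `c(total, essential, hydrophobic)` in mg/g.
#'   The hydrophobic sum plus the sum over non-hydrophobic entries equals the
#'   total exactly.
#' @export
summarize_composition <- function(t, essential = default_essential_set(),
                                  hydrophobic = default_hydrophobic_set()) {
  stopifnot(inherits(t, "composition_table"))
  a <- t$amounts
  c(total = sum(a),
    essential = sum(a[names(a) %in% essential]),
    hydrophobic = sum(a[names(a) %in% hydrophobic]))
}

#' Signed differences between two composition tables
#'
#' Computes `a - b` for every amino acid and for each group sum; an acid
#' missing from one table is treated as 0 mg/g (and noted via a message).
#'
#' @param a,b [composition_table()] objects.
#' @param essential,hydrophobic Group definitions, as in
#'   [summarize_composition()].
#' @return List with `per_acid` (named numeric vector of signed differences)
#'   and `groups` (named numeric vector `total`, `essential`, `hydrophobic`).
#' @export
compare_tables <- function(a, b, essential = default_essential_set(),
                           hydrophobic = default_hydrophobic_set()) {
  stopifnot(inherits(a, "composition_table"), inherits(b, "composition_table"))
  keys <- sort(union(names(a$amounts), names(b$amounts)))
  missing_a <- setdiff(keys, names(a$amounts))
  missing_b <- setdiff(keys, names(b$amounts))
  if (length(missing_a) > 0 || length(missing_b) > 0) {
    message("treating missing entries as 0 mg/g: ",
            paste(unique(c(missing_a, missing_b)), collapse = ", "))
  }
  va <- stats::setNames(rep(0, length(keys)), keys)
  vb <- va
  va[names(a$amounts)] <- a$amounts
  vb[names(b$amounts)] <- b$amounts
  sa <- summarize_composition(a, essential, hydrophobic)
  sb <- summarize_composition(b, essential, hydrophobic)
  list(per_acid = va - vb, groups = sa - sb)
}
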