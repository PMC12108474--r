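#' Theoretical b/y fragment-ion ladder
#'
#' Collision-induced fragmentation of protonated peptides is dominated by the
#' b (N-terminal) and y (C-terminal) backbone series; `fragment_ladder()`
#' generates all b_i and y_i for i in 1..n-1 at charges 1..`z_max`. b ions
#' carry the N-terminal modification delta; y ions carry the C-terminal water.
#' A fragment `contains_se` when its residue span includes at least one
#' selenium site, which is what lets the 47.944 Da shift be localized: every
#' fragment spanning the site is shifted, every other fragment is not.
#'
#' @param p An `se_peptide` of length >= 2.
#' @param z_max Highest fragment charge to generate (default 1).
#' @param chem Chemistry object.
#' @return Data frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`, `contains_se` and `label` (e.g. `"b2"`, `"y3^2"`).
#' @examples
#' fragment_ladder(parse_peptide("MSePGP"))
#' @export
fragment_ladder <- function(p, z_max = 1L, chem = chem_defaults()) {
  stopifnot(inherits(p, "se_peptide"))
  n <- length(p$residues)
  if (n < 2) stop("fragment ladder requires peptide length >= 2")
  z_max <- as.integer(z_max)
  if (z_max < 1) stop("z_max must be >= 1")

  delta_se <- chem$constants[["se_minus_s_delta"]]
  proton <- chem$constants[["proton_mass"]]
  water <- chem$constants[["water_mass"]]

  per_site <- chem$residues[p$residues]
  if (length(p$se_sites) > 0) per_site[p$se_sites] <- per_site[p$se_sites] + delta_se
  if (!is.null(p$site_mods)) {
    pos <- as.integer(names(p$site_mods))
    per_site[pos] <- per_site[pos] +
      vapply(p$site_mods, mod_delta, numeric(1), chem = chem)
  }
  nterm_delta <- if (is.null(p$nterm_mod)) 0 else mod_delta(p$nterm_mod, chem)

  prefix <- cumsum(per_site)
  idx <- seq_len(n - 1)
  b_neutral <- prefix[idx] + nterm_delta
  y_neutral <- prefix[n] - prefix[n - idx] + water
  b_se <- vapply(idx, function(i) any(p$se_sites <= i), logical(1))
  y_se <- vapply(idx, function(i) any(p$se_sites > n - i), logical(1))

  out <- do.call(rbind, lapply(seq_len(z_max), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1),
      index = rep(idx, 2),
      charge = z,
      mz = c((b_neutral + z * proton) / z, (y_neutral + z * proton) / z),
      contains_se = c(b_se, y_se),
      stringsAsFactors = FALSE
    )
  }))
  out$label <- paste0(out$series, out$index,
                      ifelse(out$charge > 1, paste0("^", out$charge), ""))
  rownames(out) <- NULL
  out
}

#' Match a theoretical ladder against observed peaks
#'
#' Assignment is greedy nearest-first: all fragment-peak pairs are ordered by
#' ascending absolute m/z difference (ties broken toward the lower-index
#' fragment), and each fragment and each observed peak is consumed at most
#' once. Fragments whose nearest available peak lies beyond the tolerance are
#' returned with `within_tolerance = FALSE`; the matched set at a tolerance t1
#' is always a subset of the matched set at any t2 >= t1.
#'
#' @param ladder Data frame from [fragment_ladder()].
#' @param spec An `ms2_spectrum` (peaks are sorted internally if needed).
#' @param tol_da Absolute match tolerance in Da (default 0.02, the regime of
#'   an Orbitrap acquisition at resolution 60,000). Set `tol_ppm` instead for
#'   a relative tolerance; exactly one of the two is used.
#' @param tol_ppm Optional relative tolerance in ppm; overrides `tol_da`.
#' @return Data frame with one row per ladder fragment: the ladder columns
#'   plus `observed_mz`, `intensity`, `delta_mz` (observed - theoretical) and
#'   `within_tolerance`. Unpaired fragments have `NA` observations.
#' @export
match_peaks <- function(ladder, spec, tol_da = 0.02, tol_ppm = NULL) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  nf <- nrow(ladder)
  out <- ladder
  out$observed_mz <- NA_real_
  out$intensity <- NA_real_
  out$delta_mz <- NA_real_
  out$within_tolerance <- FALSE
  peaks <- spec$peaks
  if (nf == 0 || nrow(peaks) == 0) return(out)
  if (is.unsorted(peaks$mz)) peaks <- peaks[order(peaks$mz), ]

  delta <- outer(peaks$mz, ladder$mz, "-")      # peaks x fragments
  ad <- abs(delta)
  ord <- order(ad, rep(seq_len(nf), each = nrow(peaks)))
  used_peak <- logical(nrow(peaks))
  used_frag <- logical(nf)
  for (k in ord) {
    pk <- (k - 1) %% nrow(peaks) + 1
    fr <- (k - 1) %/% nrow(peaks) + 1
    if (used_peak[pk] || used_frag[fr]) next
    used_peak[pk] <- TRUE
    used_frag[fr] <- TRUE
    out$observed_mz[fr] <- peaks$mz[pk]
    out$intensity[fr] <- peaks$intensity[pk]
    out$delta_mz[fr] <- delta[pk, fr]
    if (all(used_frag) || all(used_peak)) break
  }
  tol <- if (!is.null(tol_ppm)) 1e-6 * tol_ppm * out$mz else tol_da
  out$within_tolerance <- !is.na(out$delta_mz) & abs(out$delta_mz) <= tol
  out
}

#' Localize selenium sites from fragment evidence
#'
#' Given a spectrum and the unsubstituted (sulfur) form of a peptide, tests
#' every subset of its C/M positions as a selenium-substitution hypothesis and
#' returns the subset whose shifted b/y ladder explains the most peaks within
#' tolerance. The empty subset is a legal answer: a spectrum of the
#' unsubstituted peptide yields no shift evidence and returns no sites. Ties
#' go to the hypothesis with fewer sites, then to the lexicographically
#' smallest position set.
#'
#' @param spec An `ms2_spectrum`.
#' @param p_without_se An `se_peptide` with no selenium sites set and at least
#'   one C or M in its sequence.
#' @param n_se Optional fixed number of selenium sites (e.g. inferred from the
#'   precursor mass); when given only subsets of that size (plus the empty
#'   set for comparison) are tested.
#' @param tol_da,tol_ppm Match tolerance, as in [match_peaks()].
#' @param chem Chemistry object.
#' @return Integer vector of selenium positions (possibly empty).
#' @examples
#' p <- parse_peptide("CSeCL")
#' s <- simulate_spectrum(p, sim_config(mz_jitter_ppm = 0,
#'   missing_fragment_rate = 0, noise_peaks = 0))
#' localize_se(s, parse_peptide("CCL"))  # 1
#' @export
localize_se <- function(spec, p_without_se, n_se = NULL, tol_da = 0.02,
                        tol_ppm = NULL, chem = chem_defaults()) {
  stopifnot(inherits(p_without_se, "se_peptide"))
  if (length(p_without_se$se_sites) > 0) {
    stop("p_without_se must carry no selenium sites")
  }
  cand <- which(p_without_se$residues %in% c("C", "M"))
  if (length(cand) == 0) {
    stop("no C or M in sequence: selenium substitution impossible")
  }
  sizes <- if (is.null(n_se)) 0:length(cand) else unique(c(0L, as.integer(n_se)))
  hyps <- list()
  for (k in sizes) {
    if (k == 0) {
      hyps <- c(hyps, list(integer(0)))
    } else if (k <= length(cand)) {
      cc <- utils::combn(cand, k, simplify = FALSE)
      hyps <- c(hyps, cc)
    }
  }
  score <- vapply(hyps, function(sites) {
    q <- peptide(p_without_se$residues, se_sites = sites,
                 nterm_mod = p_without_se$nterm_mod,
                 site_mods = p_without_se$site_mods, chem = chem)
    m <- match_peaks(fragment_ladder(q, chem = chem), spec,
                     tol_da = tol_da, tol_ppm = tol_ppm)
    sum(m$within_tolerance)
  }, numeric(1))
  nsites <- lengths(hyps)
  keys <- vapply(hyps, function(s) paste(sprintf("%03d", s), collapse = ","),
                 character(1))
  best <- order(-score, nsites, keys)[1]
  hyps[[best]]
}
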