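---
title: "Identifying selenopeptides from tandem mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying selenopeptides from tandem mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selenopept)
```

## The method

Selenium-enriched organisms replace the sulfur of cysteine and methionine
with selenium, producing selenocysteine (Sec) and selenomethionine (SeMet).
The monoisotopic mass difference between Se-80 and S-32 is

$$\Delta(\mathrm{Se}-\mathrm{S}) = 79.91652 - 31.97207 = 47.94445\ \mathrm{Da},$$

so a selenopeptide sits exactly 47.94445 Da per substituted site above its
sulfur form. Identification proceeds in four stages:

1. **Candidate enumeration.** Given a spectrum's neutral precursor mass
   $M = m/z \cdot z - z\,m_p$, all modified peptides within a ppm window are
   enumerated de novo over an alphabet that includes Se-substituted C and M
   as first-class residues. The search is a depth-first extension over
   prefix masses with branch-and-bound pruning: since every residue adds
   positive mass, a prefix exceeding the upper precursor bound can be cut
   with its whole subtree. The hydrolysate is cleaved non-specifically, so
   no enzyme rule restricts candidates, and the protein database is used for
   validation, not generation.
2. **Fragment scoring.** Each candidate's theoretical b/y ladder (the
   dominant series under low-energy collisional fragmentation) is matched
   against the peaks greedily by ascending $|\Delta m/z|$ with one-to-one
   consumption. Coverage is the matched fraction of the ladder; the score is
   $0.7\,\mathrm{coverage} + 0.3\,\mathrm{matched\ intensity\ fraction}$ — a
   deterministic ranking device, not a probability. Fragments spanning a
   selenium site shift by exactly $\Delta(\mathrm{Se}-\mathrm{S})$, the rest
   do not, which is also how `localize_se()` places the site.
3. **FASTA back-validation.** The de-selenized bare sequence (Se sites
   mapped back to C/M) must occur as a substring of a protein. Leu and Ile
   are isobaric, so candidates are generated in a canonical Leu form and
   expanded to both letters only here; if both variants occur in the
   proteins, both are reported, since mass spectrometry alone cannot
   distinguish them.
4. **Differential exclusion.** Any selenopeptide whose display name is also
   identified in the selenium-free control arm cannot be attributed to
   enrichment and is excluded; counts and the length histogram are tabulated
   on the pre-exclusion set.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `precursor_tol_ppm` | 20 | ppm | the reference identifications' own ppm errors span −17.2 to +13.9, so the acceptance window must be at least ~18 ppm |
| `fragment_tol_da` | 0.02 | Da | Orbitrap acquisition at resolution 60,000; ppm mode available |
| `max_length` | 4 | residues | the selenopeptides of interest are 3–4 residues |
| `variable_mods` | acetyl, carbamidomethyl | — | sample preparation alkylates with iodoacetamide, yet the published masses show no carbamidomethyl and, for 8 of 16 peptides, one +42.011 terminal modification; both must therefore be *searchable*, neither fixed |
| `max_var_mods` | 2 | — | covers every observed assignment while keeping enumeration tractable; the Se substitution itself is part of the alphabet and not counted |
| `min_fragment_coverage` | 0.5 | fraction | half-ladder support is the weakest evidence that still separates positional isomers in fixtures |

The +42.011 Da terminal modification is *discovered* per peptide by
`resolve_reference_mods()`, which tries the unmodified and acetylated
assignments and keeps the one reproducing the published mass at 3 decimals;
N-terminal acetylation is the assumed chemistry, recorded as an inference
rather than an observation.

## Numerical conventions

- Element constants are fixed at five decimals: proton 1.00728, water
  18.01056, $\Delta(\mathrm{Se}-\mathrm{S})$ 47.94445. The published masses
  reproduce at 3 decimals only with monoisotopic (never average) masses.
- Reported Da values round half-up at 3 decimals (`round_half_up()`), m/z at
  4; reported ppm values are **truncated toward zero** at one decimal
  (`reported_ppm()`). Truncation, not rounding, is what reproduces the
  reference ppm column from its own observed m/z values (a computed −17.26
  is reported as −17.2, −3.65 as −3.6).
- One reference row (`MSeCT`) is internally inconsistent as published: its
  observed m/z does not reproduce its ppm. The row is flagged
  (`mz_inconsistent`), the ppm-consistent m/z (444.0764) is carried in a
  separate column for fixtures, and the published number is never silently
  corrected.
- Ties in ranking break by fewer modifications, then lexicographic display
  name, making output order-independent. Positional isomers with identical
  fragment evidence (e.g. when their separating ions are absent) tie on
  score and are both reported at the top.
- Degenerate inputs: an empty peak list yields zero matches, not an error; a
  precursor below the lightest residue yields an empty candidate list; a
  spectrum without a charge annotation is assumed singly charged with a
  warning; files with zero valid records are fatal.

## What the simulator emulates — and what it does not

`simulate_spectrum()` produces centroided, singly charged spectra: the b/y
ladder with Gaussian relative m/z error, each fragment independently dropped,
uniform noise peaks, and multiplicative lognormal intensities that carry no
sequence information. Defaults (chosen once as the study conditions, before
any end-to-end run): seed 42, 5 ppm jitter (well inside the 20 ppm precursor
window and consistent with the reference ppm spread), 10% missing fragments,
10 noise peaks over m/z 100–1000 (the fragment region of 3–4-mers), 20
decoys per arm drawn from the 18 letters excluding C and M — so a decoy can
never legitimately carry selenium and any Se-containing identification from
a decoy spectrum is a false positive by construction. Decoys are redrawn
until their `[M+H]+` lies in the instrument's m/z 350–2000 acquisition
range.

The simulator does **not** model isotope envelopes, charge states above 1,
neutral losses, internal/immonium ions, retention time or chromatographic
interference, and its intensities are uninformative. Passing tests therefore
demonstrate the correctness of the arithmetic, the search and the
differential logic under a clean, known-truth regime — not the engine's
performance on real chromatographic data, where co-isolation and wider
modification spaces would lower coverage.

## Recovery under noise, and what "recovered" means

The recovery property (30 random selenopeptides per seed, 5 seeds, 5 ppm
jitter, 20% missing fragments, 10 noise peaks) counts a spectrum as
recovered when the true sequence and selenium site are among the matches
tied at the top score. The tie-inclusive reading follows from the method's
own semantics: some assignments are mass-indistinguishable in principle —
an N-terminally acetylated Ser start is 1 × 10⁻⁵ Da from a Glu start,
Ala-Gly equals Gln at the fourth decimal, and positional isomers whose
separating ions were dropped present identical evidence — and the engine
reports such ties at equal rank rather than guessing. Strictly-unique
rank-1 recovery is necessarily lower under a 20% fragment-dropout regime.

## Problem sizes

The test suite and the analysis scripts run the enumeration at lengths up to
4 over ~21 extendable symbols (≈250k pruned prefixes worst case per
spectrum), two simulated arms of 36 and 23 spectra, property checks on 1000
random ladders, oracle-equivalence on 50 random precursor masses at lengths
up to 3, and the recovery study on 150 spectra — sizes chosen so the whole
analysis re-runs from scratch in a couple of minutes on one core while still
exercising every code path at the scale of the real study (59 spectra, 19
true peptides).

## Known limitations

- Charges above 1 are supported in the API but not exercised by fixtures;
  all reference identifications are singly charged.
- No false-discovery-rate machinery (target-decoy competition): the decoy
  arm here serves the differential design, not error-rate estimation.
- The composition module ingests the published table's ambiguous
  "Tryptophan (Tyr)" row as tyrosine, since acid hydrolysis destroys
  tryptophan; the essential {H,I,L,K,M,F,T,W,V} and hydrophobic
  {G,A,V,L,I,P,F,M,W} groupings are the conventional ones and are
  overridable arguments, as the source analysis names neither set.
- Sharing between sample and control is judged on the bare display name,
  ignoring terminal modifications, because control-side modification state
  is not informative for peptide identity.
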