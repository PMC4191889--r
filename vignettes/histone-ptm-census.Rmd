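---
title: "Validating, quantifying and censusing histone PTMs from shotgun proteomics output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating, quantifying and censusing histone PTMs from shotgun proteomics output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HistoneCensus)
```

## The problem

Shotgun (MudPIT-style) proteomics of chromatin produces large numbers of
peptide-spectrum matches (PSMs) from a database search over target proteins
and their reversed-sequence decoys. Before any biology can be read off, three
downstream problems must be solved: deciding which PSMs to trust, turning
trusted PSMs into protein-level abundance, and — for histones — turning
modified peptides into a site-level census of post-translational
modifications (PTMs) that can be compared between samples (here: C. elegans
sperm versus mixed-stage embryo chromatin). `HistoneCensus` implements that
downstream pipeline, together with a ground-truth-labelled synthetic PSM
generator so that every stage is testable without raw spectra.

## PSM validation

Search results are grouped by charge state (+1, +2, +3, >+3) and tryptic
status (fully/half/non-tryptic) into 12 subgroups, which differ
systematically in their score distributions. Within each subgroup with at
least `n_min = 50` direct and 50 decoy PSMs, a two-class linear discriminant
(pooled covariance, the classical reading of "discriminant analysis", stable
at small n) is fitted on (XCorr, DeltaCN, |DeltaMass ppm|); sparser subgroups
fall back to a pooled fit on all PSMs. The absolute value of DeltaMass enters
the discriminant because its sign is noise; whether mass error should enter
the discriminant at all (rather than acting only as a hard filter) is
genuinely ambiguous, and including it is the package's default reading.

Full separation of direct and decoy score distributions is not possible, so
posterior peptide probabilities are computed nonparametrically: Gaussian-kernel
density estimates (Silverman's bandwidth, 512-point grid spanning the
observed discriminant scores plus four bandwidths, renormalised to unit area
on the grid) of the direct and decoy score densities give

\[ P(\mathrm{correct}\mid s) \;=\;
   \mathrm{clip}\!\left(1 - \pi_0\,\frac{f_{\mathrm{decoy}}(s)}
   {f_{\mathrm{direct}}(s)},\,0,\,1\right), \qquad
   \pi_0 = \min\!\left(1, \frac{n_{\mathrm{decoy}}}{n_{\mathrm{direct}}}\right).
\]

The direct-PSM density is itself the mixture of correct and incorrect
matches, so this is the PeptideProphet-style posterior: the decoy density
models the incorrect component and \(\pi_0\) its mixture weight. Raw KDE
ratios wiggle, so isotonic regression is applied along the grid **before**
clipping (clipping first would bias the posterior upward under the null);
a final running maximum removes float-level non-monotonicity. PSMs pass when
the probability is at least `p_min = 0.90` (boundary inclusive) **and**
|DeltaMass| is at most `ppm_max = 6` ppm. The FDR of the passing set is the
percentage of decoy PSMs among all passing PSMs — deliberately the plain
decoy fraction, not the doubled estimator, matching how the filtering
protocol this package reimplements states it.

## Protein assembly and abundance

Validated peptides are matched to proteins by exhaustive substring search.
Proteins whose matched-peptide sets are identical are indistinguishable and
merge into one cluster locus (canonical id: lexicographically smallest
member — deterministic and order-independent). Each passing PSM contributes
one spectrum to its peptide's locus; spectra of peptides shared between
clusters are distributed proportionally to the clusters' unique-peptide
spectral counts, with an equal split when no sharing cluster has unique
evidence. This conserves total counts exactly (to 1e-9 despite fractional
splitting), which the tests assert. Coverage is the union of matched
intervals over the sequence length (longest member for clusters).

Two abundance indices are computed, with the formulas fixed here because the
source analysis reports only their values:

* **NSAF**: \((\mathrm{SpC}_i/L_i) / \sum_j (\mathrm{SpC}_j/L_j)\) —
  normalised to sum to 1, scale invariant.
* **emPAI**: \(10^{N_\mathrm{obs}/N_\mathrm{obsbl}} - 1\), with observed
  peptides capped at observable. Observable peptides come from an in-silico
  tryptic digest (cleave after K/R, not before P, no missed cleavages; fixed
  Cys +57.02146 Da) filtered to a 600–3600 Da monoisotopic window. The
  window is a documented convention — motivated by a typical m/z 300–1800
  full-scan range at charge 2 — not a reconstruction of the original
  observability criteria, which are unstated.

Protein-level spectral counts include semi-tryptic PSMs; the PTM census
below is restricted to fully tryptic PSMs, mirroring the per-subtype peptide
listings such censuses are built from.

## PTM assignment and the occurrence census

Modification mass deltas are assigned by the fixed table: ac +42.0106 (K),
me1 +14.0157 / me2 +28.0314 / me3 +42.0471 (K, R), ph +79.9663 (S/T/Y),
ub +114.042927 (K) and carbamidomethyl +57.02146 (C, fixed). The default
tolerance of ±0.005 Da resolves acetylation from tri-methylation (0.0365 Da
apart) and covers the one-unit discrepancy in the last printed decimal of
the di-methylation delta (28.0314 vs 28.0313) between the methods text and
supplementary legends of the source analysis. A delta matching no type, or
falling inside two types' windows, is an explicit error; a delta whose type
is incompatible with the annotated residue is flagged and dropped from
counts with a warning.

Sites are numbered starting at the residue **after** the initiator
methionine, the histone field's convention. Cross-species correspondence is
computed by Needleman–Wunsch global alignment (BLOSUM62, gap open 10,
gap extension 0.5 — histones are near-identical, so the mapping is
insensitive to these values, which are fixed for determinism); a query
residue aligned to a gap maps to nothing.

The census counts one occurrence per (passing, fully tryptic, histone-mapped
PSM) per countable modification it carries — a spectrum bearing k countable
mods adds k occurrences, so sites on singly and multiply modified peptides
all count. Ubiquitination is never counted: the +114 Da shift is
mass-indistinguishable from the iodoacetamide lysine adduct introduced during
alkylation. Phosphorylation is censused separately (flagged) because no
phospho-enrichment chemistry backs those identifications, and fixed
carbamidomethylation is chemistry, not biology. Localisation within the
peptide is trusted from the search engine's modification record; no
localisation scoring is attempted. When a peptide matches several proteins
the lexicographically smallest id is used; when it matches one protein at
several positions, the leftmost — both documented tie-breaks.

Two denominators can reasonably back the "modified fraction of histone
spectra": all passing histone spectra, or fully tryptic ones only. Whether
the published totals include semi-tryptic spectra is not stated, so the
pipeline computes the fraction over all passing spectra and exposes the
full-tryptic subset through the census; both are available to the user.

## Comparative statistics

`modifiedFraction()` is `100 * ptm / total` rounded **half-up** to one
decimal (matching the printed precision; R's default round-half-to-even
would disagree on boundary cases). `foldRatio()` divides unrounded
fractions and rounds the quotient half-up, reported embryo/sperm so values
above 1 mean sperm is PTM-depleted. `variantEnrichment()` flags a variant as
sample-specific when its count is positive in exactly one sample, reporting
family-normalised proportion ratios otherwise. Feeding the published counts
through these functions reproduces the published 1.8% (sperm), 4.2%
(embryo), 2.4-fold ratio, and 22 vs 31 distinct marks; the bundled sperm
census column sums to 135 occurrences. The corresponding embryo sum is 325
against a stated 330 — the transcribed per-site table does not reconcile
with that stated total, so the embryo total is computed but not asserted.

## The synthetic generator

The generator emulates the statistical structure the validation and census
stages assume, not mass spectrometry itself. Correct matches are substrings
of target sequences (lengths uniform on 7–25 residues, a typical tryptic
range); incorrect matches hit targets and decoys with equal probability —
the assumption the decoy FDR estimator relies on, stated explicitly for that
reason. Scores are class-conditional with independent components: XCorr
N(4.0, 0.8) vs N(2.0, 0.6), DeltaCN N(0.35, 0.08) vs N(0.12, 0.06)
(truncated at zero), DeltaMass N(0 ppm, 2 ppm) for correct matches and
uniform on ±50 ppm for incorrect ones, which keeps the classes overlapping
but separable and makes the 6 ppm filter consequential. No score
distributions are published for the original data; these are modelling
choices, documented, not reconstructions.

Per-site modification emissions follow the bundled published occurrence
profile, scaled (1.3x occurrence share per covered site in sperm, 4.0x in
embryos) so that, after accounting for protein choice, site coverage and
multiple mods collapsing onto single spectra, the modified fraction of
passing spectra lands near the published levels; an embryo-only H2A K120
ubiquitination channel and a small phosphorylation channel exercise the
exclusion rules. The generator does **not** emulate fragment spectra,
retention times, intensity-dependent sampling, homologous non-histone
background proteins, or localisation error — so passing tests demonstrate
the correctness of the downstream arithmetic and the calibration of the
estimators under the stated assumptions, not robustness to real-data
pathologies.

The bundled reference sequences are synthetic stand-ins (the file name says
so): mouse H2A/H2B follow canonical sequences, H3/H4 are the canonical
near-universal sequences, and the C. elegans H2A/H2B stand-ins are
constructed so that global alignment reproduces the documented cross-species
correspondences (mouse H2A K119 ↔ C. elegans K120; mouse H2B K12 ↔
C. elegans K7, and the rest of the documented site pairs).

## Problem sizes and numerical choices at a glance

* Default simulation: 20,000 PSMs per sample, 70% correct matches; the test
  suite uses 100–10,000 PSMs per sample depending on what a test measures,
  and FDR calibration is checked over 20 seeded runs of 20,000 PSMs each.
* KDE: Silverman bandwidth per class, common 512-point grid, ±4 bandwidths,
  trapezoid-renormalised; posterior isotonicised then clipped to [0, 1].
* \(\pi_0\) = decoy/direct count ratio per subgroup, capped at 1.
* Probability threshold ties pass (≥ 0.90); both-criteria failures are
  reported as `below_probability`.
* All randomness flows from a single mandatory seed; identical configuration
  gives byte-identical outputs.

## Limitations

Beyond the generator's idealisations listed above: protein inference is
identical-set clustering only (no parsimony); no missed-cleavage modelling in
the emPAI digest; no spectrum re-scoring (XCorr/DeltaCN are taken as given);
no N-terminal processing beyond initiator-Met removal; and cross-species
mapping assumes a single reference per query protein.
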