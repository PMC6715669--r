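---
title: "Detecting and quantifying methyl marks on mature miRNAs by MALDI-TOF-MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying methyl marks on mature miRNAs by MALDI-TOF-MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeth)
```

## The assay this package models

Mature miRNAs (20–25 nt) can carry base methyls — N6-methyladenosine
(m6A), N1-methyladenine (m1A), 5-methylcytosine (m5C), 3-methylcytosine
(m3C) — and the methylated fraction of specific miRNAs is elevated in
gastrointestinal cancers, making it a candidate serum biomarker. A
captured miRNA analyzed intact by negative-mode MALDI-TOF shows its
methylated forms as satellite peaks displaced by one CH2 per methyl:

$$\Delta m = m(\mathrm{CH_2}) = 14.01565\ \mathrm{Da\ (monoisotopic)},$$

the nominal "+14 Da" shift. Everything downstream builds on this:
detection is peak matching against predicted masses of the 0..k-methyl
species, stoichiometry is an intensity share across those species, site
assignment compares MS/MS fragment ladders of candidate placements, and
the modification is typed chemically (hydrazine resistance for m5C,
dimethyl sulfate reactivity for m6A vs m1A).

## Mass model

An `oligo()` is a sequence over {A, C, G, U} with explicit termini and
1-based modification positions counted from the 5′ end. Each residue is
a nucleoside-3′-monophosphate minus water; the residue sum plus one
water is the 5′-phosphate/3′-hydroxyl chain — the default, because
mature miRNAs produced by Dicer/Drosha carry a 5′-monophosphate and a
3′-OH. A 5′-hydroxyl removes HPO3; a 3′-phosphate adds HPO3; a
2′,3′-cyclic phosphate adds HPO3 − H2O. Atomic masses are IUPAC values
kept in a single table (`R/atomic-data.R`). Negative-mode ions are
[M − zH]^z−, so m/z = (M − z·m_p)/z with the CODATA proton mass;
positive mode is an explicit error, not a silent fallback.

```{r}
oligo_mass(oligo("UGAGGUAGUAGGUUGUAUAGUU"))           # let-7a-5p, [M]
oligo_mass(oligo("UGAGGUAGUAGGUUGUAUAGUU", mods = "10:m6A")) -
  oligo_mass(oligo("UGAGGUAGUAGGUUGUAUAGUU"))          # the +14 shift
```

Isotope envelopes are computed by per-element convolution aggregated by
nucleon count (unit-mass binning). At MALDI-TOF resolving power the
isotopologues of a 7 kDa RNA are not baseline-resolved from each other
but the +14 spacing dwarfs the envelope width, so unit-mass binning is
sufficient; the envelope is used for realistic simulation and for the
overlap-correction guard, which is a designed no-op at the methyl
spacing under default truncation (1e-4).

## Fragment ladders

MS/MS ion series use McLuckey nomenclature: a/b/c/d anchored 5′, w/x/y/z
anchored 3′, plus a-B (a after neutral nucleobase loss). Neutral masses
are offsets from prefix/suffix masses such that the complementary pairs
a/w, b/x, c/y, d/z sum exactly to the precursor mass — the invariant the
test suite checks against an independent elemental oracle. The default
series for localization is {c, y, w, a-B}, the set commonly dominant for
RNA in negative mode; published assay descriptions rarely state which
series were observed, so this is an engineering default, configurable
everywhere.

A base methyl shifts every ion whose span contains its position. The one
deliberate deviation from a pure containment rule: for a-B at the
modified base itself, the methyl departs with the lost base (it is a
base methyl), so that ion is unshifted. Site-localization scoring
benefits from this extra asymmetry.

## Site localization and chemical typing

`localize()` places the methyl at every legal position, generates each
hypothesis ladder, and matches observed peaks within a ppm tolerance
(default 100 ppm; MS/MS accuracy is poorer than intact MS). The score is
a fragment count — supporting (matches only under this placement) minus
contradicting (matches only under another) — not a probability;
likelihood scoring is a documented extension point. Ties form an
explicit ambiguity set rather than an arbitrary winner.

Hydrazine chemistry is modeled as complete cleavage at every unprotected
cytosine with excision of that nucleotide; m5C resists. Cut ends gain
phosphates, original ends keep the parent termini. Two placements are
*not* always distinguishable: if their cleavage segments have identical
base-composition/terminus multisets (e.g. protecting either C of a
…GCGG…/…GGCG… environment) the predicted mass patterns coincide — a
property of the chemistry the test suite asserts explicitly rather than
hiding.

The dimethyl-sulfate classifier assumes a complete reaction at every
free adenine N1 (+14.01565 each): an m6A-carrying oligo with nA adenines
shifts by nA·14.01565, an m1A carrier by (nA−1)·14.01565, separated by a
full 14 Da, so the default 0.5 Da tolerance is generous. Partial
reaction and DMS reactivity toward guanine N7 are known, documented
simplifications following the assay's qualitative use.

## Quantification and calibration

The methylation fraction is the methylated share of total intensity,
$f = \sum_{k\ge1} I_k / \sum_{k\ge0} I_k$, computed from peak heights of
accepted matches (heights, because inputs are centroided peak lists).
"Ratio between peak intensities" is ambiguous between a ratio and a
fraction; the fraction form matches the cohort-figure axes and keeps the
value in [0, 1]. When no methylated species reaches the SNR floor the
sample is flagged below detection and reported as 0 — the convention the
downstream ROC stage also applies to missing marker values.

Ionization efficiency can differ between methylated and non-methylated
oligos. With a relative response factor $r$, the measured intensity
ratio obeys $I_1/I_0 = r\,f/(1-f)$ — linear in the molar *odds*, not in
$f$. `fit_calibration()` therefore regresses the measured ratio on the
odds; the slope *is* the response factor, and `apply_calibration()`
inverts the line and clamps to [0, 1]. A straight-line fit of ratio on
fraction cannot recover $r$ as its slope; this odds-scale fit is the
package's resolution of that contradiction. The simulator applies $r$
once to every methylated species (not $r^k$), matching this single-factor
model; compounding per-methyl factors are out of scope.

### Matching tolerances

Intact-species matching defaults to 50 ppm (externally calibrated
MALDI-TOF). A matching window must scale with the actual mass error: the
synthetic-validation pipeline simulates 20 ppm errors and therefore
matches at 100 ppm (5σ), so that window dropout (~1.2% of peaks at
2.5σ), which costs a full-fraction error per lost peak, does not
masquerade as stoichiometry error. The window is an analysis parameter
chosen by that principle, not a tuned number.

## The simulator: what it does and does not establish

`simulate_intact()`, `simulate_msms()`, `simulate_calibration_series()`
and `simulate_cohort()` generate the statistical structure the analysis
assumes: one peak per (methyl count, adduct) species with lognormal
intensity noise (unit-mean, default CV 5%) and Gaussian ppm mass jitter
(default 20 ppm); Na (+21.98194) and K (+37.95588) adduct peaks at
configurable rates; fragment ladders thinned by a coverage probability;
cohort fractions from Gaussians truncated to [0, 1] (a bounded
convenience, not a claim about biology), with paired samples sharing a
latent subject effect (ρ = 0.5) and stylized lognormal CA19-9/CEA
marker columns. A single seed fans out to fixed per-component
substreams, so adding a stage never perturbs earlier draws and every
output is byte-identical per seed.

Defaults mirror the stated experimental design where one exists — the
calibration series covers fractions 0.1–0.9 in replicate, emulating the
dynamic-range mixtures of synthetic methylated/non-methylated standards;
cohort effect sizes emulate elevated case fractions with controls near
the detection limit. Where nothing is stated (paired correlation, marker
overlap, intensity budget) values were chosen once as realistic for a
serum-marker cohort and are documented here, not revisited.

A green synthetic test establishes that the estimators invert the
generative model they assume — it does not establish matrix effects,
adduct chemistry beyond Na/K, acquisition drift, or biological variance
structure in real serum. Real-data behaviour is exactly what the
deposited clinical results cover and this package does not claim.

## Downstream stages

The RIP-Seq consensus stage calls a miRNA methylated in a sample iff IP
RPM ≥ `min_rpm` and IP/input RPM enrichment ≥ `min_enrichment` (input
floored at 0.5 RPM). The published analysis does not state its call
criterion, so both thresholds are required arguments with no silent
defaults, and the published consensus count (63 miRNAs across four cell
lines) is *not* a reproduction target — only the intersection mechanics
are. Paired comparison is a closed-form paired t-test (the figure-legend
test), with a Wilcoxon signed-rank alternative behind a flag; zero
variance of differences reports t = 0/p = 1 when the mean difference is
zero and ±Inf/p = 0 otherwise. ROC/AUC uses the Mann–Whitney identity on
mid-ranks (ties count one half), verified against brute-force pairwise
comparison.

## Numerical choices and degenerate inputs

* Composition arithmetic is integer and errors on any negative count.
* Species matching ranks candidate (prediction, peak) pairs by |ppm|;
  differences under 1e-6 ppm are treated as ties (floating-point guard)
  and resolved toward lower methyl count.
* "Mono-/di-/trivalent" species are read as methylation multiplicity;
  charge states are handled separately via the `charges` argument of the
  fragment machinery and `mz_from_mass()`.
* Envelope truncation must lie in (0, 0.01]; abundances always sum to at
  least 1 − truncation.
* Centroiding uses local maxima over a MAD-based noise floor
  (`stats::mad`, window 20 Da) and intensity-weighted centroids over the
  above-half-maximum region; a flat profile yields an empty peak list.
* TSV peak lists are strict: `mz<TAB>intensity[<TAB>snr]` header, dot
  decimals, UTF-8; malformed rows error with their line number; an empty
  file is an empty peak list, not an error.
* Methylated positions per miRNA are user inputs throughout — the
  package fixes the convention (1-based from 5′) but ships no per-miRNA
  position constants.

## Known limitations

Positive-ion mode, 2′-O-methylation and non-methyl modifications, DNA
chemistry, internal fragments and neutral losses beyond a-B, absolute
copy-number quantification, vendor raw formats, and any differential
expression/GSEA analysis are out of scope. The hydrazine and DMS models
are complete-reaction idealizations. The localization score is a count,
unweighted by intensity or fragment reliability.
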