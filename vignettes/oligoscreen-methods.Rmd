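---
title: "Methods: non-targeted oligoester screening with oligoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-targeted oligoester screening with oligoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscreen)
library(dplyr)
```

## The problem

Biodegradable polyester mulch films — typically blends of polybutylene
adipate-co-terephthalate (PBAT) and polylactic acid (PLA), sometimes with a
polybutylene sebacate(-co-terephthalate) (PBSe/PBSeT) component — carry
organic additives (plasticisers, lubricants) and non-intentionally added
substances (NIAS). The dominant NIAS class is cyclic and linear oligoesters:
short chains of the polymer's own repeat units formed as synthesis
by-products. Because formulations are proprietary, their characterisation
requires non-targeted screening (NTS) across several instruments: ^1^H NMR
for the bulk polyester blend, GC-FID/GC-MS for the volatile additives with
internal-standard quantification, and direct-infusion (DI) and LC
high-resolution MS for the oligoester profile. `oligoscreen` implements the
data-analysis side of that workflow so every stage can be exercised, tested
and benchmarked on synthetic data.

## Exact-mass arithmetic

All mass calculations reduce to one pinned table of atomic masses
(monoisotopic: C 12 exactly, H 1.00782503, N 14.00307400, O 15.99491462,
Na 22.98976928; standard atomic weights for the average-mass path) and the
CODATA electron mass 0.000548580 Da. A positive ion's m/z is

$$ m/z = \frac{M + k\,m(\mathrm{delta}) - z\,m_e}{z} $$

for `k` adduct units of composition `delta` and charge `z`. The electron
mass is always subtracted per charge: at the +/-1 mDa tolerances used for
assignment, omitting it (~0.55 mDa per charge) would systematically bias
every match, and the reference value 858.3907 for the [M+NH~4~]^+^ ion of
cyclic [AA-BD]~2~-[TA-BD]~2~ is only reproduced with the correction applied.
Full floating-point precision is kept internally; masses are rounded to 4-5
decimals for display only.

The four ester repeat units are the condensed monomer pairs: butylene
adipate (AA-BD, C~10~H~16~O~4~, 200.10486 Da), butylene terephthalate
(TA-BD, C~12~H~12~O~4~, 220.07356 Da), butylene sebacate (SeA-BD,
C~14~H~24~O~4~, 256.16746 Da) and lactate (LA, C~3~H~4~O~2~, 72.02113 Da).

## The predicted structure database

`enumerate_oligo_db()` enumerates candidate oligoesters as multisets of
repeat units with a topology and end group: cyclic (no end group), free
linear (+H~2~O), methyl-capped (+CH~4~O) and butanediol-capped
(+C~4~H~10~O~2~). The default configuration mirrors the series actually
observed in PLA/PBAT/PBSeT film extracts: homopolymer rings [LA]~2-12~,
[AA-BD]~1-6~, [TA-BD]~2-3~, [SeA-BD]~1-4~; mixed AA-BD/TA-BD and
TA-BD/SeA-BD rings up to 9 units; methyl-capped PLA chains up to 20 lactate
units (optionally carrying up to 4 AA-BD units); and free or BD-capped
linear PBAT chains up to 7 units (260 species in total). The configuration
is fully open: blocks of per-family count ranges can be added or replaced,
with a safety cap (default 10^5^ candidates) refusing runaway enumerations
before any work is done.

Two conventions are worth stating. Minimum ring sizes default to 2 for pure
lactate rings (lactide is the smallest observed) and 1 for diacid-diol rings
(the 12-membered [AA-BD] ring is observed). Canonical labels list repeat
units in the fixed order AA-BD, TA-BD, SeA-BD, LA, which makes
deduplication string-stable; the same composition written in field
nomenclature with another order (e.g. a methyl-capped PLA chain carrying
AA-BD units) parses to the same species.

## Direct-infusion sequence extraction

The extraction algorithm works on a centroided, positive-mode spectrum:

1. **Threshold.** Peaks below 10^4^ counts are removed. The boundary is
   inclusive (>= 10^4^); centroid mass accuracy degrades below this working
   threshold, which is why the stage precedes everything else.
2. **Ladder search.** For each repeat family and charge (1 and 2), maximal
   chains of peaks spaced by `repeat mass / z` within an absolute +/-0.001
   Da are collected. Extension is greedy and deterministic: among candidates
   inside the window of the expected next m/z, the smallest absolute error
   wins, ties broken by intensity. A chain is only seeded at a peak with no
   in-tolerance predecessor (front-maximality), and a chain whose peaks are
   a strict subset of a longer same-family chain is dropped — the important
   case being charge 2: the alternating members of a [M+2NH~4~]^2+^ ladder
   of a composition with even counts coincide exactly with a charge-1 ladder
   of the half composition, and the longer explanation is kept.
3. **Assignment.** The lowest-m/z ion of each chain is tested under every
   supported adduct hypothesis of matching charge ([M+H]^+^, [M+NH~4~]^+^,
   [M+Na]^+^, [M+2NH~4~]^2+^); the implied neutral is matched against the
   database within the same +/-0.001 Da, the best hit (smallest error, ties
   by adduct priority NH~4~ > H > Na) fixes the adduct for the whole chain,
   and consecutive ions become the seed species plus one repeat unit each.
   Expected m/z values are re-anchored to theory after assignment, so
   tolerance errors cannot accumulate along long ladders. Unmatched seeds
   leave the chain recorded but unassigned (formula-only follow-up is
   available through `formula_search()`). Assignments made this way are
   Schymanski level 3 (formula plus tentative structure).
4. **Isotopologues.** Peaks one ^13^C (+1.00335/z) or ^18^O (+2.00424/z)
   shift above an assigned ion, with intensity strictly below the parent,
   are flagged and excluded from component summaries. Strict inequality is
   the minimal defensible rule: a true satellite of a C~20~-C~60~ oligoester
   is always far weaker than its parent, and the rule needs no abundance
   model.
5. **Components.** Assigned ions collapse to one row per species regardless
   of adduct or charge multiplicity. Peaks claimed by no ladder are
   optionally matched as singletons (single-ion species such as the largest
   homopolymer rings are otherwise invisible).

The DI stage uses an absolute Da tolerance because the spacing criterion is
a *difference* of m/z values, for which ppm would shrink the window at the
low-mass end where the seed ions sit.

## LC-MS/MS annotation

The LC stage works in ppm (default 5 ppm): extracted-ion chromatograms
group features inside the window into retention-time peaks (apex = local
maximum; apexes closer than 0.05 min merge — observed isomer gaps are
\>= 0.25 min, so the default under-merges rather than over-merges). Isomer
multiplicity is reported as a peak count; which structural or
diastereoisomer elutes where is left open deliberately.

Precursor assignment reuses the DI hypothesis ranking on a single m/z.
Candidates that match nothing fall back to an exhaustive CHNO formula
search within 3 ppm, filtered by ring-double-bond equivalents >= 0 and
H <= 2C + N + 2.

Diagnostic MS/MS corroboration generates a conservative theoretical ion set
per candidate: protonated sub-oligomers over all sub-multisets of the
composition, each with an optional free diacid (ester cleavage retaining
the acid — equivalently butadiene loss from a butylene ester) and an
optional water loss; protonated free diacids; diacid acylium ions
(diacid - OH) with and without water loss; methyl-ester analogues for
methyl-capped species; and per-family homologue ions k x repeat with k up
to max(2, count), since repeat-dimer ions are characteristic of a family
throughout a homologous series. This set explains every catalogued
characteristic MS/MS ion of the cyclic oligoesters to within 1 mDa (a
regression test enforces it) while staying small enough that a match is
informative. Confidence follows the Schymanski scale as a pure function of
the evidence: level 1 with a reference standard, level 2 with at least one
matched diagnostic ion, level 3 on formula only.

## NMR blend composition

With one assigned signal per polyester, molar fractions are
proton-normalised integrals,

$$ \mathrm{mol\%}_i = \frac{I_i/m_i}{\sum_j I_j/m_j} \times 100, $$

and weight fractions weight each molar equivalent by the repeat-unit
molecular weight before normalising. Average (standard atomic weight)
masses are used here — the molecular-weight convention of NMR work — not
the monoisotopic masses of the MS stages. End-group contributions are
neglected, the usual approximation for polymeric samples where chain ends
are a vanishing mass fraction; results carry an attribute flagging the
approximation. Both percentages sum to exactly 100 before display rounding
(integer percent, matching the reporting convention; machine output keeps
full precision), and the estimator is exactly scale-invariant in the
integrals.

## GC internal-standard quantification

Response factors follow the area-per-concentration convention relative to
the internal standard, `RF = (area_ref/conc_ref)/(area_is/conc_is)`; the
documentation states the convention so users with the reciprocal convention
can invert. Concentrations are
`(area_i/area_IS) x m_IS / (RF_i x m_sample)` in ug per g film, with
defaults matching the reference protocol (250 ug of butyl benzyl phthalate
added post extraction, 0.1 g film). Analytes quantified with a surrogate RF
(no reference compound available) keep a `surrogate` flag all the way to
the output instead of being silently merged. Replicates are averaged
against their own IS areas with the spread reported. Spike recoveries are
plain percentages.

## What the synthetic data emulate — and what they do not

The generators invert the analysis stages exactly, under a seeded RNG:

- `simulate_di_spectrum()` plants ladders at theoretical adduct m/z with
  geometric intensity decay (observed series decay with size), Gaussian
  mass jitter truncated at +/-2.5 sd (a bounded error, like an instrument
  mass-accuracy specification), optional single ^13^C satellites at
  0.011 x nC relative intensity, and uniform noise peaks kept outside a
  +/-0.005 Da guard band around planted ions so ground-truth scoring is
  unambiguous.
- `random_series_plans()` draws benchmarking plans that are identifiable in
  principle: seed ions must be mass-unambiguous in the database within 3 mDa
  under every adduct hypothesis at their charge, and plan sets are assembled
  greedily so that no cross-plan peak pair sits within the ladder tolerance
  of a repeat spacing. These guards constrain the construction of the truth,
  not the extractor; they are the synthetic analogue of the noise guard
  band.
- `simulate_nmr_integrals()` and `simulate_gc_run()` apply multiplicative
  Gaussian noise to exact inverse models.

What passing these benchmarks does **not** show: electrospray ionisation
efficiency is not modelled (planted intensities are arbitrary, so recall
results say nothing about real detectability), noise is uniform rather than
chemical background, isotope patterns are single-satellite only, and real
spectra offer no identifiability guarantee — two database species can
genuinely coincide in mass, in which case a real workflow reports the
ranked ambiguity rather than a unique answer. One aliasing is exact and
worth knowing: the [M+2NH~4~]^2+^ series of a composition with even counts
occupies the same m/z values as the [M+NH~4~]^+^ series of its half
composition, interleaved at half spacing. The subset-chain rule resolves
the pure case, but when neighbouring series supply the interleaving peaks
both readings are reported as components, exactly as a manual curation
would list them before refining duplicates.

## Numerical choices and problem sizes

Tolerances: +/-0.001 Da (DI spacing, database matching, per-ion theoretical
error), 5 ppm (LC matching), 3 ppm (formula fallback), 1e-6 Da (duplicate
centroid merge), 1e-9 Da (mass-arithmetic identities in tests). Tie-breaks
are all deterministic (smallest error, then intensity; adduct priority
NH~4~ > H > Na). Degenerate inputs error early and by name: negative
formula subtraction, cyclic species with end groups, zero-unit species,
non-positive integrals or response factors, profile-mode mzML.

The shipped benchmarks use 20 planted ladders per extraction run (2-5
members each, charges 1-2, mixed families), 1000 replicates for the NMR
noise study and 500 for the GC noise study; each completes in seconds and
scales linearly for users who want tighter Monte Carlo error.

## Known limitations

Stereochemistry and sequence isomers within a composition are out of scope
(the data cannot distinguish them); the PBT contribution inside PBAT versus
PBSeT cannot be separated by the NMR stage; spectral-library lookups and
molecular networking are not implemented; and the diagnostic-fragment
generator is deliberately conservative — extending it (e.g. with
ammonium-adducted fragments) is a one-function change but widens the match
space and should be validated against measured MS/MS spectra.
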