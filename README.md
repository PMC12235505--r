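# oligoscreen

Non-targeted screening (NTS) of the organic components of biodegradable
polyester mulch films — additives, lubricants and the oligoester
non-intentionally added substances (NIAS) that polyester synthesis leaves
behind. The package is written for analytical chemists characterising
PLA/PBAT(/PBSeT) films across the full molecular-weight range: ¹H NMR for
the bulk polyester blend, GC-FID/GC-MS with internal-standard
quantification for the volatile fraction, and direct-infusion (DI) and
LC-HRMS for the oligoester profile.

## What it computes

**Exact-mass core.** Elemental formulas in Hill notation, monoisotopic and
average masses from a pinned atomic-mass table, and positive-mode adduct
m/z with electron-mass correction:

```
m/z = (M + k·m(delta) − z·mₑ) / z,   mₑ = 0.000548580 Da
```

for the adducts [M+H]⁺, [M+NH₄]⁺, [M+Na]⁺ and [M+2NH₄]²⁺.

**Predicted oligoester database.** Cyclic and linear combinations of the
four ester repeat units — butylene adipate (AA-BD, 200.10486 Da), butylene
terephthalate (TA-BD, 220.07356 Da), butylene sebacate (SeA-BD, 256.16746
Da) and lactate (LA, 72.02113 Da) — with free, methyl-capped or
butanediol-capped ends, enumerated from a configurable block specification
and matched against observed neutral masses.

**DI oligomer sequence extraction.** In a thresholded centroid spectrum
(≥ 10⁴ counts), maximal chains of ions separated by a repeat-unit mass
divided by charge (±0.001 Da) are extracted as oligomer sequences; the
lowest ion of each chain is assigned against the database under all adduct
hypotheses, consecutive ions grow by one repeat unit, ¹³C/¹⁸O isotopologue
satellites are flagged, and assigned ions collapse into a deduplicated
component table.

**LC-MS/MS annotation.** Extracted-ion chromatograms with isomer
multiplicity, ddMS² precursor assignment (5 ppm, with an exhaustive CHNO
formula fallback at 3 ppm), diagnostic-fragment matching against generated
sub-oligomer/acylium ions, and Schymanski confidence levels 1-3.

**Quantification.** Copolymer mol% and wt% from assigned ¹H NMR integrals
(`mol%ᵢ = (Iᵢ/mᵢ)/Σⱼ(Iⱼ/mⱼ) × 100`, weight fractions via average
repeat-unit masses), and GC internal-standard quantification via response
factors with surrogate flags plus spike recoveries.

**Synthetic data.** Seeded generators invert every stage (planted ion
ladders with decay, jitter and noise; NMR integrals; GC areas), and a
packaged catalogue of the components detected in a commercial PLA/PBAT
film ships as `mulch_catalogue()`.

## Worked example

Simulate a DI spectrum containing three oligoester series (with mass jitter
and 100 sub-threshold noise peaks), then run the extraction pipeline:

```r
library(oligoscreen)

db <- enumerate_oligo_db()
plans <- dplyr::bind_rows(
  series_plan("cyclic [AA-BD]",  n_members = 4, base_intensity = 2e6),
  series_plan("cyclic [TA-BD]2", n_members = 3, base_intensity = 8e5),
  series_plan("Me-[LA]2", family = "LA", n_members = 6, base_intensity = 5e5))
sim <- simulate_di_spectrum(plans, jitter_sd = 2e-4, n_noise = 100, seed = 42)

res <- di_extract(sim$spectrum, db)
res
#> <di_extraction>
#>   peaks:       13
#>   ions:       13 (13 assigned)
#>   sequences:   3
#>   components:  13
score_extraction(res, sim$truth)
#> # A tibble: 1 × 5
#>   n_planted n_recovered recall n_false false_labels
#>       <int>       <int>  <dbl>   <int> <chr>
#> 1        13          13      1       0 ""
```

All 13 planted species (4 adipate rings, 3 terephthalate rings, 6
methyl-capped lactate chains) are recovered as [M+NH₄]⁺ assignments with no
false components; the noise never survives the intensity threshold.
`tidy(res)` returns the per-ion table with mass errors, `autoplot(res)` the
annotated stick spectrum.

The NMR stage, fed integrals consistent with a 35/40/13/12 mol% blend:

```r
sig <- simulate_nmr_integrals(c(PBA = 35, PBT = 40, PLA = 13, PBSe = 12),
                              c(4, 4, 1, 4))
nmr_composition(sig)
#> Copolymer composition (1H NMR; end groups neglected)
#>  polymer mol% wt%
#>      PBA   35  35
#>      PBT   40  44
#>      PLA   13   5
#>     PBSe   12  16
```

PLA contributes 13% of the repeat units but only ~5% of the mass — the
lactate unit is light — which is why mol% and wt% are both reported.

A command-line front end is installed as `exec/oligoscreen`
(`oligoscreen db build`, `di extract`, `lc annotate`, `nmr quant`,
`gc quant`, `simulate di`).

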