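# flavomics

Rule-based annotation of plant metabolite profiles from LC-MS/MS and GC-MS,
with dose-response (IC50) modelling.

Untargeted phytochemical profiling of a plant extract typically yields three
kinds of tables: high-resolution MS/MS features (precursor m/z, polarity,
fragment list), GC-MS peak lists of the lipoidal matter (named compounds with
area percentages), and microplate viability readings from an antiproliferative
assay. `flavomics` implements the analysis layer that turns those tables into
results, built around the fragmentation chemistry of flavonoid glycosides:

- **Mass engine** — molecular-formula parsing (plain, underscore and
  Unicode-subscript dialects), nominal and monoisotopic masses from a shipped
  isotope table, `[M-H]-`/`[M+H]+` adduct m/z under the proton-mass convention
  (±1.007276 Da), signed ppm errors, and exhaustive candidate-formula
  generation within a ppm tolerance over bounded CHNOS compositions.
- **Fragmentation rules** — neutral-loss rules for glycosyl residues
  (hexosyl 162, deoxyhexosyl 146, pentosyl 132, hexuronyl 176, rutinosyl-type
  disaccharide 308 Da), the coumaroyl acyl residue, small losses (H2O, CO2,
  CO, CH3) and the cross-ring cleavages (−90/−120 Da) that distinguish
  C-glycosides from O-glycosides; retro-Diels-Alder (RDA) fragment prediction
  (e.g. the ¹,³A⁻ ion of 5,7-dihydroxy flavonoids at m/z 151) with an
  enforced mass-conservation invariant.
- **Annotator** — ranks library candidates for each MS2 feature: formula gate
  at 20 ppm, fragment explanation by residue-loss chains and aglycone
  diagnostics, O/C linkage classification, and a configurable score
  (0.7 × explained-peak fraction + 0.3 × diagnostic fraction). Exact score
  ties (positional isomers) share a rank and are reported, never broken
  arbitrarily.
- **GC composition** — fatty-acid saturation computed from ring plus
  double-bond equivalents (RDBE = C − H/2 + N/2 + 1; 1 = saturated acid or
  ester, ≥2 = unsaturated), curated sterol/other categories, and class
  area-percent totals.
- **Dose-response** — viability % = Abs(test)/Abs(control) × 100 and a
  bounded four-parameter logistic fit
  `v(c) = bottom + (top − bottom) / (1 + 10^(hill (log10 c − log10 IC50)))`
  with the IC50 standard error from the fit covariance.
- **Synthetic data** — seeded generators for every stage (forward-rule MS2
  spectra with decoys, Dirichlet GC tables, 4PL plates) so the entire
  pipeline is testable without any external download.

## Worked example

```r
library(flavomics)

# an O-hexoside of quercetin: deprotonated precursor 463.0918 with
# fragments 301 (aglycone), 283, 255, 151
f <- ms2_feature("feat8", 463.0918, "negative", c(301, 283, 255, 151))
annotate_feature(f)[1:3, c("candidate", "formula", "error_ppm", "linkage", "score", "rank")]
#>              candidate   formula error_ppm linkage score rank
#> 1           Hyperoside C21H20O12   7.77474       O   0.8    1
#> 2        Isoquercitrin C21H20O12   7.77474       O   0.8    1
#> 3 Quercetin-O-hexoside C21H20O12   7.77474       O   0.8    1
```

The three quercetin O-hexosides are chemically identical at MS2 level, so
they tie at rank 1 with score 0.8 (all four peaks explained, 4 of 6 quercetin
diagnostics observed); the explanation string reads
`301=-hexosyl (aglycone ion); 283=-hexosyl-water; 255=diagnostic 255
(quercetin); 151=diagnostic 151 (quercetin)`. The linkage is `O` because the
hexosyl loss is observed without any cross-ring (−90/−120) loss.

```r
summarize_composition(bidens_gc_peaks())
#> GC class composition (19 peaks)
#>   saturated fatty acids:     8.69%
#>   unsaturated fatty acids:  11.38%
#>   sterols:                  39.92%
#>   other identified:          6.60%
#>   total identified:         66.59%

p <- gen_plate(ic50 = 1.66, noise = noise_config(seed = 42))
fit_plate(p)
#> Four-parameter logistic dose-response fit
#>   IC50:   1.818  (SE 0.124)
#>   top:    100    bottom: 0.01466    hill: 1.007
#>   n = 24 points, 8 distinct concentrations
```

The simulated plate uses the two-fold dilution design 100 → 1.5625 mg/mL in
triplicate with 5% well CV; the fit recovers the true IC50 (1.66) within the
replicate scatter, and the reported uncertainty is the delta-method standard
error of the IC50 from the fit covariance.

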