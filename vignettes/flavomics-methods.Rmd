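---
title: "Methods: rule-based metabolite annotation and dose-response fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based metabolite annotation and dose-response fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavomics)
```

## Scope and model

`flavomics` implements the identification logic used in untargeted profiling
of flavonoid-rich plant extracts. The chain of reasoning it encodes is the
one practitioners apply by hand: a high-resolution precursor m/z constrains
the molecular formula; neutral losses between precursor and product ions
reveal glycosyl, acyl and small-molecule residues; cross-ring sugar losses
distinguish C- from O-glycosides; and low-mass retro-Diels-Alder (RDA)
products fingerprint the aglycone. Around that core sit two supporting
analyses that the same studies routinely report: class composition of the
GC-amenable lipoidal fraction, and IC50 estimation from microplate viability
assays.

## Mass arithmetic

All masses derive from one shipped plain-text isotope table
(`inst/extdata/isotope_masses.tsv`: principal-isotope mass numbers and exact
masses for H, C, N, O, P, S), so tests and library code read the same
constants. Nominal mass is the integer mass-number sum (C = 12, H = 1,
O = 16, ...), the convention under which GC compound tables quote molecular
weights. Adduct m/z uses the proton-mass convention:
m/z([M−H]⁻) = M − 1.007276 Da, the electron mass being absorbed into the
proton value as in routine TOF calibration; only the singly charged ±H
adducts are supported, matching electrospray behaviour of phenolics in the
m/z range covered here.

Candidate-formula generation enumerates every CHNOS(P) composition within
per-element bounds whose adduct m/z falls inside the ppm window, then sorts
by absolute ppm error with ties broken by the Hill-order string. The default
bounds (C ≤ 60, H ≤ 100, N ≤ 6, O ≤ 20, S ≤ 3) comfortably cover acylated
flavonoid di-glycosides; the enumeration vectorises over the heavy elements
and solves the hydrogen count from the mass window, so the default lattice
evaluates in well under a second. No chemical filtering beyond the bounds is
applied (no nitrogen rule, no RDBE cut): completeness with respect to the
bounds is the contract, verified in the tests against an independent
brute-force enumerator.

Note that ppm error is taken relative to the *theoretical* mass. At 20 ppm —
the customary identification cutoff for TOF instruments, and the package
default — the distinction from observed-relative error is negligible, but the
convention matters for reproducibility of signed errors.

## Neutral-loss rules and RDA prediction

The rule set (`inst/extdata/neutral_loss_rules.json`) carries the residue
losses that dominate flavonoid glycoside spectra: hexosyl 162, deoxyhexosyl
146, pentosyl 132, hexuronyl 176 and the rutinosyl-type disaccharide 308 Da;
coumaroyl 146 as the common acyl residue; water, CO2, CO and methyl as
ubiquitous small losses; and the −90/−120 Da cross-ring cleavages of
C-linked hexoses. Each rule stores a residue formula, and the loader asserts
that the integer loss equals the formula's nominal mass. Matching is at
nominal level with a 0.5 Da tolerance by default because fragment lists in
published identification tables are unit-resolution; an exact-mass mode (for
high-accuracy data, tolerance in mDa) uses the monoisotopic residue masses
instead. `loss_candidates()` reports single rules and chains of at most two
sugar/acyl residues; the deoxyhexosyl/coumaroyl ambiguity at 146 Da is
deliberately left to the caller — both rules are returned, and the annotator
resolves acylation only when the acyl + hexosyl pattern explains the
spectrum.

Linkage classification follows the standard reading: any cross-ring loss
implies a C-glycoside; a full glycosyl loss without cross-ring losses
implies an O-glycoside. The call is order-invariant in the match list and,
in line with observed spectra, C-glycoside candidates are still allowed to
show the full sugar loss (the aglycone ion), so the distinction rests on the
presence of cross-ring products, not the absence of the aglycone peak.

RDA prediction is data-driven rather than graph-derived: each aglycone
record stores the composition of the A-ring-containing 1,3-cleavage product
(C7H4O4 for the common 5,7-dihydroxy A-ring; C7H4O5 for the
5,6,7-trihydroxy case; C8H6O4 for a 7-O-methylated A-ring), and the B-side
product is its complement in the aglycone formula. The deprotonated 1,3A⁻
ion is then nominal(A-part) − 1, and ion plus complementary neutral equal
the deprotonated aglycone mass *by construction* — the conservation
invariant is asserted on every call rather than trusted. Flavonols
additionally receive the 1,4 cleavage, whose A-side neutral is the 1,3
A-part minus CH2O. Chalcone and aurone scaffolds have no stored partition
and return an explicit zero-row result with a reason attribute, never a
silent empty answer.

## The annotator

For each feature, library entries are gated by formula: the entry's
theoretical adduct m/z under the mode's adduct hypothesis must lie within
the configured ppm tolerance (default 20) of the precursor. Retention time
is carried through but never scored — no retention model is assumed — so
positional isomers (e.g. the 3-O- vs 4′-O-hexosides of quercetin) tie by
design; candidates with identical score and |ppm| share a rank, and the
report keeps all of them.

Each observed fragment is explained, where possible, by: the candidate's own
residue-loss ladder (prefixes of its decoration sequence, computed at exact
masses); cross-ring products if its innermost sugar is C-linked; one or two
small losses appended to the precursor or to any ladder ion (depth ≤ 3:
residues then small losses, covering patterns such as −162−18 and the
−18/−44/−62 family of acid spectra); the aglycone's diagnostic fragments; or
its RDA products. The score is a weighted sum, 0.7 × (explained-peak
fraction) + 0.3 × (fraction of the aglycone's diagnostic list observed),
weights configurable. The fractions make the score monotone: removing an
explained peak can never raise it. Features with an empty peak list are
annotated on precursor mass alone and flagged `ms1_only`.

The packaged compound library (82 entries) and feature fixture transcribe a
published identification table of a *Bidens pilosa* extract verbatim,
including rows whose printed precursor m/z is inconsistent with the assigned
formula by far more than the stated error (one flavonol aglycone row is
−40 ppm off; several phenolic-acid rows exceed 100 ppm). Those rows are
retained as printed — with a note column where the printed polarity and the
fragment arithmetic disagree — because they document the limits of the
source data; the annotation regression test records that 45 of 82 features
place the published identity in the top rank tier under the 20 ppm gate, and
the misses are dominated exactly by those inconsistent rows. Observed m/z
from that table is never used as ground truth for mass arithmetic.

## GC class composition

Fatty-acid membership is computed, not curated: a peak is a fatty acid iff
its name contains "acid" (covering free acids and their methyl/ethyl esters,
which GC libraries name as "... acid, methyl ester") and its formula has
exactly two oxygens. Saturation splits on ring-plus-double-bond equivalents,
RDBE = C − H/2 + N/2 + 1: RDBE 1 is the acid/ester carbonyl baseline
(saturated), RDBE ≥ 2 marks unsaturation. Sterols and the residual "other"
group (long-chain alcohols, tocopherol, a cholate ester) are curated flags
on the input table because no computable rule reproduces that grouping;
`summarize_composition()` refuses a non-fatty-acid peak without a curated
category rather than guessing. Class sums are exact (permutation-invariant,
conserving the grand total to 1e−9) and reported rounded to two decimals,
the precision of conventional composition tables.

## Dose-response fitting

Viability is the control-normalised absorbance ratio × 100. The 4PL model is
parameterised in log10 concentration,
v(c) = bottom + (top − bottom)/(1 + 10^(hill·(log10 c − log10 IC50))), with
hill > 0 so viability decreases with dose and v(IC50) = (top + bottom)/2
identically. Fitting uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`): IC50 constrained to the tested range widened
100-fold either side, hill ∈ [0.1, 10], plateaus loosely bounded;
initialisation from the response quantiles and the dose nearest the
midpoint. Replicates enter as individual points, and the IC50 standard error
is the delta-method transform of the log10-scale covariance — reported
explicitly as a fit SE, since "±" values in assay reports are often
ambiguous between SE and replicate SD. Non-convergence sets a flag and NA
estimates, never a silent fallback.

One design point deserves emphasis. A two-fold series from 100 down to
1.5625 mg/mL around an IC50 of ~1.7 samples only the upper half of the
curve, leaving the top plateau unidentified from dosed wells alone; the
likelihood is then flat along a top/IC50 ridge and the IC50 estimate is
biased high. But the untreated control wells *are* zero-dose observations of
that plateau — at c = 0 the model evaluates exactly to `top` — so
`fit_plate()` includes them as data points. With the anchor, the mean
recovered IC50 over 500 seeded synthetic plates at 5% well CV is within a
fraction of a percent of truth (asserted at 5% in the test suite); without
it, the bias exceeds 10%.

## Synthetic data: what it does and does not emulate

The generators invert the analysis rules under a single seed
(`noise_config()`; each stage derives a fixed-offset sub-stream, so stages
are independently reproducible). MS2 spectra are built forward from a
compound entry — residue-loss ladder, cross-ring products for C-glycosides,
aglycone diagnostics and RDA ions — then perturbed: Gaussian ppm error on
the precursor (default sigma 5 ppm), Gaussian Da jitter on fragments
(default 0.3 Da), and uniform decoys on [50, precursor − 5] Da at low
intensity, redrawn until at least 1 Da from every true fragment so decoys
never collide with a rule mass. GC tables draw names/formulas from
fatty-acid, sterol and alcohol templates with symmetric-Dirichlet area
percentages scaled to a configured total (default 66.59%, a realistic
identified fraction for a lipoidal extract). Plates follow the triplicate
two-fold design (100 → 1.5625) with proportional well noise (default CV 5%,
typical of optical-density reads).

Round-trip identities pin the estimators to the generators: zero-noise
spectra are recovered at 100% top-1; zero-noise plates return the generating
4PL parameters to numerical precision; generated GC tables conserve the
configured total exactly. What the generators deliberately do not emulate:
chromatographic peak shapes and retention behaviour, isotope envelopes,
multiply charged species or adducts beyond ±H, intensity response curves,
and spectra of compounds outside the rule vocabulary. Passing the synthetic
suites therefore demonstrates the internal consistency of rules, annotator
and fitters — not instrument-level realism.

Problem sizes in the shipped tests (60–200 synthetic spectra, 500 synthetic
plates, brute-force formula checks on lattices up to C25 H40 N5 O12 S2) were
chosen so the full suite exercises every stage in tens of seconds on a
single core.

## Known limitations

- Sugar stereochemistry is invisible: hexose vs galactose conjugates
  (isoquercitrin vs hyperoside) are identical to every rule here and tie in
  the ranking; only orthogonal information (retention, standards) separates
  them.
- Diagnostic-fragment lists are curated per aglycone and negative-mode only;
  aglycones without curated lists score 0 on the diagnostic term.
- The annotator explains spectra against its library; it performs no de novo
  elucidation and no spectral similarity search.
- Formula generation is bounded-exhaustive, not heuristic; very wide bounds
  on high masses grow combinatorially.
- The 4PL fit assumes homoscedastic residuals on the viability scale; the
  proportional absorbance noise of real readers mildly violates this at the
  low-viability end.
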