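Package: flavomics
Title: Rule-Based Annotation of Plant Metabolite Profiles from LC-MS/MS and
    GC-MS with Dose-Response Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted phytochemical profiling built around the
    fragmentation chemistry of flavonoid glycosides and phenolics. Provides
    molecular-formula parsing and exact-mass arithmetic, candidate formula
    generation within a ppm tolerance, a neutral-loss rule engine
    (glycosyl, acyl and small-molecule losses, cross-ring cleavages),
    retro-Diels-Alder diagnostic-fragment prediction with mass conservation,
    a ranked MS2 feature annotator, GC-MS lipoidal class composition
    summaries (saturated and unsaturated fatty acids split by ring plus
    double-bond equivalents, curated sterols), four-parameter logistic
    dose-response fitting for IC50 estimation, and seeded synthetic-data
    generators so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
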