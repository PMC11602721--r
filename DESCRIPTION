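Package: chemtriage
Title: Heuristic Reaction-Outcome Triage from Orthogonal NMR and LC-MS Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Staged pass/fail decision-making for exploratory synthetic
    chemistry campaigns characterized by benchtop 1H NMR and (UPLC-)MS.
    Provides molecular-formula arithmetic and monoisotopic/average mass
    calculation, combinatorial enumeration of divergent synthetic routes and
    of coordination-balanced metal-organic assemblies (cages and helicates),
    expected m/z ladder generation across charge states and retained
    counterions, chromatogram peak detection and targeted or table-based m/z
    matching, dynamic-time-warping comparison of NMR spectra, peak-count and
    chemical-shift-perturbation heuristics for supramolecular and host-guest
    screening, a campaign-level decision engine that AND-combines the two
    orthogonal data streams, and seeded generators of synthetic NMR and LC-MS
    data so that every stage of the pipeline can be exercised without
    instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
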