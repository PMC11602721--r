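---
title: "Heuristic reaction-outcome triage from orthogonal NMR and MS evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic reaction-outcome triage from orthogonal NMR and MS evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtriage)
```

## The decision problem

Exploratory synthetic chemistry — parallel condensation screens, divergent
elaboration of successful precursors, combinatorial self-assembly of
metal–organic architectures — rarely reduces to maximizing one scalar figure
of merit. A reaction may "work" in many ways (or produce an interesting
species nobody targeted), and no single measurement settles the question.
The practitioner's remedy is orthogonality: mass spectrometry answers
*is a species of the right mass present?* while ¹H NMR answers *has the
mixture's structure changed, and does it look like one clean product?*
`chemtriage` implements a staged, rule-based decision engine over those two
data streams. Each reaction at each campaign stage receives a binary NMR
verdict and a binary MS verdict; by default a reaction is a *hit* only if it
passes **both** (an AND gate), and only hits generate follow-up experiments:
scale-up and diversification in a medicinal-chemistry-style campaign, or
replication and guest-binding assays in a supramolecular campaign.

The AND rule is deliberately conservative in a specific sense: both
heuristics are tuned loosely (each tolerates false positives on its own),
and the conjunction removes them. A weighted combination
(`combine = "weighted"` in `stage_criteria()`, scores
`w_nmr·s_nmr + w_ms·s_ms >= 1`) is available for workflows that trust one
channel more; the default weights of ½ each make it exactly the AND gate, so
the default behaviour never depends on that generalization.

## Expected-mass prediction

All MS evidence is judged against *algorithmically generated* expectations,
never against measured references.

**Organic products.** Molecular formulas are integer element-count vectors
over an embedded IUPAC mass registry (monoisotopic masses drive all m/z
arithmetic; average masses are carried for molar-mass reporting — at the
0.5 Da matching tolerance of a single-quadrupole instrument the electron
mass is immaterial and is ignored). Transform rules compose product formulas
from reactant formulas: (thio)urea formation and azide–alkyne cycloaddition
are pure additions, imine condensation loses one water per C=N bond formed,
Sonogashira coupling loses HBr. `enumerate_route()` expands a staged
combinatorial route (e.g. 3 amines × 2 electrophiles → 6 condensation
targets, then × 2 diversification branches → 12 terminal analogues) and
`adduct_mz()` attaches the positive-mode ions `[M+H]⁺`, `[M+Na]⁺`,
`[M+NH₄]⁺`.

**Metal–organic assemblies.** For a screen of carbonyl pyridines × polytopic
amines × metal ions, "chemically meaningful" species are defined as
homoleptic, coordination-balanced assemblies under maximal site occupancy:
every ligand is the full imine condensate of one amine (topicity *t*) with
*t* pyridines, every metal carries its full complement of bidentate
pyridyl-imine chelates (capacity 3 for octahedral Zn²⁺, 2 for tetrahedral
Cu⁺), and stoichiometries (m metals, l ligands) satisfy
`m × capacity = l × topicity`. The enumeration is therefore the
integer-multiple series of the minimal balanced solution up to a per-metal
maximum (10 for Zn²⁺, 12 for Cu⁺ by default). Mononuclear members are kept
by default (`include_mononuclear = FALSE` excludes them); the tests pin the
enumeration to an exhaustive double-loop search over all (m, l) pairs.
The net charge is `Q = m × metal charge` (neutral imine ligands), so the
tetrahedral Zn₄L₄ cage is 8+ and the Zn₂L₃ helicate 4+. In positive-mode
electrospray such a cation is observed at every charge state z = 1..Q,
retaining n = Q − z counterions:

    m/z(z) = (M + n·M_counterion) / z

`build_lookup_table()` precomputes this complete "charge ladder" for every
assembly over the whole screening grid. The counterion is a required
configuration field with no default chemical identity — its mass enters
every ladder value, and assuming one silently would be worse than forcing
the user to say which salt they used. The synthetic scenarios use triflate,
as a scenario choice, not a package default.

## MS processing

Gradient UPLC-MS runs are reduced to a total-ion chromatogram; peaks are
local maxima of the 5-point moving-average-smoothed TIC whose topographic
prominence exceeds a fraction (default 5%) of the trace maximum, merged
within 0.05 min, and integrated trapezoidally between valley bounds. "Main"
peaks are those holding at least 10% of the summed peak area (`rel_area_min`,
exposed in configuration — area rather than height, because area is what the
integrator conserves). Each main peak's scans are averaged (equal weights)
and re-centroided by 0.05 Da binning with intensity-weighted centroids;
`match_targeted()` passes when any expected ion lies within the tolerance
(default 0.5 Da, unit resolution) of any spectrum peak above a 2% relative
intensity floor.

Direct-injection runs (column bypassed, as used for assembly screening)
collapse to one time-averaged spectrum. `match_assembly_table()` counts, for
each lookup-table entry, the distinct charge states matched within
tolerance and passes only when some entry shows at least **two** distinct
charge combinations. Against a table with hundreds of ladder values a single
accidental match is likely; requiring two rungs of the *same* ladder is the
false-positive control. Carry-over between injections is instrument hygiene,
not data processing, so blank handling is out of scope here.

## NMR processing

Spectra are interpolated onto a common grid (0–12 ppm at 0.002 ppm, matching
the digital resolution scale of an 80 MHz benchtop instrument), solvent /
suppression regions are zeroed via per-campaign mask intervals, and
intensities are normalized to unit maximum (unit area is available).

**Chemical change (divergent screen).** The starting-material spectra are
summed (`combine_references()`) and compared with the reaction spectrum by
dynamic time warping: absolute-difference local cost, symmetric steps, a
Sakoe–Chiba band of 5% of the grid length (0.6 ppm — wide enough to absorb
benchtop drift, narrow enough that a genuinely new resonance cannot be
warped onto an old one), implemented in C++ with path backtracking. All
thresholds operate on the *normalized* distance (total cost / warping-path
length) so they are independent of grid resolution.

**Threshold calibration.** No numeric DTW thresholds are inherited from
anywhere; they are fixed by this package's own synthetic suite, once, before
the acceptance tests were frozen. Measured on the standard grid at the
default noise envelope (σ = 1% of the spectrum maximum): replicate pairs
(same peaks, independent noise) sit at a normalized distance of ≈ 0.0048
(the floor scales as ≈ 0.47 σ); unreacted mixtures against their own
reference reach at most ≈ 0.0068; full peak-pattern replacement gives
≥ 0.0107. The defaults split these regimes: `chemical_change` fires above
**0.009**, `parity_check` accepts below **0.006**, and the constructor
enforces parity < change since the two thresholds answer opposite
questions. A single shifted singlet between otherwise identical spectra
lands near 0.003 — intentionally *below* the change threshold: one moving
peak at benchtop resolution is drift, not chemistry. Consequently the
parity criterion is robust up to roughly σ ≈ 1.2%; the noise-degradation
test documents how recovery decays beyond that.

**Symmetric-product heuristic (supramolecular screen).** A single symmetric
assembly should show about as many ¹H resonances as its starting materials
combined — but at different shifts. `symmetric_product_test()` passes when
the reaction peak count is within ±2 of the summed starting-material counts
*and* at least half the reaction peaks lie ≥ 0.02 ppm from every
starting-material peak. Oligomer/polymer forests fail the count clause;
unreacted mixtures fail the shift clause. Peak picking uses local maxima
above 10% of the spectrum maximum merged within 0.05 ppm; the 10% floor
keeps baseline noise out of the count at the noise levels the generator
produces.

**Guest binding.** Both the host and the host-plus-guest spectra are
convolved with a unit-area Lorentzian of 10 Hz FWHM (frequency-domain
equivalent of exponential apodization) to emulate fast exchange and erase
fine structure; the kernel window spans 40×FWHM — Lorentzian tails are
heavy, so narrower windows lose percent-level area — and the result is
rescaled to conserve the integral exactly. Binding is called when any
aromatic-window (6.0–9.5 ppm) peak moves ≥ 0.02 ppm, appears, or
disappears. The window bounds and the broadening value are configuration,
not constants of nature.

## The synthetic-data generator

`gen_campaign()` manufactures complete campaigns with known truth:
Lorentzian ¹H lines (2 Hz FWHM) on the standard grid with additive Gaussian
noise (default σ = 1% of maximum), Gaussian chromatographic envelopes
(0.05 min width on a 2.5 min gradient window) carrying stick mass spectra,
and flat envelopes for direct injection. One bundle seed derives a
deterministic substream per generated object, so a single integer reproduces
an entire campaign.

The planted conditions mirror the campaign shapes the decision engine is
built for: a 3 × 3 × 2 supramolecular grid of 18 combinations of which
exactly two assemble (a Zn₄L₄ cage from the tritopic amine and a Zn₂L₃
helicate from a ditopic amine), each hit replicated six times, with the cage
binding three of six guests and the helicate none; and a divergent screen of
six condensations of which five succeed, every success scaling up with
parity and fanning out into two diversification branches (of which three
Sonogashira and four CuAAC outcomes carry the product ion). True hits carry
three randomly chosen rungs of their ladder plus decoy sticks; failures
carry only decoys, rejection-sampled at least 1 Da clear of every table
value. Product resonances are placed well away from starting-material
resonances (≥ 0.65 ppm where room permits, relaxing geometrically in
congested windows but never below 0.1 ppm) and at least three land in the
aromatic window so binding assays have something to perturb.

What the generator does **not** emulate — J-coupling multiplets, isotope
envelopes, baseline drift and phase error, retention-time shifts, detector
saturation, overlapping charge envelopes — bounds what a passing test shows:
the suite certifies the *decision logic* under controlled signal/noise, not
instrument robustness on real spectra. On real data the thresholds are the
knobs to revisit, which is why every one of them is configuration.

## Numerical choices and degenerate inputs

* DTW ties prefer the diagonal step, making the backtracked path unique and
  minimal; the band is measured around the stretched diagonal so unequal
  lengths are legal; an over-narrow band that disconnects the end cell is an
  error rather than an infinity.
* Peak merging keeps the taller of two maxima closer than the separation
  limit; chromatographic valley bounds are argmin between retained apices,
  trace ends outside.
* Empty inputs are contracts, not surprises: empty expected-ion lists,
  empty lookup tables and direct-injection runs passed to the
  chromatographic detector all raise errors; all-zero traces and empty
  spectra return empty results and failed matches.
* Enumeration with `max_metals = 0`, or a topicity/capacity pair with no
  balanced solution in range, returns an empty list — an empty answer to a
  well-posed question.
* Replicate aggregation defaults to all-must-pass (a reproducibility claim
  should not survive a failed replicate); majority voting is a configuration
  switch.

## Problem sizes used by the test suite

The acceptance suite runs the full supramolecular recovery over 20 seeds
(18 reactions, 12 replicates and 12 guest assays each) and the divergent
campaign end to end, the DTW oracle comparisons on sequences up to 50
points, and the mass-conservation property over 1000 random formula pairs —
sizes chosen to exercise every code path at desk scale while keeping the
whole suite in the minutes range.

## Known limitations

* The charge-ladder model assumes counterion loss is the only ionization
  channel for assemblies; mixed adducts and fragment ions are not predicted.
* Peak *counting* on low-field spectra is resolution-limited; the package
  reproduces that limitation faithfully (it is one reason the MS gate
  exists) rather than compensating for it.
* The lookup-table size depends on topicity assignments and per-metal
  maxima, which are configuration data: the enumeration rule is pinned by
  oracle tests, not by any externally printed table size.
* Decision timestamps make logs non-identical across runs; determinism is
  guaranteed (and tested) for everything except the timestamp field.
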