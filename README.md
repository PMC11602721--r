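# chemtriage

Staged pass/fail triage of exploratory chemistry reactions from two
orthogonal data streams: benchtop ¹H NMR and (UPLC-)MS.

## Who this is for

Groups running screening-style synthetic campaigns — parallel condensation
screens that feed scale-up and divergent elaboration, or combinatorial
metal–organic self-assembly screens that feed replication and host–guest
assays — who want the *go / no-go* step to be explicit, reproducible and
auditable instead of living in a chemist's head. The package contains no
instrument control: it consumes spectra and chromatograms (JCAMP-DX / CSV
for NMR, a documented CSV dialect for LC-MS), grades them, and plans the
next round of experiments.

## The core rules

For each reaction at each stage, an NMR heuristic and an MS heuristic each
return pass/fail, and the stage verdict is their conjunction (weighted
combination available; the defaults reproduce the AND gate). The heuristics
are:

* **Chemical change** — dynamic time warping distance between the reaction
  spectrum and the sum of starting-material spectra; normalized distance
  above a threshold ⇒ the mixture changed. Scale-up **parity** reuses the
  same metric with a strictly tighter threshold.
* **Targeted MS** — expected product masses are generated algorithmically
  from molecular-formula arithmetic over reaction transform rules
  (condensations, Sonogashira −HBr, CuAAC addition) with standard
  positive-mode adducts; a hit requires an expected ion among the *main*
  UPLC peaks (relative area ≥ 10%).
* **Symmetric product count** — a clean self-assembled architecture shows
  about as many ¹H resonances as its starting materials combined, but
  shifted; mixtures and oligomer forests fail.
* **Assembly table MS** — every coordination-balanced assembly
  `m × capacity = l × topicity` over the screening grid is enumerated under
  maximal site occupancy, its full counterion charge ladder
  `m/z = (M + n·M_ci)/z, z = 1..Q, n = Q − z` precomputed, and a
  direct-injection spectrum passes only when ≥ 2 rungs of one ladder match.
* **Guest binding** — after heavy Lorentzian line broadening, any
  aromatic-window resonance that moves, appears or disappears upon guest
  addition ⇒ bound.

A seeded synthetic-data module generates whole campaigns with known ground
truth, so the entire decision pipeline is testable without any instrument.

## Worked example

```r
library(chemtriage)

# Expected chemistry: urea condensation and its ESI adducts
rules <- standard_rules()
am  <- building_block("1", "alkyne_amine", "C3H5N")
iso <- building_block("5", "isocyanate", "C7H5NO")
urea <- apply_transform(rules$urea, list(am, iso))
urea
#> <species> 1+5  C10H10N2O  174.0793 Da
adduct_mz(urea)
#>     adduct       mz
#> 1   [M+H]+ 175.0866
#> 2  [M+Na]+ 197.0685
#> 3 [M+NH4]+ 192.1131

# A tetrahedral Zn4L4 cage and the top of its counterion charge ladder
blocks <- supramolecular_blocks()
cage <- assembly_species(blocks[["24"]], blocks[["28"]], blocks[["Zn"]],
                         m = 4, l = 4)
cage
#> <assembly> [Zn_4(24,28)_4]8+  C96H108N28Zn4+8  1908.65 Da
head(mz_series(cage, blocks[["OTf"]]), 4)
#>   z n        mz
#> 1 1 7 2951.3119
#> 2 2 6 1401.1799
#> 3 3 5  884.4693
#> 4 4 4  626.1140

# A full synthetic supramolecular campaign, graded end to end
bundle <- gen_campaign(supramolecular_scenario(), seed = 11)
run_campaign(bundle)
#> <campaign result> supramolecular
#>   screen: 2/18 pass
#>   replicate: 12/12 pass
#>   replicate_aggregated: 2/2 pass
#>   guest_assay: 3/12 pass
#>   bound guests per host: 24/28/Zn=3, 24/29/Zn=0
```

Reading the output: of the 18 pyridine × amine × metal combinations, the
decision-maker passed exactly the two planted assemblies (the Zn₄L₄ cage
`24/28/Zn` — net charge 8+ — and the Zn₂L₃ helicate `24/29/Zn`, 4+); each
was replicated six times, all twelve replicates passed parity and table
matching, and the guest assays found three of six guests bound by the cage
and none by the helicate.

A command-line interface over the same functions is installed at
`inst/cli/chemtriage` (subcommands `enumerate`, `mztable`, `analyze-nmr`,
`analyze-ms`, `decide`, `plan`, `simulate`, `run-campaign`); see
`?run_cli`.

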