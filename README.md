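# otolithchem

Tools for asking a connectivity question that matters for reef-fish
conservation: **are mangroves an obligatory juvenile habitat, and does
mangrove extent therefore shape where the adult fish occur?** The package
implements the full inference chain used to answer it from otolith
microchemistry and visual-census data:

1. **LA-ICP-MS signal reduction** — raw per-isotope count-rate time series
   (30 s gas blank + 90 s ablation) are cleaned of spikes with Tukey far-out
   fences, background-subtracted, and converted to concentrations (ppm) by
   external standardization against NIST 612 glass with calcium as the
   internal standard and linear drift interpolation between bracketing
   standards. Limits of detection follow the 3-sigma-blank convention:
   `LOD_e = 3 sd(blank_e) / S_e`, scaled like the concentrations.
2. **Element screening and compositional transform** — an element is kept
   only if detected above LOD in ≥ 70 % of otoliths in at least one habitat
   or site and its CV in the reference glass is < 10 %; retained
   concentrations become percent-of-total compositions.
3. **Habitat statistics** — one-way PERMANOVA (Euclidean, pseudo-F from the
   distance partition, 999 label permutations), per-element PERMANOVAs, and
   an arcsin-√x PCA for visualization.
4. **Random-forest habitat classification** — 5000 trees, each grown on a
   75 % subsample without replacement, evaluated out-of-bag, with an
   exhaustive search over all `2^k − 1` element subsets to find the most
   accurate fingerprint.
5. **Ontogenetic reconstruction** — the classifier is applied to ten
   ablation spots from the otolith core to 1260 µm (the juvenile portion),
   fish length at each spot is back-calculated with the Dahl-Lea model
   `L_i = (R_i / R_cpt) · L_cpt`, and cohort occupancy profiles summarize
   mangrove use through juvenile life.
6. **Survey biogeography** — distance-sampling UVC records are truncated at
   5 m (500 m² belt transects), converted to density (fish·m⁻²) and biomass
   (g·m⁻², via `W = a·FL^b`), aggregated per lagoon/reef stratum, and tested
   against mangrove area standardized by coast length (Pearson χ² on the 2×2
   presence table, Spearman rank correlations).

A first-class synthetic-data generator emulates every input the chain
consumes — habitat-specific elemental fingerprints (mangrove: elevated Ba,
Cr, Mn, Sn; reef: elevated Rb, Sr), instrument blank/noise/drift/spikes,
ontogenetic habitat shifts along transects, and survey abundance coupled to
mangrove extent — so the whole pipeline is testable without instrument data.

## Worked example

```r
library(otolithchem)

res <- run_pipeline(pipeline_config(seed = 1, search_trees = 500))
print(res)
#> <pipeline_result>
#>   retained elements: Li, B, Mg, Cr, Mn, Cu, Zn, Rb, Sr, Sn, Ba, U
#>   PERMANOVA: F_1,194 = 366.54, p = 0.001
#>   classifier: Cr (OOB overall 100.0%)
#>   occupancy: 100% mangrove at 0-140 um, 82% from 280 um
#>   UVC: Spearman rho(density) = 1.00
```

Reading the output: 12 of the 12 simulated analytes survive the
detection/CV screen; habitat explains the multi-element composition
(pseudo-F on 1 and 194 df, p at the permutation floor); the exhaustive
search finds that a single element already separates the two planted
fingerprints perfectly out-of-bag (the percent transform amplifies a trace
element's contrast when the dominant Sr moves the denominator the other
way); every simulated adult carries the mangrove signature on its first two
ablation spots and ~82 % from 280 µm outward, recovering the programmed
17-of-20 full-residency cohort to within classification error; and stratum
density tracks standardized mangrove area almost perfectly under maximal
coupling, with the presence χ² equal to the number of strata (the perfect
2×2 case).

Individual stages are ordinary functions — `reduce_runs()`,
`retain_elements()`, `percent_transform()`, `permanova_oneway()`,
`exhaustive_search()`, `classify_transect()`, `occupancy_profile()`,
`stratum_summary()` — and accept data read from CSV (see
`read_session_csv()`) as well as generator output.

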