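---
title: "Methods: from raw ablation signals to habitat connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw ablation signals to habitat connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otolithchem)
```

## The scientific problem

Otoliths grow by accretion and permanently record trace elements from the
ambient water, so the chemistry of the juvenile core of an adult otolith
tells us where that adult lived as a juvenile. `otolithchem` implements the
complete chain needed to exploit that record for a mangrove-versus-reef
question: reduce raw laser-ablation ICP-MS signals to concentrations, learn
a habitat fingerprint from fish of known capture habitat, read the juvenile
habitat back off adult otolith transects, and ask independently whether
adult abundance across an archipelago tracks mangrove extent.

## Signal reduction model

Each ablation is a 120 s per-isotope count-rate series: 30 s of gas blank,
then 90 s of ablation. The reduction assumes

* a **linear detector**: net count rate is proportional to concentration,
  with a per-isotope sensitivity $S_e$ (CPS/ppm);
* **slow linear drift**: $S_e$ changes linearly with acquisition order
  within a session, so bracketing NIST 612 standards allow interpolation.
  Interpolation is in *sequence index*, not wall-clock time, because
  acquisition order is the only ordering the session metadata records;
  back-to-back replicate standards are averaged into one bracket first;
* a **constant matrix**: the otolith is aragonite with a fixed calcium mass
  fraction, so Ca can serve as internal standard. The default is 38.8 wt%
  (the aragonite convention, exposed as `ca_mass_fraction`).

Concentrations follow the usual internal/external standardization
$$C_e = \frac{R_e}{R_{Ca}}\cdot\frac{S_{Ca}}{S_e}\cdot C_{Ca},$$
which makes every concentration invariant to a common rescaling of all
count rates (ablation yield) — the property that motivates the internal
standard, and one of the package's tested invariants.

**Outlier cleaning.** Both windows are cleaned per isotope with Tukey
*far-out* fences $[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$,
quartiles by linear interpolation (type-7). The fences are two-sided: a dip
in the blank is as non-physical as a spike. A window needs at least 4
readings for quartiles to be defined; fewer is an error, not a silent pass.

**Limits of detection.** $LOD_e = 3\,\mathrm{sd}(\text{blank}_e)/S_e$,
scaled to ppm exactly like the concentrations. Standard deviations use the
sample ($n-1$) convention throughout (LOD and standard CV); where a
population-SD reading of a worked example is wanted, both conventions are
exposed and the choice is explicit in the call. The counting-time factor
$\sqrt{1/n_B + 1/n_A}$ of the fuller LOD formulation is available via
`counting_time_term` but off by default. An element below its LOD is stored
as 0 ppm with a flag — zeros are data (non-detections), not missing values.

## Element screening and the percent transform

An element enters the statistics only if (1) it is detected in at least
70 % of otoliths in *some* habitat or *some* site, and (2) its CV across
the session's reference-glass analyses is below 10 %. Retained
concentrations are closed to percent of their row sum. Two interpretations
were genuinely open and are resolved as follows:

* **Ca is excluded from the denominator.** It is the internal standard
  pinned to a constant by construction; including it would compress every
  other element's share to near zero and encode no information.
* **"All measured elements" means "all retained elements".** Dropped
  elements are dominated by below-LOD zeros and standard noise; letting
  them into the denominator would contaminate the composition with exactly
  the signals the screen rejected.

The closure has a consequence worth knowing: if a *dominant* element (Sr,
~2000 ppm in this matrix) differs between habitats, the shared denominator
induces apparent contrast in every other element. That is not an artifact
of the implementation but of percent data; the univariate tests and the
subset search should be read with it in mind, and the test suite
deliberately plants trace-element-only contrasts when it needs a clean
null.

## PERMANOVA

The one-way pseudo-F is computed from the pairwise Euclidean distance
partition ($SS_{total} = \sum_{i<j} d_{ij}^2/N$, within-group terms
analogous), which for Euclidean distances equals the classical
raw-coordinate partition — an identity the tests verify. Significance comes
from unrestricted random permutation of group labels with the observed
statistic included in the reference set: $p = (1 + \#\{F^\pi \ge
F\})/(1+n_{perm})$, so the smallest attainable p with 999 permutations is
0.001. Percent compositions are used untransformed; the arcsin-√x transform
is applied only in the PCA, which is a visualization aid. With one response
column the pseudo-F reduces exactly to the ANOVA F, which provides the
closed-form oracle used in testing; a 1000-dataset null simulation checks
the test holds its 5 % size on the 199-permutation grid.

## Random-forest classifier and subset search

"75 % of the data build each tree" is implemented as per-tree subsampling
*without replacement* with out-of-bag evaluation — every fish is predicted
by the ~25 % of trees that did not train on it, which is what lets a
5000-tree forest "predict every individual several times". It is *not* a
single 75/25 split; the out-of-bag reading is documented as the package's
assumption wherever accuracy is reported. Feature sampling per split is the
standard $\sqrt{p}$.

The exhaustive search fits one forest per non-empty candidate subset
($2^k-1$ of them, capped at $k \le 20$), each with a seed derived
deterministically from the global seed and the subset's position, so the
ranking is reproducible and evaluations independent. Ties in out-of-bag
accuracy are broken toward fewer elements, then lexicographically — a
parsimony rule, which on strongly separated synthetic data often hands the
win to a single element. Prediction is majority vote over all trees; an
exact 50/50 vote goes deterministically to the most prevalent training
class (reef, under the study's 37/159 design).

## Ontogenetic reconstruction

Ten ablation spots from the core to 1260 µm (140 µm steps) cover the
juvenile portion of the otolith — 1260 µm being the otolith radius of the
smallest juvenile in the design, kept as a configurable constant. The
Dahl-Lea model $L_i = (R_i/R_{cpt})\,L_{cpt}$ back-calculates length at
each spot; it is exact proportional arithmetic, and the implementation
accepts $R_i = 0$ (the core spot maps to length 0) so the first spot of
every transect participates in the cohort profile rather than erroring.
Ages are annulus counts supplied as inputs (one annulus per year).

Because "used mangrove as a juvenile" admits two readings, both are
computed rather than choosing silently: `"early"` (mangrove at 0 and
140 µm) and `"throughout"` (mangrove at all ten spots). Classification
errors compound across ten spots, so the throughout rule is noticeably
stricter under imperfect classifiers — visible in the synthetic cohort
results.

## UVC biogeography

Distance-sampling records are truncated at 5 m per side — the boundary is
*closed* (a fish at exactly 5.0 m is kept), a deliberate reading of
"truncation at 5 m" — giving 500 m² belt transects (50 m × 5 m × 2).
Density is count/500; biomass uses $W = a\,FL^b$ with per-species
coefficients supplied as a table (nominal synthetic defaults ship with the
package). Stratum summaries are unweighted transect means with empty
transects included. The presence χ² is Pearson's *without* continuity
correction — with correction, a perfect 2×2 table over $n$ strata would no
longer give $\chi^2 = n$, breaking the closed-form anchor the tests rely
on. Spearman correlations are Pearson correlations of midranks with the
two-sided t approximation.

## What the generator emulates — and what it does not

The synthetic generator is first-class, tested code. It emulates:

* log-normal within-habitat concentration variation (strictly positive,
  right-skewed trace data; default CV 0.3) around habitat fingerprints with
  a configurable fold-change (default 3) on Ba, Cr, Mn, Sn (mangrove-up)
  and Rb, Sr (reef-up);
* the session structure: 8 otoliths between duplicate standard brackets, a
  standard after every ten transect ablations, linear sensitivity drift
  (default 0.2 %/run);
* Gaussian count noise with variance proportional to the mean — Poisson-like
  without forcing integer counts at high rates — plus 2 % outlier spikes at
  10× the local window mean, sized to exercise the Tukey fences visibly;
* 1 Hz sampling (120 readings per run): unconstrained by the design, small
  and sufficient;
* an instrument whose blank level (25 CPS) and sensitivity (2000 CPS/ppm)
  put the LOD near 0.008 ppm, so that trace analytes such as Rb (~0.05 ppm
  in this matrix) are measurable — the regime the element-retention design
  presupposes;
* a 20-fish adult cohort with 17 full-term and 3 early-only mangrove
  residents, capture lengths ~N(224, 25) mm truncated to [180, 280], and
  capture radii proportional to length (11.25 µm/mm, 5 % log-noise) so the
  back-calculated length at 1260 µm centres near 112 mm;
* survey abundance Poisson-distributed with mean proportional (at maximal
  coupling) to standardized mangrove area over a synthetic 14-stratum
  archipelago — 8 strata with mangrove, 6 without.

It does **not** emulate plasma physics, isobaric interferences, matrix
effects beyond a scalar sensitivity, spatial autocorrelation of habitat
chemistry within a fish's residency, inter-annual signature drift, or
observer error in the censuses. Passing tests therefore demonstrate the
*inference chain* is correct under its stated assumptions, not that any
particular field dataset satisfies those assumptions. A site-effect
variance parameter exists (`site_sd`) but defaults to 0, since the study
design does not constrain it.

## Numerical choices and degenerate inputs

* Noise-free synthetic sessions must reduce to the programmed truth within
  1e-9 relative error — the round-trip is exact up to floating point
  because drift is linear and interpolation is linear in the same index.
* All-equal windows have IQR 0; the fences collapse to the constant and the
  window passes through cleaning unchanged.
* Background subtraction floors at 0; a zero net Ca signal is an error
  (the internal standard is unusable), not a zero concentration.
* A singleton group, a constant univariate response, a zero-margin 2×2
  table, and a constant correlation vector are all rejections with
  explanatory messages, never silent NAs.
* Seeds: every stochastic entry point takes one; derived child seeds use a
  fixed integer recurrence kept inside 32-bit range.

## Problem sizes

The test suite runs reduced configurations (tens of fish, 60–500 trees,
99–199 permutations) chosen to exercise every property at comfortable
desk scale; the acceptance script runs the full study design — 196 otolith
surfaces, a 4095-subset search at 500 trees per forest, 999 permutations,
a 20-fish cohort and a 420-transect survey — in about two minutes. The
final classifier always uses the full 5000-tree specification.

## Known limitations

* The exhaustive search cost doubles per candidate element; beyond ~15
  candidates it is the dominant cost, and beyond 20 it is refused.
* Percent closure couples elements; no log-ratio (CLR/ILR) machinery is
  provided because the chain is defined on raw percents.
* No detection-function modelling for the censuses — fixed-width truncation
  is the design.
* Habitat classification treats spots independently; no smoothing or
  change-point structure along transects.
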