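---
title: "Tracing starch sources in beer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing starch sources in beer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchtrace)
```

## The problem

Brewers extend barley malt with wheat, corn, or rice. Each adjunct
contributes secondary metabolites that survive into the finished beer —
benzoxazinoid glucosides and their sulfates from wheat, oxindoleacetic-acid
glucosides and a characteristic C20/C21 oxylipin series from corn,
dioxindole derivatives and peptide-like compounds from rice. Ultra-high
resolution mass spectrometry resolves thousands of molecular compositions in
a single infusion, so the starch source can be read from exact masses alone,
with LC-MS² as the structure-confirming companion platform. `starchtrace`
implements that entire analysis as composable, deterministic functions, and
ships a cohort simulator so every stage can be validated against a known
ground truth.

## Exact-mass chemistry

All masses are monoisotopic, on the 12C = 12 scale, over the alphabet
C, H, N, O, S, P, Cl. Negative-mode ions are handled electron-inclusively:
[M−H]⁻ subtracts a proton (1.00727645 Da), [M+Cl]⁻ adds a chlorine atom plus
an electron (+34.96940126 Da). A formula is considered chemically plausible
when 0.3 ≤ H/C ≤ 3.0, O/C ≤ 1.2 (≤ 2.0 with phosphorus), N ≤ 7, S ≤ 3,
P ≤ 2, Cl ≤ 1, and its ring-and-double-bond equivalents
RDBE = C − (H+Cl)/2 + (N+P)/2 + 1 are a non-negative integer (the
even-electron/nitrogen rule for neutral molecules; phosphorus enters with
the trivalent convention so that phosphate esters — an observed compound
class — keep integer RDBE).

Formula assignment searches the bounded space C ≤ 66, H ≤ 126, N ≤ 7,
O ≤ 27, S ≤ 3, P ≤ 2, Cl ≤ 1 exhaustively (the heteroatom/C/O grid is
enumerated once and H solved per mass, which is exact, not heuristic). A
mass is *unambiguously* assigned when exactly one candidate passes, or the
best candidate's absolute error is at least 3-fold smaller than the
runner-up's. This operationalizes "unambiguous formula annotation"
deterministically and conservatively; the tests cross-check the search
against an independently coded library-lookup oracle.

## Alignment and preprocessing

Direct-infusion peak lists are aligned by single-linkage clustering of the
pooled sorted mass list with a relative gap threshold (default 0.5 ppm,
matched to sub-0.15-ppm instrument performance with margin). Clusters wider
than 3× the tolerance are split at their largest internal gap rather than
silently merged, bounding feature width. The consensus m/z is the
intensity-weighted mean, each sample contributes its most intense peak per
feature, and absences are zero-filled.

Occurrence filters mirror standard practice: a direct-infusion feature must
occur in at least 5 samples; an LC feature must occur in at least one third
of some class (the "at least" is read strictly, so the required count is the
ceiling of the fraction). LC intensities are drift-corrected feature-wise by
a LOWESS fit of pooled-QC intensity against injection order; every sample is
divided by the interpolated curve and rescaled by the median QC level so
intensities stay physical. Features absent in half the QCs pass through
unchanged, logged.

## The OPLS-DA estimator

`oplsda()` fits one joint model of all four classes against a one-hot
response with three predictive components — the geometry in which component
1 separates pure-barley beers from adjunct beers, component 2 wheat from
corn/rice, and component 3 corn from rice — plus (by default) one orthogonal
component. Orthogonal components are estimated first: the first NIPALS
loading is projected off the column space of X'Y, normalized into an
orthogonal weight, and the resulting component deflated from X; predictive
components then come from NIPALS PLS2 on the filtered matrix. Everything is
deterministic: NIPALS starts from the response column with the largest
variance (ties to the lowest index) and every weight vector is
sign-canonicalized so its largest-magnitude entry is positive, making
results bit-for-bit reproducible.

**Scaling.** Columns are always mean-centered; the default column scaling is
Pareto (divide by the square root of the SD). For log-normally distributed
MS intensities with random dropout zeros, unit-variance scaling inflates
low-intensity noise features until they drown the class signal, and a
log10-plus-offset transform turns dropout zeros into extreme negative
outliers; Pareto scaling — the long-standing compromise recommendation for
MS data — preserves some magnitude information while taming the dynamic
range. On the default simulated cohorts this is the difference between
Q² ≈ 0.31 and Q² ≈ 0.65 at identical data. Unit-variance and unscaled modes
remain available.

**Validation.** Q² = 1 − PRESS/SSTot over class-stratified 7-fold
cross-validation (folds deterministic under a seed; each fold recomputes its
own centering/scaling, and features constant within a training split are
ignored for that fold). CV-ANOVA forms
F = ((SSTot − PRESS)/d1) / (PRESS/d2) with per-element degrees of freedom
d1 = K·A and d2 = K·(N−1−A), where K is the number of classes and A the
total component count; the p-value is the upper F tail, and PRESS ≥ SSTot
yields p = 1 by definition rather than an error. Hotelling's T² flags score
outliers at the 95% ellipse using the exact F-based threshold
A(n−1)(n+1)/(n(n−A))·F₁₋α(A, n−A); outlier removal is a logged single-pass
refit, never iterated, so no silent mass exclusion can occur.

New samples are projected by applying the stored centering/scaling,
stripping the orthogonal components, rotating with W(P'W)⁻¹, and assigning
the nearest class centroid in predictive score space.

## Markers, van Krevelen, networks

Per-class marker scores project each feature's predictive-loading vector
onto the normalized direction from the overall score centroid to the class
centroid; in a balanced two-class model this reduces to the loading axis,
and a merged {corn, rice} pseudo-class captures compositions shared by both
adjuncts. The marker set is everything strictly above the 95th percentile of
the scores (linear-interpolation quantile); threshold ties are excluded, so
N distinct scores yield exactly floor(N/20) markers — 7,700 masses give 385.

Van Krevelen coordinates are exact count ratios H/C vs O/C with the
composition-class color code (CHO, CHNO, CHOS, CHNOS, P-containing; P takes
precedence). Mass-difference networks connect formulas (exact count
differences) or raw masses (ppm tolerance with a geometric-mean denominator,
symmetric in the pair) through a library of 46 named reaction differences
covering redox, conjugation, and amino-acid condensation chemistry; the
shipped set covers the full planted marker chemistry, and larger lists load
from TSV. Three sulfation variants are provided because observed
glucoside→sulfate pairs in cereal metabolism correspond to +H2SO3 rather
than the textbook +SO3; all three are named separately so edge labels stay
honest.

MS² similarity is a modified cosine: square-root intensity weighting,
fragments matched directly or at the precursor-difference shift
(neutral-loss match), each fragment used once, pairs taken greedily by
descending intensity product. Greedy matching equals the exhaustive optimum
on small spectra (verified against a brute-force oracle in the tests) and is
linear-time in candidate pairs. The network keeps edges at similarity
≥ 0.65 and labels connected components as clusters.

Cross-platform comparison merges LC isomers by m/z (single linkage, 5 ppm),
then matches DI masses to merged LC masses at ±5 ppm with the pair mean as
the ppm denominator — symmetric, so the match relation does not depend on
which platform anchors it. Overlap fractions count each feature once even in
many-to-many matches.

## The cohort simulator

`generate_cohort()` emulates the study design the analysis assumes: four
classes (barley, wheat, corn, rice), a shared background of uniformly
sampled, chemically filtered CHNO formulas whose [M−H]⁻ ions land in m/z
100–1,000, and planted class markers elevated by a configurable fold change
(corn-and-rice markers elevated in both classes). Defaults: 25 samples per
class, 2,000 background formulas, 8-fold marker elevation, log-normal
intensity noise with σ = 0.5, 10% dropout, 0.1 ppm mass-error SD (the
sub-ppm regime of a well-calibrated FTICR). Where the study design gives no
number (σ, dropout, base intensities), values were fixed once at what a
practitioner would call realistic for infusion MS and are not revisited.
LC-ToF mode adds uniform retention times in 0.5–9.5 min, a linear intensity
drift over injection order, a pooled QC every 10th injection (QCs are pooled
means re-measured with half the sample-level noise, not resampled
biology), template-based MS² spectra for marker features (dominant glucosyl
loss for glucosides, water/CO2 losses otherwise, plus ≤ 2% uniform noise
peaks), and consensus feature m/z whose error scales down with the square
root of the cohort size, as alignment averaging implies.

What the simulator deliberately does not model: isotopologue peaks, adduct
clusters beyond the configured adduct, chromatographic peak shapes,
correlated (biological) covariance between features, batch structure beyond
a single linear drift, and intensity-dependent dropout. Passing tests
therefore demonstrate that the pipeline recovers planted signal under
realistic noise — not that it is robust to every artifact of real
instruments; on real data the de-isotoping and adduct deconvolution steps of
an upstream peak picker are assumed done.

## Numerical and design choices

- Tolerances: alignment 0.5 ppm (DI), fragment matching 0.01 Da (ToF scale),
  cross-platform ±5 ppm; all arguments, never constants.
- Peak-list readers collapse duplicates within 0.1 ppm and report sorting
  repairs; readers never silently reorder or merge.
- NIPALS converges at a relative score change of 1e-12 (cap 1000
  iterations); a null orthogonal component (weight norm < 1e-10 of the
  loading) stops orthogonal extraction with a warning instead of
  manufacturing noise components.
- Ties: percentile-threshold ties are excluded (logged); the NIPALS start
  column ties to the lowest index; greedy fragment pairs tie-break on
  fragment indices.
- Degenerate inputs fail loudly: constant columns must be dropped before
  fitting, folds cannot exceed the smallest class, empty spectra and empty
  reaction libraries are errors.
- Problem sizes in the validation suite: cohorts of 100 samples × ~2,050
  features, five seeds for the recovery properties and three for the model
  validity bounds; enumeration oracles run on 100 random masses in m/z
  100–500. These sizes exercise every code path at full statistical fidelity
  while keeping the whole suite under a minute.

## Known limitations

Positive-mode adducts, multiply charged ions, and isotope-pattern scoring
are out of scope. The reaction library is a curated core, not the exhaustive
difference list a dedicated annotation engine would carry. CV-ANOVA degrees
of freedom follow the per-element bookkeeping documented above; other
published variants differ in small ways and give slightly different (equally
tiny) p-values on well-separated data. The Hotelling refit is single-pass by
design — data sets needing repeated exclusion rounds deserve manual
inspection, not automation.
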