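---
title: "Single-cell shotgun lipidomics of PC and SM: models and methods"
author: "scLipidFlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell shotgun lipidomics of PC and SM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLipidFlow)
```

# The measurement being modelled

Cells sorted by FACS (one or fifty per well) land in a 96-well plate
preloaded with solvent and two internal standards -- PC 17:0/17:0 and
dihydrosphingomyelin 12:0, spiked at 1000 fmol into fifty-cell wells
and 1.38 fmol into single-cell wells. Each well is infused through a
chip-based nanoESI source into a unit-resolution triple quadrupole
running a precursor ion scan of m/z 184: only ions that shed a
phosphocholine head-group fragment are recorded, which restricts the
640--850 m/z window to phosphatidylcholine (PC, including ether-linked
PC O-) and sphingomyelin (SM). Species are annotated at the
sum-composition level -- class, total side-chain carbons and total
carbon--carbon double bonds -- because the class-selective scan carries
no acyl-level or double-bond-position information.

The package implements the full computational chain downstream of the
instrument: target-list chemistry, spectrum processing, extraction-blank
subtraction, internal-standard quantification, and the single-cell
heterogeneity statistics. A plate simulator stands in for the
instrument so every stage can be tested against known ground truth.

# Lipid chemistry

Elemental formulas are assembled from the class backbone: a diacyl PC
with C carbons and D double bonds is C(C+8) H(2C-2D+16) N O8 P, an
ether PC trades one ester oxygen for two hydrogens, and an SM is
C(C+5) H(2C-2D+13) N2 O6 P. Only the protonated adduct is computed:
positive-mode detection of the m/z 184 fragment implies [M+H]+.

```{r masses}
adductMz("PC 34:1")          # the most abundant endogenous species
adductMz("PC 17:0/17:0")     # the PC internal standard (sum comp. PC 34:0)
phosphocholineFragmentMz()   # the reporter fragment, nominal m/z 184
```

Isotopologue envelopes come from truncated multinomial convolution of
natural isotope abundances (vendored IUPAC/CODATA constants, so results
are bit-stable). Envelopes are truncated at M+4; beyond that,
contributions are below 0.5% for formulas in the scan window. Because
PC carries one nitrogen and SM two, PC [M+H]+ nominal masses are even
and SM odd -- the two classes never collide at the monoisotopic level
within the 0.5 Da matching tolerance, but their *isotopologues* do
interleave (see Deisotoping).

The packaged target list covers diacyl PC 28:0--44:12, ether PC O-
30:0--40:7, SM 32:1--42:3 and both internal standards (63 entries).
Endogenous PC 34:0 and SM 30:0 are deliberately absent: they are
isobaric with the internal standards at unit resolution, so their
signal would be indistinguishable from the spike. Odd-chain diacyl PC
names parse, but isobaric odd-chain/ether ambiguity is reported as
ether-linked only.

# The plate simulator

The simulator's defaults are the package's statement of the study
conditions; they were fixed on biological grounds and are not tuned.

* **Per-cell totals**: 20 fmol PC and 4 fmol SM per cell. Per-species
  amounts then sit in the amol-to-low-fmol range; 20 fmol PC is a
  mid-range literature value for cultured mammalian cells and SM is
  set at one fifth of PC, a typical whole-cell SM/PC ratio.
* **Biological variability**: lognormal with CV 0.25 on per-cell class
  totals and on per-species fractions (renormalised per class), a
  mid-range single-cell molecular CV.
* **Technical variability**: lognormal with CV 0.05 per well and
  species, emulating shot-to-shot infusion and spray fluctuation of
  chip-based nanoESI. Without it, fifty-cell and bulk wells average
  away nearly all biological noise and become unrealistically precise,
  so that sub-percent processing biases would register as significant
  group differences.
* **Peak shape and noise**: Gaussian peaks of 0.6 Da FWHM on a 0.05 Da
  grid emulate unit resolution (the M+1 partly merges into the M+0
  shoulder); a flat baseline (150 counts) with Gaussian sd 70 plus a
  Poisson-like term (sd = sqrt(intensity)) sizes single-cell base
  peaks near S/N 85 -- the upper half of the 10--100 range such spectra
  show -- with ~1% species straddling the S/N 4 detection threshold.
  A lower setting (base peak S/N ~30) would cap the detectable set
  near 25 species, inconsistent with the >50 species the workflow
  demonstrably recovers from single cells, so the upper half of the
  band is the self-consistent choice.
* **DHA supplementation**: under the `"DHA"` treatment the mean
  fractions of PC species with >= 6 double bonds are tripled and the
  composition renormalised, mimicking incorporation of
  docosahexaenoic acid (22:6) into membrane PC.
* **Profiles**: C2C12- and HepG2-like compositions for the
  supplementation experiment, and four prostate profiles with PC 34:1
  pinned at published shares of total PC (LNCaP 0.48, PC3 0.26, DU145
  0.35, PNT1 0.33). Lineages differ across many species, not one, so
  each line applies a broad multiplicative tilt to the shared
  template; DU145 and PNT1 share most of their tilt because those
  lines are near-indistinguishable by PC/SM profile.
* **Contaminants**: two background peaks (678.51, coincident with
  PC 28:0, and 725.40, matching no target) are rendered in *every*
  well -- they model solvent/extraction background, which is exactly
  what extraction-blank subtraction corrects.

What the simulator does **not** emulate: ion suppression and
cross-species response differences (all response factors default to
1, as relative quantification against one standard per class assumes),
spray instability over the acquisition, mass-calibration drift,
detector saturation, and chimeric contributions from lipid classes
other than PC/SM. Passing tests on simulated plates therefore
demonstrate the correctness of the computational chain under the
stated noise model, not instrument-level robustness.

# Spectrum processing

Processing follows the unit-resolution shotgun convention and its
standard settings: 0.5 Da matching tolerance, minimum intensity 0.1%,
minimum S/N 4, smoothing and deisotoping enabled.

* **Noise** is estimated on the acquired (unsmoothed) trace as
  1.4826 x MAD of first differences / sqrt(2), restricted to the
  low-activity half of the spectrum selected on a 2 Da running mean.
  Selecting *regions* rather than individual low samples avoids
  truncating the noise distribution; the estimator recovers a known
  sd within ~10% and ignores peaks. S/N for a peak is its
  baseline-subtracted height over this estimate, so smoothing does not
  silently inflate S/N.
* **Smoothing** is a boxcar of 0.3 Da with truncated end windows;
  integrated intensity is conserved.
* **Baseline**: direct infusion has no chromatographic gradient, so a
  flat baseline is estimated as the median intensity over the same
  low-activity mask and subtracted before picking. A global median
  would be dragged upward by peak tails in crowded high-signal wells
  and bias small-peak areas low.
* **Peak picking**: local maxima above 3 x noise, iteratively pruned
  by prominence (height above the higher separating minimum) so noise
  bumps on a larger peak's shoulder are not promoted to peaks. The
  centroid is the intensity-weighted mean over the contiguous
  above-half-maximum region; the area is the trapezoidal integral of
  baseline-subtracted intensity between the separating minima.
* **Matching**: each target takes the nearest picked peak within
  0.5 Da; a peak satisfies at most one target, conflicts resolve
  nearest-first and exact ties go to the lower expected m/z.
  Unmatched targets keep a zero-area row.
* **Deisotoping**: working up the m/z axis, each species' area is
  reduced by the predicted isotopologue contributions of lighter
  matched species whose M+k (k = 1..4) lands within 0.15 Da of its
  m/z, using that species' own already-corrected area times its
  M+k/M+0 envelope ratio. This covers the classic same-class M+2
  overlap from the species with one more double bond (2.007 Da below,
  landing 0.009 Da off target) *and* the cross-class case in which an
  SM monoisotopic peak sits ~0.06 Da above the M+1 of a PC one nominal
  mass unit below (e.g., SM 40:1 at 787.67 vs PC 36:2's M+1 at
  787.60). Correcting only the M+2 overlap would leave such SM species
  several-fold overestimated, because the PC pool is roughly five
  times the SM pool. Same-class M+1 never fires: within a class,
  targets are at least 2 Da apart, so M+1 peaks fall between targets
  and stay unmatched. Corrections clamp at zero with a warning, and
  the operation is idempotent on its own output.
* **Filters**: a species passes if S/N >= 4 and its deisotoped area is
  at least 0.1% of the well's largest deisotoped species area. The
  0.1% reference point is the within-well base species (the relative
  reading of "minimum intensity"); an absolute-counts reading was
  rejected as unit-dependent. Failing rows keep their areas but are
  excluded from quantification, with the failed criterion recorded.

A physical limit worth stating: when a species sits directly on the
M+1 of an interferer ~10x its size, its area is the small difference
of two large merged quantities. The correction removes the bulk of the
interference, but percent-level residuals of the big peak translate
into tens of percent of the small one. This is a property of merged
unit-resolution areas, not of the implementation; the recovery and
linearity properties are therefore stated over collision-free species,
and collision-affected SM species should be read with caution -- in
simulation and on a real instrument alike.

# Quantification

Blank subtraction comes first: per species, the mean (optionally
median) deisotoped area over the batch's extraction blanks is
subtracted and negatives clamp to zero; zeros are retained as zeros,
not treated as missing. Internal-standard rows are never
blank-subtracted -- blanks are spiked with IS too, so ratioing first
and subtracting later would distort the reference; this resolves the
ordering the source leaves unstated. Amounts then follow as

    fmol(species) = corrected_area(species) / area(class IS) x spiked_fmol(class)

with PC species (diacyl and ether) against the PC standard and SM
against the SM standard. No isotope-response or chain-length response
correction is applied -- quantification is relative by construction,
and a single response factor per class is the method's stated
assumption; this is a documented limitation, not an oversight. A well
whose IS fails the filters is reported unquantifiable rather than
rescued. Percent-of-class compositions and the >= 6 double-bond
(DHA-containing) PC fraction derive from the fmol table and are
invariant to any per-well rescaling.

# Heterogeneity statistics

* **CV versus mean**: per species, CV = sd/mean x 100 across the wells
  of one group (groups are analysed separately, one cell line and
  treatment at a time -- pooling would read treatment effects as
  heterogeneity). An ordinary-least-squares polynomial of CV on
  log10(mean) -- degree 2 by default, as the CV--mean relation of
  counting-limited data is convex on the log scale -- provides the
  trend, and species outside the pointwise confidence interval of the
  fitted line at their mean are flagged, with the side recorded. The
  CI of the mean response is the flagging band; the wider prediction
  interval is computed alongside for reference. A CI band is narrow by construction, so a fair number of
  species are flagged -- it answers "is this species off the trend
  line", not "is this species extreme for a single draw".
* **Welch comparisons**: unpaired two-sided t tests with Satterthwaite
  degrees of freedom per species, flagged at raw P < 0.05 (no
  multiple-testing correction, the field's usual reporting convention);
  Benjamini--Hochberg q-values are emitted alongside. Species constant
  in both groups with equal means get p = 1 by convention. Bulk versus
  fifty-cell comparisons are made on the relative-intensity (percent)
  scale.
* **PCA** is centred and scaled, via `prcomp`; constant species are
  dropped with a message, and loadings are also returned as
  per-species correlations with each component for loading plots.
* **t-SNE** delegates to Rtsne with exact (theta = 0) gradients and
  perplexity = round(sqrt(N)) (minimum 2, reduced with a warning when
  it reaches N/3); all other settings are the Rtsne defaults, which in
  particular do not z-score species individually. Given a seed the
  embedding is deterministic.
* The pipeline's analysis stage embeds the per-cell
  relative-intensity matrix (percent of each cell's total) rather than
  raw fmol: per-cell totals carry cell-size variability that would
  otherwise dominate every distance, and single-cell lipidome
  comparisons are conventionally displayed on this scale.

# Pipeline and reproducibility

`runSimulate()`, `runProcess()` and `runAnalyze()` (or `runPipeline()`,
and the thin command-line wrapper in `inst/scripts/sclipidflow.R`)
chain the stages on disk: spectra as per-well TSV (or mzML via mzR),
plate layout, ground truth, annotated peak tables, fmol matrices,
heterogeneity reports and plots, plus a `manifest.yaml` that re-runs to
identical outputs. Every stochastic step flows from one integer seed;
identical seeds give byte-identical results.

The packaged scenarios follow the two experiment shapes: the DHA
experiment (2 lines x 2 treatments x 3 blanks + 3 fifty-cell + 18
single-cell wells -- a full 96-well plate) and the prostate panel (4
lines x 3 fifty-cell + 18 single-cell wells + blanks). The test suite
exercises scaled-down versions of these designs (10--12 single cells
per group) to keep runs short; the acceptance checks use the full
plate shapes.

# Known limitations

* Sum-composition annotation only; no sn-position, acyl split or
  double-bond position.
* One response factor per class: amounts are relative, not absolute
  molar quantities.
* SM species on cross-class M+1 collisions carry the residual-overlap
  uncertainty described above.
* Endogenous PC 34:0 / SM 30:0, if present in a real sample, would
  inflate the internal-standard areas and deflate all amounts of that
  class; the defined-acyl standards are chosen to keep that overlap
  small in practice.
* The simulator's noise model is stationary white noise plus
  shot noise; structured interference (solvent clusters, in-source
  fragmentation) is reduced to the two configurable contaminant peaks.
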