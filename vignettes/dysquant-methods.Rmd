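---
title: "Quantifying sarcolemmal dystrophin from spectral confocal stacks: models and methods"
author: "dysquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcolemmal dystrophin from spectral confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Duchenne and Becker muscular dystrophy (DMD, BMD) are caused by loss or
reduction of dystrophin, a protein of the muscle-fibre plasma membrane (the
sarcolemma). Quantifying residual dystrophin in muscle biopsies matters both
for diagnosis (mild BMD, female carriers) and as a pharmacodynamic readout
for dystrophin-restoring therapies, where the expected increases are subtle.
Conventional immunofluorescence reads a single filtered intensity per pixel
and cannot resolve signals close to the noise floor; spectral confocal
imaging instead records, for every pixel, the whole emission spectrum as a
lambda stack — one image slice per detection window — so the analysis can
find the true emission peak and quantify at the wavelength where the
fluorophore is brightest.

`dysquant` implements this quantification scheme end to end:

1. **Acquisition model** (`spectral_stack`, `wavelength_axis`): a channel is
   a rows × cols × n~λ~ cube of 12-bit intensities (0–4095 a.u.), with a
   detection window of width 15 nm slid in steps of 5.21 nm (windows
   overlap). The dystrophin channel (AF488-type secondary, excitation
   470 nm) is collected from 485–625 nm (27 windows); the β-spectrin
   membrane-guide channel (Cy5-type, excitation 570 nm) from 590–780 nm
   (37 windows). Frames are 512 × 512 px at 0.361 µm/px. The nominal pixel
   pitch and field of view quoted for this acquisition geometry are not
   perfectly consistent with each other (512 × 0.361 ≈ 184.8, not 184.52);
   the package records the pitch as linear µm/px and does not attempt to
   reconcile the two.
2. **ROI model** (`elliptical_roi`): the unit of quantification is a small
   ellipse confined to the sarcolemma. The protocol uses 26 ROIs in each of
   3 fields per biopsy — 78 ROIs per biopsy — placed on the membrane using
   the β-spectrin channel as a guide, deliberately avoiding sarcoplasm,
   vessels and adipose or connective tissue.
3. **Spectral quantification** (`roi_mean_spectrum`, `peak_wavelength`,
   `quantify_field`, `aggregate_biopsy`): each ROI's *spectral signature* is
   its mean pixel intensity per window; a single maximum-emission-peak
   window is chosen from the average signature and every ROI is read at
   that window, giving one intensity value per ROI and a mean ± SE per
   biopsy.
4. **Automatic ROI detection** (`detect_rois`): an operator-independent
   reimplementation of the manual placement, described below.
5. **Statistics** (`icc_absolute_agreement`, `normality_test`,
   `compare_groups`, `compare_methods`): reproducibility via ICC,
   Shapiro–Wilk normality, Kruskal–Wallis plus pairwise Wilcoxon rank-sum
   comparisons of raw ROI intensities between diagnostic groups, and an
   equal-variance two-sample *t*-test comparing manual against automatic
   per-biopsy means.

Because no raw patient images are publicly available, the package also
ships a synthetic muscle-field simulator with exact ground truth
(`generate_geometry`, `render_field`, `generate_cohort`, `oracle_rois`);
every claim the test suite makes is made against that ground truth.

## The automatic detection pipeline

All stages are deterministic; every tunable lives in `pipeline_config()`.

**Reference slice.** The β-spectrin stack is reduced to the single window
with the highest mean fluorescence (ties to the lowest index; indices are
1-based in the R API).

**Denoising.** A median filter of radius 1 px (config: `median_radius_px`).
Edges are handled by mirror (reflect-101) padding. The filter is an exact
neighbourhood median implemented as a vectorized sorting network, so unit
tests can demand bit-exact agreement with a brute-force oracle.

**Binarization.** Otsu's criterion, computed by exhaustive sweep over the
integer intensity levels, maximizing between-class variance with ties
resolved to the lowest threshold; the mask is `image > threshold`. In the
β-spectrin channel the membrane is the bright class.

**Fibre extraction.** Fibre interiors are connected components of the
*complement* of the bright-membrane mask, cleaned by binary opening (disc
r = 2 px), hole filling and removal of frame-touching components, then
filtered by area (≥ 300 px ≈ 39 µm²) and circularity (4πA/P² ≥ 0.3).
The polarity choice — membrane bright, interiors extracted from the
complement — is what makes "uniform, approximately circular regions"
correspond to muscle fibres. The permissive circularity floor reflects that
dystrophic fibres are polygonal and variable in size, not round.

**Sarcolemma location.** Fibre regions are dilated (disc r = 4 px) and the
dilated area outside the original regions is the inter-fibre band where the
sarcolemma lies. The band's thickness is estimated as twice the median of
its distance transform on the ridge, and a per-pixel tangent orientation
field is derived from the structure tensor of the smoothed band. Two
numerical details matter here: the band is padded with a one-pixel
background ring before the distance transform so that the frame edge bounds
the band like any other boundary (otherwise frame-edge membrane reads as
twice its true thickness), and by default the band is intersected with the
bright-membrane mask (`refine_band = TRUE`). The dilation band alone is as
wide as the dilation radius dictates, not as wide as the membrane; without
the refinement, ellipses sized from the band overhang into sarcoplasm and
bias every intensity estimate low. With it, ellipse size tracks the actual
membrane.

**Ellipse proposal.** Candidate ROIs are centered on the band's ridge
pixels, thinned greedily in (row, col) scan order to a minimum spacing, with
the major axis following the local tangent. Default geometry derives from
the measured membrane thickness *t*: semi-minor = max(1, t/2 − 0.5),
semi-major = 2 × semi-minor, spacing = 2 × semi-major. The −0.5 px keeps
boundary pixel *centers* strictly inside the membrane under the
pixel-center-inside-ellipse rasterization rule; with semi-minor exactly t/2
the rasterized ellipse picks up one row of off-membrane pixels and the ROI
mean inherits a percent-level negative bias.

**Scoring and selection.** Each candidate receives three components in
[0, 1] — brightness (mean reference intensity in the ROI, normalized by the
field maximum), orientation (|cos| of the angle to the local wall tangent),
and wall overlap (fraction of pixels on the membrane minus fraction off it,
clipped) — combined as a convex sum with default weights (⅓, ⅓, ⅓). Whether
the original ranking combined its three criteria additively or
multiplicatively is not stated anywhere we could check; the additive form is
the minimal realization and the weights are config-exposed. Selection is
greedy in descending total score, ties broken by (row, col), skipping any
candidate whose rasterized pixels intersect an already selected ROI, until
26 ROIs (or exhaustion, which sets a shortfall flag). Only the β-spectrin
channel is ever consulted, so detection is blind to the dystrophin signal —
a property the tests assert directly.

## Quantification choices

The emission peak is selected **per biopsy** by default: all 78 ROI spectra
are pooled, averaged, and the argmax window re-read for every ROI. The
protocol's "single value for the maximum emission peak in each case"
supports this reading but does not pin the pooling level; `peak_policy =
"per_field"` is retained for comparability. The SE is computed over the 78
pooled ROIs, not over field means, matching how the published group
summaries are described. β-spectrin may be quantified as a diagnostic
output but is never used to normalize dystrophin: its intensity is itself
elevated in dystrophic muscle, which would make normalized ratios
understate dystrophin differences.

`detection_percentage(signal, reference)` expresses a residual signal
relative to a control mean to one decimal — e.g. a 15 a.u. trace against a
2982.9 a.u. control mean is 0.5%, the kind of signal that is invisible
under conventional fluorescence microscopy.

## The synthetic field model

`generate_geometry()` emulates a transverse muscle section: fibre cross
sections are multiplicatively weighted Voronoi cells of Poisson-disc seed
points (weights U(0.85, 1.15) perturb the cells into irregular polygons),
separated by a sarcolemma wall where the two smallest weighted distances
differ by less than the wall thickness, plus a wall ring along the frame
edge so every interior is membrane-enclosed. Defaults: 512 × 512 px, 30
fibres, 4 px wall (≈1.4 µm at 0.361 µm/px). Fibre counts per field and
wall thickness are not documented for the original acquisition; these
defaults are chosen as histologically plausible for transverse sections of
young patients at 63×, and are parameters, not facts. Optional confounder
classes (vessel, adipose, connective tissue) convert whole cells, never
destroying more than 20% of the fibres, so the pipeline's robustness to
"misinformative regions" is testable.

`render_field()` renders each channel as: class intensity × Gaussian
emission line integrated over each detection window, plus optional flat
autofluorescence and optional linear bleed-through from the other channel,
plus Gaussian noise of variance readout² + shot_scale × signal (a Gaussian
approximation of Poisson shot noise), rounded and clipped to 12 bits.
Window responses are normalized to 1 at the brightest window of the
channel's own axis, so the noiseless wall intensity at the peak window
equals `wall_mean` exactly and ground truth stays analytic. Default
emission peaks are 519 nm (AF488-like) and 670 nm (Cy5-like) with spectral
sigmas of 18 and 22 nm — nominal values for the secondary antibodies used
in this protocol; the Gaussian line shape itself is a modelling choice, as
the acquisition defines only the windowing.

Wall intensity heterogeneity is drawn per ~8 px arc patch along each wall
segment (`patch_px`), truncated at zero. The patch scale is deliberately
comparable to an ROI's major axis: `wall_sd` is specified as the
*between-ROI* standard deviation, and heterogeneity at much coarser scale
would not deliver it — ranked selection then concentrates many ROIs on few
bright segments and their values stop being independent. Group levels
default to the published per-group means, with between-ROI SD = SE × √78
for the dystrophin antibodies (whose published errors are SEs over 78
pooled ROIs). The β-spectrin errors pool at an unstated level and taken at
face value would imply a 64% per-ROI coefficient of variation, so the β
channel instead uses a 15% CV — a typical membrane-staining spread. Biopsy
true means vary around the group mean with a 5% between-biopsy CV by
default (`between_biopsy_cv`), a modest inter-patient spread that keeps the
three diagnostic groups separated as the published violin plots show;
setting it to 0 makes parameter-recovery experiments exact.

`oracle_rois()` stands in for the human operator: ellipses centered on the
ground-truth wall midline, tangent-aligned, pairwise disjoint, each with
≥ 90% of its pixels on the membrane. Because oracle placement uses ground
truth and automatic placement uses only the rendered β channel, comparing
the two quantifications reproduces the manual-vs-automatic design.

**What the simulator does not model:** optics (no PSF, no z-dimension),
photobleaching, spatially correlated autofluorescence, chromatic
misregistration between channels, and any correlation between β-spectrin
and dystrophin staining heterogeneity (the two channels' patch values are
drawn independently). Passing tests therefore demonstrate that the
pipeline recovers known truth under idealized but noisy acquisition; they
do not certify performance on real sections with fibrosis, necrotic fibres
or sectioning artefacts, where the confounder classes are only a coarse
proxy.

## Statistical layer

ICC uses the two-way random-effects, absolute-agreement, single-measures
form, computed from the ANOVA mean squares
(MS~R~ − MS~E~) / (MS~R~ + (k−1)MS~E~ + k(MS~C~ − MS~E~)/n), with the
standard F-based 95% interval. The reproducibility protocol this serves
reports replicate counts inconsistently (four experiments vs three
replications); the implementation simply takes raters = columns supplied.
"Wilcoxon" is the unpaired rank-sum form, since the comparisons are of
unpaired raw fluorescence values; pairwise p-values are reported raw by
default (matching how the original analysis reports them), with an
optional Holm adjustment. The method comparison is the pooled-variance
two-sample *t*-test. Degenerate inputs (constant matrices, zero pooled
variance) raise classed errors rather than returning NaN.

## Problem sizes and numerical conventions

- Unit tests run on 160 × 160 fields with 8 fibres; acceptance-level checks
  use full 512 × 512 fields, the 10/3/6 × 3-field cohort design, and all
  three dystrophin antibody levels. These sizes are the package's chosen
  test design points.
- Coordinates are 0-based (row, col), origin top-left, row increasing
  downward; θ is measured from the +col axis in [0, π). A pixel belongs to
  an ellipse iff its center satisfies the ellipse inequality (≤).
- Intensities live in 16-bit TIFF containers holding 12-bit values; stack
  metadata travels in a JSON sidecar (`centers_nm`, `step_nm`,
  `bandwidth_nm`, `excitation_nm`, `pixel_size_um`, `bit_depth`,
  `channel_label`). Round trips are bit-exact. ROI sets travel as CSV; the
  ImageJ binary ROI archive is not supported.
- Every stochastic component (geometry, rendering, cohort truth, oracle
  placement order) is seeded; identical inputs and seeds give bit-identical
  outputs, and the detection pipeline itself contains no randomness.

## Known limitations

- The ranking weights, ellipse sizing rule and morphological radii are
  faithful but minimal realizations of a procedure described only
  qualitatively; alternative readings (multiplicative ranking, ratio-form
  wall occupancy) are noted in the documentation but not implemented.
- The published patient-level numbers (group means, ICC = 0.94) are used as
  simulation ground truth for parameter recovery; they cannot be recomputed
  from raw data because none is deposited.
- Proprietary microscope formats (Leica LIF/LAS X) are out of scope; data
  must be exported to multi-page TIFF first.
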