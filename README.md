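# dysquant

Quantification of sarcolemmal dystrophin from spectral confocal (x-y-λ)
image stacks of transverse muscle sections.

## The problem

Duchenne and Becker muscular dystrophies (DMD, BMD) are defined by
near-absent versus reduced dystrophin at the muscle-fibre membrane (the
sarcolemma). Measuring residual dystrophin — and subtle increases under
dystrophin-restoring therapy — demands more sensitivity than conventional
immunofluorescence offers. Spectral confocal microscopy records, for every
pixel, the whole emission spectrum as a *lambda stack* (one slice per
detection window: 15 nm windows stepped by 5.21 nm, 12-bit intensities), so
quantification can read each region of interest (ROI) exactly at its
maximum emission peak. With this approach, dystrophin traces down to ~0.5%
of the healthy-control level are quantifiable.

`dysquant` is for muscle pathology and neuromuscular research groups who
want this quantification scheme as reproducible, scriptable code:

- **I/O** for spectral stacks (multi-page 16-bit TIFF + JSON metadata
  sidecar) and elliptical ROI sets (CSV);
- **automatic ROI detection** on the β-spectrin membrane-guide channel:
  reference-wavelength selection → median denoising → Otsu binarization →
  morphological fibre extraction → sarcolemma location by dilation →
  tangent-aligned ellipse proposal → ranking by brightness, orientation and
  wall overlap → greedy selection of the best 26 non-overlapping ellipses
  per field (fully deterministic, blind to the dystrophin channel);
- **spectral quantification**: per-ROI mean emission spectra, selection of
  the shared maximum-emission-peak window, per-ROI peak intensities and
  biopsy summaries (mean ± SE over 3 fields × 26 = 78 ROIs);
- **statistics**: ICC(A,1) reproducibility with F-based confidence
  interval, Shapiro–Wilk, Kruskal–Wallis + pairwise Wilcoxon rank-sum group
  comparisons of raw ROI intensities, and the equal-variance two-sample
  *t*-test comparing manual and automatic quantification;
- a **synthetic muscle-field simulator** (weighted-Voronoi fibre packing,
  wall-confined Gaussian emission spectra on the real wavelength grids,
  shot + readout noise, 12-bit quantization, vessel/adipose/connective
  confounders, oracle "manual" ROIs) so the whole pipeline is verifiable
  against known ground truth without patient data.

For an ROI with pixel set *P*, the spectral signature is
*S(λₖ) = mean over P of I(x, y, λₖ)*; the study's single value per ROI is
*S(λ\*)* with *λ\* = argmaxₖ mean spectral signature* over the biopsy's 78
ROIs. Candidate ellipses are ranked by
*score = w_b·brightness + w_o·|cos(θ − tangent)| + w_w·overlap*, default
weights (⅓, ⅓, ⅓). The methods vignette
(`vignettes/dysquant-methods.Rmd`) documents every stage, parameter and
modelling choice.

## Worked example

```r
library(dysquant)

field <- simulate_field("DMD", seed = 42)   # one 512x512 two-channel field
field
#> <synthetic_field> 512x512 px, 30 fibres, antibodies: NCL-Dys1, seed 1228985497

rois <- detect_rois(field$beta_stack, field_id = "demo")
rois
#> <roi_set> field 'demo': 26/26 ROIs

fq <- quantify_field(field$dys_stack, rois)
fq
#> <field_quant> field 'demo': 26 ROIs, peak 516.26 nm, mean 488.9 a.u.

detection_percentage(15, 2982.9)
#> [1] 0.5
```

The field is simulated at the published DMD NCL-Dys1 level (500.8 a.u. true
sarcolemma peak intensity). Detection finds 26 membrane ellipses using only
the β-spectrin channel; quantification picks the emission window nearest
the AF488-like 519 nm peak (516.26 nm here, one 5.21 nm step's ambiguity is
expected with 26 noisy spectra) and recovers a mean of 488.9 a.u. — within
one between-ROI standard error of the generating truth. The last line is
the worked residual-signal case: a 15 a.u. trace is 0.5% of the 2982.9 a.u.
control mean.

Whole cohorts run the same way, in memory or from disk:

```r
res <- quantify_cohort(cohort_spec(), seed = 1)     # 10 DMD / 3 BMD / 6 control
cohort_statistics(res)                              # KW + Wilcoxon, manual-vs-auto t-test

# or on disk, via the CLI (inst/cli/dysquant):
#   dysquant simulate --config cohort.yaml --seed 1 --out sim/
#   dysquant quantify --in sim/ --rois auto   --out res/auto
#   dysquant quantify --in sim/ --rois oracle --out res/oracle
#   dysquant report   --in res/ --out report/
```

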