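---
title: "Measuring the diversity of chromatin compartments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the diversity of chromatin compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdiv)
```

## The measurement model

`chromdiv` works on images of isolated, Feulgen-stained cancer cell nuclei.
Feulgen–Schiff staining is stoichiometric for DNA, so after background
correction the optical density (OD) of a pixel is proportional to the local
DNA content; the package stores OD on a 10-bit scale (0–1023) with a binary
nuclear mask whose interior holes are filled on load. The biological object
of interest is the *chromatin compartment*: a contiguous region of
relatively highly condensed (dark, heterochromatin-like) or relatively
weakly condensed (bright, euchromatin-like) chromatin. The marker rests on
the hypothesis that nuclei whose compartments are numerous and diverse in
size and density indicate aggressive disease.

### Pixel labelling

Each nuclear pixel is classified against the OD statistics of its
neighbourhood, a two-sided generalisation of Niblack's adaptive threshold.
With `mean` and population `sd` computed over the in-mask pixels of a
square window, a pixel is dark when `OD > mean + k*max(sd, sigma_min)`,
bright when `OD < mean - k*max(sd, sigma_min)`, grey otherwise. The grey
class is essential: it separates condensed and decondensed compartments
from the *average local* OD rather than from each other, so the rule adapts
to staining intensity (the labelling is exactly invariant under adding a
constant to all ODs) and to local contrast.

Tunable parameters, with defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `window_radius` | 4 (9×9 window) | px | ≈1.5 µm at 165 nm/px, the optical depth of field and the compartment scale |
| `k` | 0.5 | – | sd multiplier; smaller values label more pixels |
| `sigma_min` | 2.0 | OD (10-bit) | floor on the local sd; suppresses noise-driven labels in flat regions, the classic Niblack failure |
| `min_mask_fraction` | 0.5 | – | pixels whose window has less in-mask support are forced grey |
| `g_min` | 4.0 | OD/px | minimal mean boundary Sobel gradient for a region to survive validation |
| `min_region_size` | 3 | px | speckle suppression |

The exact local rule and validation metric used in the original clinical
work were not published in full; the two-sided symmetric threshold and the
boundary-gradient validation below are this package's own concrete
choices, kept behind narrow function surfaces (`label_pixels`,
`validate_regions`) so either can be swapped without touching the rest of
the pipeline.

### Region validation

Candidate 8-connected dark/bright regions are validated by edge support,
in the spirit of Yanowitz and Bruckstein's ghost-removal step: a region is
kept only if the mean 3×3 Sobel gradient magnitude over its boundary
pixels reaches `g_min` and it has at least `min_region_size` pixels;
otherwise it is relabelled grey. The gradient is computed on a mask-aware
OD image in which out-of-mask pixels are replaced by the local in-mask
mean, so the nuclear boundary itself does not generate spurious edge
support. Validation can only remove labels, never create them.

### Entropy sums and the DESH

Per nucleus and compartment class, two histograms are formed: compartment
sizes on 32 log-spaced bins over 1–2048 px (sizes span orders of magnitude
within nuclei of a few thousand pixels, and log bins keep small and large
compartments comparable), and within-compartment pixel ODs on 64 linear
bins over 0–1023. The nucleus' diversity value is the sum of the two
Shannon entropies (bits). Base 2 is a convention; any fixed base rescales
all features equally and is absorbed by training. The OD histogram counts
*pixels*, not per-compartment means, reading "densities within
compartments" as the pixel-level distribution.

Per patient and class, the entropy sums of all nuclei form the *dual
entropy sum histogram* (DESH). The quantisation is adaptive:
equal-frequency (percentile) edges with `Q = 40` bins fitted on the pooled
training sums, so every bin is populated in training; duplicate edges
collapse, and test values outside the training range are clipped into the
end bins. Equal-frequency quantisation is the standard adaptive scalar
quantiser; the exact scheme of the original work was unpublished, so `Q`,
bin counts and spacing are all exposed as configuration.

### Adaptive features and the classifier

DESH bins are scored by outcome contrast on the training cohort,
`w_b = (p̄_poor(b) − p̄_good(b)) / (p̄_poor(b) + p̄_good(b) + 1e-12)`,
a bounded ratio in [−1, 1]; the patient feature is the weighted sum
`F = Σ p_b w_b`. This is the simplest bounded member of the
adaptive-texture-feature family in which histogram cells are weighted by
their association with outcome; the weighting function is deliberately
isolated in `fit_bin_weights` as a plug point, since the published
description does not pin down the exact variant. Weights are antisymmetric
under swapping the outcome labels, and the classifier call flips
accordingly.

The two features feed an equal-prior Gaussian classifier with common
covariance (pooled with Bessel weights; a trace-scaled ridge
`λ = 1e-6·tr(Σ)/2` is added only if the condition number exceeds 1e8,
with an absolute floor for fully degenerate 2×2 cases). The decision
boundary is a line; the tie `g = 0` is called DCC, the clinically
conservative side (flags risk), and is measure-zero in practice.

## Survival evaluation

Classification accuracy is summarised by the balanced correct
classification rate (BCCR, the mean of sensitivity and specificity), which
is insensitive to outcome-class imbalance, alongside the ordinary CCR.
Outcome dichotomisation is cancer-type specific: for ovarian carcinoma,
poor = recurrence or cancer-specific death within ten years, good = ten
event-free years, and patients censored earlier are `unknown` — excluded
from classification metrics (the dichotomy is undefined for them) but kept
in survival analyses, which need no dichotomisation. For endometrial
carcinoma, poor = cancer-specific death, everything else good.

Kaplan–Meier curves use Greenwood variances with log(−log) 95% intervals;
group comparisons use the log-rank test; hazard ratios come from Cox
proportional-hazards models with Efron tie handling (the least biased
default for moderate ties) and Wald tests at z = 1.96. The Cox fit
delegates to the `survival` package; the contract (Efron ties, Wald
intervals) is what the tests pin down, including a closed-form three-record
example solved by hand from the score equation. Named covariate presets
encode the multivariable models: FIGO substage (IB/IC vs IA) and
histological grade for ovarian; age (continuous) and pathological risk
class (HPR vs LPR) for endometrial. Records missing any variable of an
analysis are excluded from that analysis. Finally, `integrate_risk`
combines the marker with the pathological risk classification into three
groups (low = SCC∧LPR, high = DCC∧HPR, medium otherwise).

## The synthetic cohort generator

Because the clinical cohorts are access-restricted, the package ships a
generator that emulates the relevant features of the real material:
elliptical 72×58 px nuclei (≈3300 px, near the reported median nuclear
area), OD background noise, and irregular compartments grown by stochastic
8-neighbour accretion from separated seed points — irregular shapes
deliberately exercise the boundary-gradient validation. Survival times are
exponential with class-specific hazards and administrative censoring, so
the true hazard ratio is known exactly for recovery tests; the defaults
(0.075/yr vs 0.018/yr, 12-year horizon) give 10-year event-free survival
near 47% and 84%, echoing the scale reported for DCC and SCC patients.

Three presets define the study conditions:

* **separated** — the poor class has more compartments per nucleus
  (Poisson means 11 dark / 8 bright vs 5 / 4), a wider size distribution
  (log-normal sdlog 0.7 vs 0.25 around larger means) and larger
  within-compartment OD dispersion (sd 12 vs 3). These differences follow
  the observation that poor outcome associates with more and larger
  compartments; the magnitudes were chosen once to represent a clearly
  separable cohort.
* **null** — identical parameters in both classes; any held-out accuracy
  above chance would indicate information leakage.
* **high_contrast** — few, small (9–12 px), widely separated compartments
  with OD offsets far above the noise floor, kept a window-radius away
  from the nuclear boundary. Under these conditions the segmentation is
  expected to recover every planted compartment exactly; the size cap
  matters because a compartment whose extent approaches the local window
  would raise the local mean enough to create contrast halos around
  itself (a known behaviour of window-relative thresholds), and the edge
  margin matters because windows truncated by the mask lose background
  support.

The outcome label of a simulated patient is its latent class; survival
times are drawn from the class hazard separately. The generator does *not*
model optics (PSF, shading), ploidy/DNA-index, nucleus-detection errors,
or between-patient staining variability. Passing the end-to-end tests
therefore shows that the pipeline recovers planted class structure of the
stated kind and finds nothing under the null — it does not certify
clinical performance on real material.

## Numerical choices and degenerate inputs

* Local statistics use integer OD values and cumulative-sum windows, so
  they are bit-identical to a direct per-pixel loop (all partial sums are
  exactly representable); the test suite asserts this equality.
* Population (divide-by-n) sd; windows truncate at the image edge; local
  statistics use only in-mask pixels.
* Empty histograms and single-count histograms have entropy 0; a patient
  with zero nuclei or an empty mask is an error, not a silent zero.
* Equal quantisation edges collapse (all-identical training sums give a
  single bin); DESH normalisation makes the marker invariant to
  duplicating nuclei.
* Component labelling is 8-connected (with 4-connected background for
  hole filling, the standard duality) and deterministically ordered
  row-major by first pixel, so retraining on identical input is
  byte-identical, including the serialised `marker.json`.

## Problem sizes used in the shipped checks

The end-to-end checks run 40+40 training and 40+40 held-out patients with
50 nuclei each on the separated preset (seed 42), and five null cohorts of
40+40 training / 100+100 held-out patients with 8 nuclei each. The null
check is asserted on the mean BCCR across the five cohorts: a single
cohort's chance-level BCCR has Monte Carlo sd ≈ 0.035, so per-cohort
assertions inside [0.40, 0.60] would occasionally fail for a correct
implementation, while the mean (sd ≈ 0.016) tests the same hypothesis. The
acceptance script uses slightly smaller cohorts (30+30 × 30 nuclei) and
three null cohorts, which keeps the Monte Carlo error of the reported
rates within a few percentage points.

## Known limitations

* The precise local-threshold generalisation, validation metric, histogram
  binning and bin-weighting of the original clinical marker were not fully
  published; this package's choices are principled substitutes, and all of
  them are configurable or isolated behind plug points.
* Compartments larger than the local window develop grey interiors and
  contrast halos — inherent to window-relative thresholds. At the default
  9×9 window this limits faithful single-region recovery to compartments
  of roughly ≤60 px; larger structures fragment (consistently between
  classes, so the marker remains usable, but per-compartment statistics
  are then window-dependent).
* Sub-pixel boundaries, 3-D structure and alternative diversity indices
  (Gini, Simpson) are out of scope.
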