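---
title: "Methods: compartment-restricted dsDNA focus counting and downstream radiation-response analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-restricted dsDNA focus counting and downstream radiation-response analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytofoci)
```

# Scope and model overview

`cytofoci` quantifies cytoplasmic double-stranded DNA (dsDNA) foci — the
trigger of cGAS–STING innate immune signaling after irradiation — from
three-channel fluorescence fields, and carries the counts through the
standard downstream analytics of a radiation-quality comparison:
linear dose–response fits with slope comparison, exponential-saturation
fits for fold-change endpoints, linear-quadratic (LQ) clonogenic survival
with relative biological effectiveness (RBE), `2^(-ddCt)` qPCR
quantification, differential-expression (DE) filtering of FPKM matrices,
and Z-score summaries.

Every stage is validated against a synthetic-data module that generates
images and assay tables with known ground truth. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic validation does and does not demonstrate.

# The imaging model

## Compartment rule

A candidate dsDNA signal is accepted as a *cytoplasmic focus* iff

1. its pixel area is at least `min_area` (default 5 px),
2. **no** pixel of it overlaps any nucleus label, and
3. its centroid lies inside a cytoplasm territory and at least 50 % of its
   pixels lie in that territory.

Choices worth making explicit:

* **Area, not diameter.** The 5-pixel cutoff is interpreted as a pixel
  *area* (the spot-counting plugin convention). A 5 px diameter would imply
  a ~20 px area and would reject most genuine foci at typical sampling.
* **Strict any-overlap nucleus rule.** Exposure optimized for the dim
  cytosolic signal saturates the nuclear dsDNA stain, so the nucleus appears
  as one enormous bright component. Any pixel of overlap with a nucleus
  label disqualifies a component; this guarantees the saturated blob (and
  anything bridging into it) can never inflate cytoplasmic counts.
* **Partial-boundary adjudication.** A component straddling the territory
  edge is accepted when its centroid is inside and at least half its pixels
  are; the rejection reasons `too_small`, `in_nucleus`, `outside_cytoplasm`
  and `unassigned` are applied in that order, so each rejected component
  carries one deterministic reason.

## Segmentation

Nucleus and cytoplasm masks are thresholded with a global Otsu threshold per
channel — both stains are strongly bimodal — overridable by an explicit
threshold. Nuclei are 8-connected components above `min_nucleus_area`
(default 50 px, removing debris). Touching nuclei are *not* split; border
and pathological cells are excluded from per-cell statistics instead of
guessing a split. Cell territories are a nearest-seed partition: each
nucleus seeds one region grown across the thresholded cytoplasm stain
(`EBImage::propagate`), so adjacent cells split their shared stained area
and no pixel is assigned twice. Nucleus pixels are excluded from the
returned cytoplasm mask; stained regions unreachable from any nucleus stay
unlabeled. Cells whose territory touches the image border are flagged and
excluded from counts by default (their cytoplasm is truncated).

## Detection threshold

Candidate signals are components of pixels above `median + k * MAD` of the
dsDNA channel (default `k = 5`). An Otsu threshold is deliberately *not*
used here: the saturated nuclei dominate the upper histogram mode and would
pull a bimodal threshold far above the dim cytosolic foci. The median/MAD
pair is robust to both the nuclei (a few percent of pixels) and the focus
pixels themselves. Connectivity is 8-connected everywhere (nuclei, foci),
stated once and used consistently; labels are renumbered in raster-scan
order so labeling is deterministic.

## Background correction

Focus counts of unirradiated cells are a biological background. Group means
are corrected by subtracting, within each radiation quality, that quality's
own 0 Gy mean. Corrected means may be negative and are reported as computed,
not clipped — clipping would bias low-dose estimates upward.

# The synthetic field generator

Cells are elliptical nuclei (default semi-axes 14 x 10 px) with a
cytoplasmic ring (default 12 px), placed without overlap by rejection
sampling (300 bounded retries, then an error naming the constraint). Foci
per cell are Poisson with mean `b + s_q * dose`; the 0 Gy background rate
`b` is a configurable modelling choice (default 1 focus/cell), not a
literature value. Planted foci are near-circular disks with areas drawn
uniformly from `focus_area` (default 3–12 px, so the 5 px cutoff is
exercised from both sides), rendered at `focus_intensity` (default 2000 on a
12-bit scale), blurred with a Gaussian PSF (`psf_sigma`, default 1 px), and
read out with additive Gaussian noise (`noise_sd`, default 50) on top of a
camera dark offset (`background_level`, default 100) so noise is not
clipped at zero. The nuclear area of the dsDNA channel is rendered at
`nuclear_saturation_level` (default 4095 = sensor maximum), emulating the
overexposed nuclear signal.

Three placement guards keep the ground truth meaningful under blur:
cytoplasmic plants keep a 2 px clearance from the territory edge and a 5 px
clearance from the nucleus (so a blurred focus neither leaves its
compartment nor bridges into the saturated nuclear blob), and plants are
mutually separated by at least 4 px so two plants never merge into one
connected component. A plant that cannot be placed in a crowded cell is
skipped and simply absent from the truth table.

Determinism: one integer seed plus the field index is mixed
(`mix_seed()`) into a per-field substream; identical `(params, dose,
index)` give bit-identical images and truth.

**What the generator does not emulate:** real point-spread functions and
confocal optics, Poisson shot noise, intensity inhomogeneity, touching or
overlapping cells, mitotic figures and micronuclei, and autofluorescence.
Passing the synthetic validation therefore demonstrates correctness of the
*rule set and its implementation*, not segmentation robustness on difficult
real images.

# Dose–response analytics

Fit observations are per-dose group means (matching the mean ± SD
presentation of per-cell counts), weighted by `1/SE^2` when standard errors
are present. The linear fit keeps a free intercept even after background
subtraction (a through-origin fit is available via `intercept = FALSE`).
Slopes of two qualities are compared by
`t = (s_A - s_B)/sqrt(SE_A^2 + SE_B^2)` with Welch–Satterthwaite degrees of
freedom from the two slope variances — the conservative choice when the two
fits have different residual variances.

Fold-change endpoints that saturate are fit by the exponential-saturation
form `y(D) = P - (P - 1) exp(-k D)`. The baseline is fixed at `y(0) = 1`
because the fold change of the unirradiated control is 1 by definition;
`P` is the plateau fold change and `k` (1/Gy) the approach rate. Starting
values are `P = max(response)`, `k = 1/max(dose)`, with up to 8 jittered
restarts of the Levenberg–Marquardt optimizer; a flat series at 1 is
returned as a flagged degenerate fit (`P = 1`, `k` unidentifiable) rather
than an error. Two groups are compared by the extra-sum-of-squares F-test
between the pooled (shared `P, k`) and separate fits.

# Survival and RBE

Plating efficiency is the mean colonies/seeded fraction of the 0 Gy flasks,
per quality; each flask's surviving fraction is normalized within its
experiment. The LQ model is fit as least squares of
`ln SF = -(alpha D + beta D^2)` with both coefficients constrained
non-negative; the two-parameter non-negative problem is solved exactly by
active-set enumeration (unconstrained fit if feasible, else the best
single-parameter boundary fit), so `beta` lands exactly at 0 for purely
exponential data instead of going negative.

Two standard errors are reported per dose: the empirical between-flask SE
and the binomial counting error of the pooled colony count. The fit weights
use the counting error: with triplicate flasks the empirical variance has
only 2 degrees of freedom and makes notoriously unstable weights, while the
counting error is the known sampling variance of a colony count.
Zero-colony flasks cannot enter the log fit and are excluded with a logged
warning.

The iso-survival dose is the positive root of
`beta D^2 + alpha D + ln(level) = 0` (linear closed form when `beta = 0`),
and `RBE = D_reference / D_test` at that level (0.10 by default). The
package makes no claim about any specific cell line's RBE; the demo
parameter sets (X-ray-like alpha 0.3/Gy, beta 0.03/Gy²; carbon-like alpha
0.75/Gy, beta 0.04/Gy², a reduced shoulder as expected at high LET) give a
closed-form RBE near 1.9, and the validation checks that the pipeline
recovers whatever the generating parameters imply.

# Expression analytics

**ddCt.** Technical replicates are averaged per (condition, gene); then
`dCt = Cq(target) - geomean(Cq(ref1), Cq(ref2))` per condition,
`ddCt = dCt(condition) - dCt(control)`, fold change `2^(-ddCt)`. The
geometric mean is taken over the two reference genes' mean *Cq values*,
following the stated assay convention; the alternative arithmetic mean of
Cq (equivalent to a geometric mean on the expression scale) is available via
`reference_mean = "arithmetic"`. One subtlety: adding a constant to every
Cq leaves fold changes exactly unchanged under the geometric convention
only when the reference Cqs are stable across conditions (the shift terms
then cancel); with condition-dependent reference Cqs the geometric
convention is shift-invariant only approximately (order 1e-3 per cycle of
imbalance), while the arithmetic convention is exactly invariant. The
reference-stability report (SD of mean Cq across conditions, flag above
0.5 cycles by default) is a descriptive convention, not a reconstruction of
any published stability algorithm.

**DE filter.** Cutoffs are inclusive, mirroring how the thresholds are
written:
`FC >= 1.5` (either direction), `p <= 0.05`, mean FPKM `>= 0.5` in at least
one group. Fold change is the ratio of raw group means; the p-value is an
unpaired two-tailed Welch t-test on `log2(FPKM + 0.1)` (pseudocount
configurable) — the upstream vendor pipeline's exact test is unspecified, so
this declared convention is used. No multiple-testing correction enters the
DE flag — the rule set is defined on raw p-values — and a Benjamini–Hochberg
FDR column is emitted alongside for transparency.

**Z-scores.** Per gene across conditions, `(x - mean)/SD`; constant rows
are returned as zeros with a flag instead of NaN.

# Validation design and problem sizes

The test suite validates each stage against independent oracles: hand
calculations (the mixed-reference ddCt example, the Welch t formula, the
quadratic iso-survival root), closed forms (LQ survival probabilities,
noise-free round trips), brute-force re-implementations (the DE gene loop),
and seeded Monte-Carlo recovery against generator truth. Scales were chosen
to make the checks statistically meaningful while keeping the suite quick:
20 synthetic fields of 10 cells for focus-calling exactness; 20 fields of
5 cells for detection precision/recall; 6 doses x 200 cells/dose with 200
power replicates and 1000 null replicates for the slope comparison; 200
replicates of triplicate clonogenic experiments (1000 cells seeded per
flask, dose grids bracketing each quality's 10 % survival dose) for RBE
recovery; a 50-gene, 2 x 3 sample matrix for the DE oracle.

# Known limitations

* Segmentation assumes well-separated cells with one nucleus each; touching
  nuclei are merged, and no machine-learned or 3-D segmentation is offered.
* The detection threshold is global per field; strong illumination
  gradients would require a local background model.
* The LQ fit is the plain linear-quadratic model; no repair-kinetics or
  low-dose hypersensitivity extensions.
* qPCR quantification assumes perfect primer efficiency (a Pfaffl-style
  efficiency correction is out of scope).
* The DE filter reproduces a threshold rule set; it is not a replacement
  for count-based DE models when raw counts are available.
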