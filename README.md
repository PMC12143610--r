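# cytofoci

Radiation damages DNA; fragments of that DNA can end up in the cytoplasm,
where the cGAS–STING pathway senses them and triggers a type-I interferon
response. Comparing how efficiently different radiation qualities (sparsely
ionizing X-rays vs densely ionizing carbon ions) drive this pathway requires
a chain of quantitative steps: counting discrete cytoplasmic dsDNA foci per
cell in three-channel fluorescence images, fitting and comparing their dose
response, relating the radiation qualities through clonogenic survival and
relative biological effectiveness (RBE), and quantifying the downstream
transcriptional response by qPCR and RNA-seq filtering.

`cytofoci` implements that chain as a tidyverse-style R package for
radiobiologists and bioimage analysts, together with a seeded synthetic-data
module that generates ground-truthed images and assay tables, so every stage
can be validated end to end without external data.

## What the package computes

**Compartment-restricted focus calling.** Nuclei are segmented from the
DAPI-like channel (global Otsu threshold, 8-connected components);
per-cell cytoplasm territories are obtained by propagating each nucleus
across the thresholded phalloidin-like channel (nearest-seed partition).
Candidate dsDNA signals are connected components above a robust
`median + k·MAD` threshold (the deliberately overexposed nuclei would ruin a
bimodal threshold). A signal is counted as a cytoplasmic dsDNA focus iff

* its area is ≥ `min_area` pixels (default 5; area, not diameter),
* no pixel of it overlaps a nucleus label (strict — the saturated nuclear
  signal must never leak into the counts), and
* its centroid and ≥ 50 % of its pixels lie inside one cytoplasm territory.

Per-cell counts are background-corrected by subtracting each radiation
quality's own 0 Gy mean.

**Dose–response analytics.** Mean foci/cell vs dose is fit by weighted least
squares; qualities are compared with a t-test on the two slopes
(`t = (s_A − s_B)/√(SE_A² + SE_B²)`, Welch–Satterthwaite df). Fold-change
endpoints that saturate are fit by `y(D) = P − (P − 1)·e^(−kD)` with
`y(0) = 1` fixed, and trends are compared by an extra-sum-of-squares F-test.
Group layouts use the unpaired two-tailed Welch t-test or two-way ANOVA with
Tukey's multiple comparisons.

**Clonogenic survival and RBE.** Colony counts become surviving fractions
via the plating efficiency; `ln SF = −(αD + βD²)` is fit with α, β ≥ 0
(weights from binomial counting error); RBE at survival level `S` is the
ratio of the two qualities' iso-survival doses, with
`D(S) = (−α + √(α² − 4β ln S)) / (2β)`.

**Expression analytics.** Relative qPCR quantification by `2^(−ΔΔCt)`,
normalizing target Cq to the geometric mean of two reference genes (Gapdh,
Rpl13a by default) plus a descriptive reference-stability report; RNA-seq
differential-expression filtering with the inclusive criteria fold change
≥ 1.5 (either direction), p ≤ 0.05 (unpaired two-tailed t-test on
log2(FPKM + 0.1)), and mean FPKM ≥ 0.5 in at least one group; per-gene
Z-scores across conditions for heat maps.

**Synthetic ground truth.** `simulate_field()` renders elliptical nuclei
with cytoplasmic rings, plants Poisson-distributed foci whose mean follows
`b + s_q·dose`, saturates the nuclear dsDNA signal, and returns exact truth
(masks plus per-focus centroid/area/compartment records);
`simulate_survival_data()`, `simulate_cq_table()` and
`simulate_expression_matrix()` do the same for the assay tables. All
generators are bit-reproducible given a seed.

## Worked example

The demo experiment compares an X-ray-like quality (slope 0.1 foci/cell/Gy,
α = 0.3 /Gy, β = 0.03 /Gy²) with a carbon-like quality (slope 0.3
foci/cell/Gy, α = 0.75 /Gy, β = 0.04 /Gy²) on fully simulated data:

```r
library(cytofoci)
report <- run_pipeline(pipeline_config(seed = 42), out_dir = "demo-out")
report
#> <run_report> seed 42
#>   imaging: 120 cells across 24 fields
#>   slopes: carbon - xray = 0.191 foci/cell/Gy (p = 0.00526, significant)
#>   RBE(xray/carbon) at 10% survival: 1.90
#>   expression: 10 DE genes; 2 qPCR fold changes
#>   warnings: 1
```

The slope difference of 0.191 foci/cell/Gy recovers the planted difference
of 0.2 and is flagged significant; the RBE of 1.90 matches the closed-form
iso-survival dose ratio of the generating LQ parameters (1.894); the DE
filter recovers the 10 planted differentially expressed genes. The one
warning reports zero-colony flasks at the highest carbon dose, which are
excluded from the log-space LQ fit.

Individual stages compose the same way:

```r
sim <- simulate_field(imaging_truth_params(seed = 1), dose = 8,
                      quality = "carbon")
counts <- count_field_foci(sim$field)          # per-cell foci counts

sf  <- surviving_fractions(simulate_survival_data(survival_truth_params()))
fit <- fit_lq(sf$summary)
tidy(fit)
#> # A tibble: 2 × 3
#>   term  estimate std_error
#>   <chr>    <dbl>     <dbl>
#> 1 alpha   0.264    0.0233
#> 2 beta    0.0367   0.00547
dose_at_survival(fit, 0.1)                     # iso-survival dose in Gy
```

Fitted objects have `tidy()`, `glance()` and `autoplot()` methods;
`plot_foci_dose_response()` and `plot_zscore_heatmap()` cover the two main
figure types.

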