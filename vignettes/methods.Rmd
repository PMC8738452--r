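---
title: "Methods: quantifying single-cell reporter assays with hcreporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying single-cell reporter assays with hcreporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(hcreporter)
```

# The measurement problem

Transcriptional reporter assays read out pathway activation as a
fluorescent signal. Measured per well, the readout confounds two distinct
biological modes: a **digital** response, where stimulation switches more
cells from "off" to "on", and an **analogue** response, where each
responding cell produces more reporter per cell. Two treatments with the
same well-level fold change can act through entirely different modes, and
receptor co-stimulation experiments in particular hinge on which mode the
second receptor engages. hcreporter implements the full analysis chain:

1. a seeded synthetic-data generator with ground truth at every level
   (per-cell tables, rendered two-channel images with label maps, and
   differential-expression tables with planted temporal classes);
2. single-cell detection in two-channel images, where a constitutive red
   channel marks transfected cells and a green channel carries the
   reporter;
3. the digital/analogue decomposition of population responses;
4. four-parameter Hill dose–response fitting with bootstrap confidence
   intervals and EC50-shift comparison;
5. a resampling synergy test against the additive null;
6. a two-caller consensus filter for differential-expression tables with
   temporal gene classification and combined-versus-single-stimulus gene
   accounting.

# The generative model

`stimulus_model()` specifies both modes with Hill functions of dose: the
probability that a transfected cell responds rises from `p0` to `pmax`
(digital arm), and the mean green intensity of a responding cell rises
from `gain0` to `gainmax` (analogue arm). A `synergy_factor` multiplies
the responder probability under co-stimulation (capped at 1, with a flag
when the cap binds). Non-responders emit `nonresponder_green` (default 0,
i.e. truly dark). Defaults (`p0 = 0.02`, `pmax = 0.8`, gains 2000–8000
on a 16-bit scale) give realistic dynamic range without saturating the
camera.

`simulate_cell_table()` draws cells in a documented order (transfection
flag, position, radius, red intensity, responder switch, green noise) so
that seeds are reproducible and partial comparisons across parameter
changes stay aligned. `render_image_pair()` rasterises a cell table into
16-bit red/green images plus an integer ground-truth label map; when
cells are allowed to overlap, contested pixels go to the first-drawn
cell and the pair is flagged. Images round-trip through multi-page TIFF
(`write_image_pair()` / `read_image_pair()`).

Realism and limits: cells are discs with uniform interior intensity plus
Gaussian (or lognormal) noise — no shading, no texture, no out-of-focus
light. That is deliberate: the generator's job is to provide *exact*
ground truth for validating the measurement code, not to imitate
microscope physics. Effects the simplification hides (segmentation bias
on irregular shapes, flat-field error) must be assessed on real data.

# Cell detection

`segment_cells()` runs the classical high-content pipeline:

- **Rolling-ball background subtraction**, implemented as grayscale
  opening with a disc structuring element. The erosion/dilation use a
  row-decomposed running-extremum scan with replicate padding, so the
  cost is linear in pixels per disc row rather than quadratic in radius.
- **Global thresholding** at `background_level + threshold_delta`.
- **8-connected component labeling.** Built on `igraph` components
  because the common 4-connected labeling splits diagonally touching
  blobs inconsistently with how humans gate them.
- **Size and circularity gating.** Circularity is `4πA/P²` capped at 1,
  with the perimeter measured as the length of the 0.5-level isocontour
  of the object indicator (`grDevices::contourLines`). On a digital
  grid, naive boundary-pixel counts make even perfect discs fail a 0.8
  circularity gate; the isocontour length gives discs ≈ 0.97–1.0 while
  merged doublets still fall below 0.8. Rejected objects are kept in a
  `rejects` attribute with reasons, because gate tuning is a judgement
  call the analyst must be able to audit.

Green is then measured strictly through the red-derived masks
(`measure_green()`): the reporter channel never influences which pixels
belong to a cell, which avoids selection bias toward bright responders.
`make_region_masks()` derives membrane, perinuclear and nuclear
sub-masks from the label map for region-ratio readouts
(`region_ratio()`), e.g. membrane-to-cytoplasm receptor translocation.

# Digital/analogue decomposition

For a well, `summarize_well()` records the fraction of transfected cells
above a responder threshold (`responder_threshold()` defaults to
mean + 3 SD of control green) and the mean green among responders.
`decompose()` then reports, for treated versus control:

- `delta_digital_pct`: percent change in responder fraction;
- `delta_analogue_pct`: percent change in per-responder intensity;
- `delta_overall_pct`: percent change in mean green over all transfected
  cells;
- contribution shares on the percent-change scale,
  `contribution_digital = Δd / (Δd + Δa)`, plus a log-scale variant
  `log(fold_d) / log(fold_overall)` which is exact under the
  multiplicative identity.

When non-responders are truly dark, the overall fold change factorises
exactly: `fold_overall = fold_digital × fold_analogue`. The
`identity_residual` reports the relative violation of this identity; it
is ~1e-16 on dark-non-responder simulations and grows monotonically with
non-responder brightness, so it doubles as a data-quality diagnostic.
The canonical worked example — responder fraction tripled (+200%),
per-cell intensity doubled (+100%) — yields a digital contribution of
2/3:

```{r decompose-example}
ctrl <- list(fraction_responding = 0.1, mean_green_responders = 100,
             mean_green_transfected = 10)
trt <- list(fraction_responding = 0.3, mean_green_responders = 200,
            mean_green_transfected = 60)
decompose(trt, ctrl)
```

Degenerate cases (de novo activation from a zero control fraction, no
responders in the treated well, mixed-sign deltas) are flagged rather
than silently producing shares outside [0, 1].

# Hill fitting and EC50 shifts

`fit_hill()` fits `e0 + (emax − e0) · d^h / (EC50^h + d^h)` with EC50
parameterised as log10(EC50), which makes the bootstrap distribution of
potency roughly symmetric and keeps EC50 positive by construction. The
optimiser is `minpack.lm::nlsLM` with box constraints
(log10 EC50 ∈ [−12, 12], slope ∈ [0.05, 20]) over a multistart grid;
starts are tried in order of their raw sum of squares and the search
stops as soon as a converged fit beats the best remaining start's raw
SSE, which recovers noise-free curves to ≤ 1e-6 while keeping a
200-bootstrap fit under a second. A Nelder–Mead fallback handles
pathological inputs but is flagged non-converged. Flat curves are
flagged `ec50_unidentifiable`; EC50 estimates outside the tested dose
range are flagged `ec50_outside_range` rather than rejected.

Confidence intervals are percentile intervals from a case bootstrap
stratified by dose (so the design is preserved in every resample). On a
48-point design with 10% noise, simulated coverage of the 95% interval
for log10 EC50 is ≈ 0.91 — slightly conservative-of-nominal behaviour
typical of percentile intervals at this n, and comfortably calibrated
for screening use. `compare_ec50()` differences the paired bootstrap
draws of two fits to give a shift estimate, interval, and an
add-one-corrected two-sided p-value (identical fits give p = 1 exactly).

```{r hill-example}
doses <- rep(c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30), each = 6)
set.seed(7)
y <- hill_response(doses, 0, 1, ec50 = 1, hill = 1) + rnorm(length(doses), 0, 0.08)
fit <- fit_hill(doses, y, n_boot = 200, seed = 7)
summary(fit)
plot(fit)
```

# Synergy as excess over additivity

`test_synergy()` takes replicate responses for control, each single
stimulus, and the combination, and tests whether the combined effect
exceeds the *sum* of single effects (each relative to control):
`excess = mean(AB) − mean(A) − mean(B) + mean(control)`. The statistic
is studentised by a delta-method standard error. The null distribution
comes from a stratified bootstrap after recentring every arm to its own
mean (imposing additivity exactly), and the null draws are symmetrised
(`t` and `−t` pooled). Symmetrisation guarantees p ≥ 0.5 for exactly
additive data and, in simulation at n = 18 replicates, holds the 5%
one-sided size within [0.02, 0.08] while retaining ≥ 80% power against
an excess of three pooled standard errors. The seed argument is
mandatory: a resampling p-value that silently changes between runs is a
reproducibility bug, not a convenience. `bliss_excess()` is provided
separately for probability-scale readouts, since additive-excess and
Bliss independence are different nulls and should never be conflated.

# Differential-expression consensus

`apply_consensus_filter()` implements a deliberately strict two-caller
rule: a gene is kept only if **both** callers give FDR ≤ 0.01, the two
log2 fold changes agree in sign, the consensus (mean) |log2FC| is at
least log2(1.5), and the mean FPM exceeds 5 **on the relevant side** —
the treated side for up-regulated genes, the control side for
down-regulated ones (a gene silenced from a high baseline should not be
discarded because its treated expression is low). Sign-discordant genes
are returned in a `discordant` attribute for audit. The implementation
is validated against an independent gene-by-gene brute-force oracle and
checked for threshold monotonicity and caller-order symmetry.

`classify_temporal()` assigns genes passing the filter at 6 h and/or
24 h to `early_transient`, `late_onset`, `prolonged` (same sign at both
times) or `biphasic` (sign flip), and reports the 6 h/24 h overlap with
the 24 h set as denominator. `synergy_gene_accounting()` splits
combined-stimulation genes into *recruited* (significant only under
co-stimulation) versus *enhanced* (overlap), and quantifies enhancement
as the zero-intercept regression slope of combined on single-stimulus
log2 fold changes, with a gene-level bootstrap interval; the
zero-intercept form is the right model because a gene with no single
response and no combined response must sit at the origin.
`biotype_partition()` reports the protein-coding / lncRNA / other split
of any gene set.

# Validation strategy and problem sizes

Every module is tested against ground truth the generator plants, never
against values the implementation itself produced: detection must find
exactly the planted cells (precision = recall = 1 on in-gate, noise-free
images, centroids within 1 px); the decomposition must reproduce the
2/3 worked example and the multiplicative identity to ≤ 1e-12 over 50
seeded wells; Hill fits must recover log10 EC50 with median error < 0.1
across a 3 × 3 × 3 parameter grid with ≥ 85% bootstrap-CI coverage;
the synergy test is calibrated over 1000 null repeats and powered over
200 alternative repeats; the consensus filter must match the
brute-force oracle exactly on 5000 genes; temporal classes must be
recovered without error at zero caller noise; and the planted
enhancement slope of 1.4 must fall inside its bootstrap interval.
`scripts/acceptance.R` re-runs this battery end to end against the
installed package at any seed and writes the quantities as JSON.

# Design decisions

- **Pipeline of composable functions, not one monolithic fit.** The
  stages consume each other's outputs (tables → summaries →
  decompositions → tests) and are independently testable; model-like
  stages (`fit_hill`, `test_synergy`, `compare_ec50`, decompositions)
  return classed S3 objects with `print`/`summary`/`predict` methods.
- **Functions + vignette as the interface, no command-line wrapper.**
  Every entry point is seeded and scriptable; a CLI would only wrap
  argument parsing around the same calls.
- **Hand-rolled grayscale morphology and labeling.** Available image
  libraries offered 4-connected labeling and binary-only opening;
  correctness of the 8-connected, grayscale variants mattered more than
  reusing them, and both are validated against brute-force references
  in the tests.
- **Percent-change contribution shares by default**, because that is the
  scale on which the worked example and most assay reporting operate;
  the log-scale share is also returned for users who prefer exact
  multiplicative attribution.
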