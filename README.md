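# hcreporter

Single-cell quantification of fluorescence reporter assays, with a
digital/analogue decomposition of population responses, Hill
dose–response fitting, a resampling synergy test, and a two-caller
consensus filter for differential-expression tables. A seeded
synthetic-data generator provides ground truth at every level so each
stage can be validated against known answers.

## The problem

A well-level reporter readout confounds two biological modes: more
cells switching on (**digital**) versus each responding cell making more
reporter (**analogue**). Two treatments with identical well-level fold
changes can act through opposite modes, and co-stimulation experiments
hinge on which mode a second receptor engages. hcreporter measures
single cells in two-channel images (a constitutive red transfection
marker defines the cells; the green reporter is measured strictly
through red-derived masks), splits the population response into the two
modes with contribution shares, and carries the analysis through
dose–response, synergy, and transcriptome-level consensus calls.

## Worked example

Simulate a control and a treated well from a known stimulus model, set
the responder threshold from the control population, and decompose the
response:

```r
library(hcreporter)

model <- stimulus_model(p0 = 0.05, pmax = 0.8, ec50_digital = 1,
                        gain0 = 3000, gainmax = 12000, ec50_analogue = 1)
cfg <- sim_config(n_cells_per_well = 2000, rng_seed = 42)
control <- simulate_cell_table(cfg, model, dose = 0,  seed = 42)
treated <- simulate_cell_table(cfg, model, dose = 10, seed = 43)

thr <- responder_threshold(control)
decompose(summarize_well(treated, thr, condition = "agonist 10 uM"),
          summarize_well(control, thr, condition = "vehicle"))
#> response decomposition (percent change vs control)
#>   digital   +1763.3%
#>   analogue   +273.4%
#>   overall   +6800.7%
#>   contributions: digital 0.866, analogue 0.134 (log-share 0.689)
#>   multiplicative-identity residual: 0.00821
```

The response here is dominantly digital: most of the gain comes from
recruiting new responding cells, not from brighter cells. The identity
residual checks the factorisation `fold_overall = fold_digital ×
fold_analogue`, which is exact when non-responders are dark.

The same tables can be rendered as 16-bit images and re-measured from
pixels:

```r
img <- render_image_pair(control, cfg)
cells <- segment_cells(img$red + 0, detection_params(threshold_delta = 1000))
cells <- measure_green(cells, img$green + 0)
```

Dose–response and synergy:

```r
fit <- fit_hill(doses, responses, n_boot = 200, seed = 1)
summary(fit)                      # EC50 with bootstrap CI, flags
compare_ec50(fit, fit_costim)     # potency shift, CI, p-value

test_synergy(control_wells, a_wells, b_wells, ab_wells,
             n_resamples = 2000, seed = 1)   # excess over additivity
```

DE consensus (both callers FDR ≤ 0.01, sign-concordant, |mean log2FC| ≥
log2(1.5), FPM > 5 on the relevant side):

```r
kept6  <- apply_consensus_filter(tables, contrast = "6h")
kept24 <- apply_consensus_filter(tables, contrast = "24h")
classify_temporal(kept6, kept24)  # early_transient / late_onset / prolonged / biphasic
synergy_gene_accounting(set_a, set_b, set_ab, n_boot = 200, seed = 1)
```

See `vignettes/methods.Rmd` for the model, numerical choices, and
validation strategy.

## Tests

```r
# from the package root, against the installed package
testthat::test_dir("tests/testthat", package = "hcreporter",
                   load_package = "installed")
```

The suite validates every stage against planted ground truth, including
a brute-force oracle for the consensus filter, calibration/power checks
for the synergy test, and bootstrap-coverage checks for the Hill fits.

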