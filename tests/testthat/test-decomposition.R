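sum_fix <- function(f, a, o) {
  list(fraction_responding = f, mean_green_responders = a,
       mean_green_transfected = o)
}

test_that("percent-change decomposition reproduces the worked contribution rule", {
  # digital +200%, analogue +100% -> digital contributes 2/3
  d <- decompose(sum_fix(0.3, 200, 60), sum_fix(0.1, 100, 10))
  expect_equal(d$delta_digital_pct, 200)
  expect_equal(d$delta_analogue_pct, 100)
  expect_equal(d$contribution_digital, 2 / 3)
  expect_equal(d$contribution_analogue, 1 / 3)

  # single-component case: digital +100%, analogue 0
  d1 <- decompose(sum_fix(0.2, 100, 20), sum_fix(0.1, 100, 10))
  expect_equal(d1$contribution_digital, 1)
  expect_equal(d1$delta_overall_pct, 100)

  # treated = control: all deltas zero, contributions flagged undefined
  d0 <- decompose(sum_fix(0.1, 100, 10), sum_fix(0.1, 100, 10))
  expect_equal(d0$delta_overall_pct, 0)
  expect_true(is.na(d0$contribution_digital))
  expect_equal(d0$flag, "undefined")

  # opposite-sign components are flagged, not averaged
  dm <- decompose(sum_fix(0.2, 80, 16), sum_fix(0.1, 100, 10))
  expect_equal(dm$flag, "mixed-sign")
  expect_true(is.na(dm$contribution_digital))

  # no responders in the control well: de-novo activation
  dn <- decompose(sum_fix(0.2, 100, 20), sum_fix(0, NA, 5))
  expect_equal(dn$flag, "de-novo activation")
  expect_true(is.na(dn$contribution_digital))
})

test_that("multiplicative identity holds exactly with dark non-responders", {
  m <- stimulus_model(p0 = 0.1, pmax = 0.9, nonresponder_green = 0)
  ctrl <- well_summary_at(m, dose = 0, n = 5000, seed = 1)
  trt <- well_summary_at(m, dose = 3, n = 5000, seed = 2)
  d <- decompose(trt, ctrl)
  expect_lt(d$identity_residual, 1e-12)

  # a bright non-responder baseline breaks the identity measurably
  m2 <- stimulus_model(p0 = 0.1, pmax = 0.9, nonresponder_green = 500)
  ctrl2 <- well_summary_at(m2, dose = 0, n = 5000, seed = 1)
  trt2 <- well_summary_at(m2, dose = 3, n = 5000, seed = 2)
  expect_gt(decompose(trt2, ctrl2)$identity_residual,
            d$identity_residual)
})

test_that("deltas and contributions are invariant to intensity rescaling", {
  m <- stimulus_model(p0 = 0.1, pmax = 0.9)
  ctrl <- well_summary_at(m, dose = 0, n = 2000, seed = 4)
  trt <- well_summary_at(m, dose = 5, n = 2000, seed = 5)
  d <- decompose(trt, ctrl)
  scale_sum <- function(s, c) {
    s$mean_green_responders <- s$mean_green_responders * c
    s$mean_green_transfected <- s$mean_green_transfected * c
    s
  }
  d2 <- decompose(scale_sum(trt, 7.3), scale_sum(ctrl, 7.3))
  expect_equal(d2$delta_digital_pct, d$delta_digital_pct)
  expect_equal(d2$delta_analogue_pct, d$delta_analogue_pct)
  expect_equal(d2$delta_overall_pct, d$delta_overall_pct)
  expect_equal(d2$contribution_digital, d$contribution_digital)
})

test_that("well summaries recover the planted responder fraction", {
  m <- stimulus_model(p0 = 0, pmax = 0.6, nonresponder_green = 0,
                      gain0 = 5000, gainmax = 8000)
  cfg <- sim_config(n_cells_per_well = 10000, noise_sd = 50,
                    transfection_fraction = 0.5, rng_seed = 8)
  tab <- simulate_cell_table(cfg, m, dose = 1)   # p = 0.3, separable
  ws <- summarize_well(tab, threshold = 1000)
  expect_lt(abs(ws$fraction_responding - 0.3),
            3 * sqrt(0.3 * 0.7 / ws$n_transfected))
  expect_lte(ws$n_responding, ws$n_transfected)

  # all below threshold -> fraction 0
  ws0 <- summarize_well(tab, threshold = 1e9)
  expect_equal(ws0$fraction_responding, 0)

  # nothing transfected -> error
  tab$truth_transfected <- FALSE
  expect_error(summarize_well(tab, 1000), "transfected")
})

test_that("responder threshold rule uses control mean + k SD", {
  cells <- data.frame(green_mean = c(10, 20, 30),
                      truth_transfected = TRUE)
  expect_equal(responder_threshold(cells), 20 + 3 * 10)
  expect_equal(responder_threshold(cells, k = 2), 40)
})

test_that("time course: digital saturating earlier gives smaller t-half", {
  mk <- function(f, a) sum_fix(f, a, f * a)
  ctrl <- mk(0.1, 100)
  # digital saturates by 6 h, analogue keeps rising to 24 h
  s <- list(mk(0.28, 110), mk(0.30, 150), mk(0.30, 200))
  tc <- timecourse_decomposition(s, ctrl, times = c(3, 6, 24))
  th <- attr(tc, "t_half")
  expect_lt(th["digital"], th["analogue"])
  expect_equal(nrow(tc), 3)

  # monotone series gives monotone per-timepoint deltas
  expect_true(all(diff(tc$delta_analogue_pct) > 0))
  expect_true(all(diff(tc$delta_overall_pct) > 0))

  # constant component: undefined half-time
  sc <- list(mk(0.1, 100), mk(0.1, 100))
  tcc <- timecourse_decomposition(sc, ctrl, times = c(6, 24))
  expect_true(is.na(attr(tcc, "t_half")["digital"]))

  expect_error(timecourse_decomposition(list(ctrl), ctrl, times = 6),
               "2 timepoints")
})

test_that("contribution recovery across a generator grid (2% at n = 1e4)", {
  p0 <- 0.2
  g0 <- 1000
  for (pf in c(1.5, 2.5)) {
    for (gf in c(1.2, 1.4)) {
      # dose where the digital curve gives p = p0 * pf; then scale the
      # analogue curve so the gain fold at that dose is exactly gf
      f_dose <- uniroot(function(d)
        hill_response(d, p0, 1, 1, 1) / p0 - pf, c(1e-6, 1e3))$root
      frac <- hill_response(f_dose, 0, 1, 1, 1)
      gmax <- g0 + (gf - 1) * g0 / frac
      m <- stimulus_model(p0 = p0, pmax = 1, nonresponder_green = 0,
                          gain0 = g0, gainmax = gmax)
      cfg <- sim_config(n_cells_per_well = 10000, noise_sd = 0,
                        transfection_fraction = 0.5, rng_seed = 0)
      tc <- simulate_cell_table(cfg, m, 0, seed = 21)
      tt <- simulate_cell_table(cfg, m, f_dose, seed = 22)
      d <- decompose(summarize_well(tt, 900), summarize_well(tc, 900))

      # percent-change-rule contribution computed from the realised truth
      pf_real <- mean(tt$truth_responder[tt$truth_transfected]) /
        mean(tc$truth_responder[tc$truth_transfected])
      dd_true <- 100 * (pf_real - 1)
      da_true <- 100 * (gf - 1)
      expect_lt(abs(d$contribution_digital -
                      dd_true / (dd_true + da_true)), 0.02)
      # overall change equals the product of the component folds
      expect_lt(abs(d$delta_overall_pct - 100 * (pf_real * gf - 1)),
                1e-6)
      # and sits near the analytic 100 * (pf * gf - 1) at this n
      expect_lt(abs(d$delta_overall_pct - 100 * (pf * gf - 1)),
                0.15 * 100 * (pf * gf - 1))
    }
  }
})
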