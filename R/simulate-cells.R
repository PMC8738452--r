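#' Simulate a per-cell measurement table for one well
#'
#' Draws a synthetic well of the reporter assay with known ground truth.
#' Each cell is independently transfected with probability
#' `config$transfection_fraction`; each transfected cell flips its
#' responder switch with the digital Hill probability at `dose`
#' (times `synergy_factor` under `costim`, capped at 1); responders emit
#' green at the analogue Hill gain, non-responders at
#' `model$nonresponder_green`; measured intensities add noise per
#' `config$noise_model`. Untransfected cells never respond.
#'
#' Stochastic draws come from a single RNG seeded at entry, in a fixed
#' order: transfection flags, positions x then y, radii, red
#' intensities, responder switches, green noise. Identical arguments
#' therefore give bit-identical tables.
#'
#' @param config a [sim_config()].
#' @param model a [stimulus_model()].
#' @param dose non-negative stimulus concentration.
#' @param costim logical; co-stimulation condition?
#' @param well_id character label written into the table.
#' @param seed integer seed for this well; defaults to
#'   `config$rng_seed`.
#' @param avoid_overlap logical; if `TRUE`, cell centres are placed so
#'   that rendered disks cannot touch (rejection sampling on a jittered
#'   grid), which is what detection-fidelity tests need.
#' @return a `data.frame`, one row per cell, with columns `cell_id`,
#'   `well_id`, `dose`, `costim`, `x`, `y`, `radius_px`, `area_px`,
#'   `red_mean`, `red_integral`, `green_mean`, `green_integral`,
#'   `truth_transfected`, `truth_responder`. Coordinates are 0-based
#'   pixel positions, `x` = column, `y` = row.
#' @examples
#' cfg <- sim_config(n_cells_per_well = 50, noise_sd = 0)
#' tab <- simulate_cell_table(cfg, stimulus_model(), dose = 1)
#' table(tab$truth_transfected, tab$truth_responder)
#' @export
simulate_cell_table <- function(config, model, dose, costim = FALSE,
                                well_id = "W1", seed = config$rng_seed,
                                avoid_overlap = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(model, "stimulus_model"))
  if (length(dose) != 1 || dose < 0) stop("dose must be a single non-negative value")
  n <- config$n_cells_per_well
  if (n <= 0) stop("n_cells_per_well must be positive")
  set.seed(as.integer(seed))

  transfected <- runif(n) < config$transfection_fraction

  rmax <- config$radius_range[2]
  if (avoid_overlap) {
    pos <- .place_nonoverlapping(n, config$width, config$height, rmax)
    x <- pos$x; y <- pos$y
  } else {
    x <- runif(n, rmax, config$width - 1 - rmax)
    y <- runif(n, rmax, config$height - 1 - rmax)
  }
  radius <- runif(n, config$radius_range[1], config$radius_range[2])

  red_true <- ifelse(transfected,
                     rnorm(n, config$red_mean, config$red_sd),
                     config$red_untransfected +
                       rnorm(n, 0, config$red_sd / 10))
  red_true <- pmax(red_true, 0)

  p <- responder_probability(model, dose, costim)
  responder <- transfected & (runif(n) < as.numeric(p))
  gain <- responder_gain(model, dose, costim)
  green_true <- ifelse(responder, gain, model$nonresponder_green)

  green_meas <- switch(config$noise_model,
    normal = green_true + rnorm(n, 0, config$noise_sd),
    # lognormal: noise_sd is the log-scale SD (dimensionless)
    lognormal = green_true * rlnorm(n, 0, config$noise_sd)
  )

  area <- round(pi * radius^2)
  out <- data.frame(
    cell_id = paste0(well_id, "_c", seq_len(n)),
    well_id = well_id,
    dose = dose,
    costim = costim,
    x = x, y = y,
    radius_px = radius,
    area_px = area,
    red_mean = red_true,
    red_integral = red_true * area,
    green_mean = green_meas,
    green_integral = green_meas * area,
    truth_transfected = transfected,
    truth_responder = responder,
    stringsAsFactors = FALSE
  )
  attr(out, "responder_probability") <- as.numeric(p)
  attr(out, "responder_gain") <- gain
  out
}

# Jittered-grid placement guaranteeing >= 2 px gaps between disks of
# maximal radius; errors if the grid cannot hold n cells.
.place_nonoverlapping <- function(n, width, height, rmax) {
  pitch <- 2 * rmax + 3
  nx <- floor((width - 2 * rmax - 2) / pitch)
  ny <- floor((height - 2 * rmax - 2) / pitch)
  if (nx * ny < n)
    stop("image too small for ", n, " non-overlapping cells")
  slots <- sample(nx * ny, n)
  ix <- (slots - 1) %% nx
  iy <- (slots - 1) %/% nx
  jx <- runif(n, -0.5, 0.5)
  jy <- runif(n, -0.5, 0.5)
  list(x = rmax + 1 + ix * pitch + pitch / 2 + jx,
       y = rmax + 1 + iy * pitch + pitch / 2 + jy)
}

#' Simulate all wells of a condition series
#'
#' Convenience wrapper looping [simulate_cell_table()] over the
#' configured doses and replicate wells. Per-well seeds are derived from
#' `config$rng_seed` by consecutive offsets so the whole plate is
#' reproducible from one integer.
#'
#' @inheritParams simulate_cell_table
#' @param doses dose series; defaults to `config$doses`.
#' @return a single `data.frame` of stacked well tables; wells are
#'   labelled `"d<dose index>_r<replicate>"` plus a costim suffix.
#' @export
simulate_plate <- function(config, model, costim = FALSE,
                           doses = config$doses) {
  tabs <- list()
  k <- 0L
  for (i in seq_along(doses)) {
    for (r in seq_len(config$n_replicate_wells)) {
      k <- k + 1L
      wid <- sprintf("d%02d_r%02d%s", i, r, if (costim) "_co" else "")
      tabs[[k]] <- simulate_cell_table(
        config, model, doses[i], costim = costim, well_id = wid,
        seed = (config$rng_seed + 7919L * k) %% .Machine$integer.max
      )
    }
  }
  do.call(rbind, tabs)
}
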