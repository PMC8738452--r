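#' Per-cell stimulus-response model for the synthetic reporter assay
#'
#' Describes how a single transfected reporter cell responds to a
#' stimulus dose. Activation has two components, mirroring how reporter
#' populations behave in high-content assays:
#' \describe{
#'   \item{digital}{a per-cell Bernoulli "responder" switch whose
#'     probability follows a Hill curve in dose, from `p0` (baseline
#'     fraction of spontaneously active cells) to `pmax`;}
#'   \item{analogue}{the green reporter intensity of a responding cell,
#'     a second Hill curve from `gain0` to `gainmax` (arbitrary
#'     fluorescence units, AU).}
#' }
#' Under co-stimulation the switch probability and the responder gain
#' are both multiplied by `synergy_factor` (probability capped at 1), so
#' super-additive combined effects emerge downstream rather than being
#' hard-coded into any summary.
#'
#' Defaults emulate a serum-response-factor reporter line: a very low
#' spontaneous responder fraction, a maximal responder fraction around
#' 80%, and a several-fold intensity gain, with EC50 of 1 concentration
#' unit and unit Hill slopes for both components.
#'
#' @param p0,pmax baseline and maximal responder probability, with
#'   `0 <= p0 <= pmax <= 1`.
#' @param ec50_digital,hill_digital dose of half-maximal switch
#'   probability and Hill slope of the digital component.
#' @param gain0,gainmax baseline and maximal responder green intensity
#'   (AU, >= 0).
#' @param ec50_analogue,hill_analogue dose dependence of the analogue
#'   component.
#' @param nonresponder_green green level of non-responding cells (AU);
#'   0 gives the idealised assay in which only responders fluoresce.
#' @param synergy_factor multiplier (>= 1) applied to switch probability
#'   and responder gain under co-stimulation.
#' @return an object of class `stimulus_model` (a validated list).
#' @seealso [simulate_cell_table()], [responder_probability()],
#'   [responder_gain()]
#' @examples
#' m <- stimulus_model(pmax = 0.8, synergy_factor = 1.5)
#' responder_probability(m, dose = 1)
#' @export
stimulus_model <- function(p0 = 0.02, pmax = 0.8,
                           ec50_digital = 1, hill_digital = 1,
                           gain0 = 2000, gainmax = 8000,
                           ec50_analogue = 1, hill_analogue = 1,
                           nonresponder_green = 0,
                           synergy_factor = 1) {
  if (!(p0 >= 0 && p0 <= pmax && pmax <= 1))
    stop("need 0 <= p0 <= pmax <= 1")
  if (ec50_digital <= 0 || ec50_analogue <= 0)
    stop("ec50 values must be > 0")
  if (gain0 < 0 || gainmax < 0 || nonresponder_green < 0)
    stop("intensities must be >= 0")
  if (synergy_factor < 1)
    stop("synergy_factor must be >= 1")
  structure(list(
    p0 = p0, pmax = pmax,
    ec50_digital = ec50_digital, hill_digital = hill_digital,
    gain0 = gain0, gainmax = gainmax,
    ec50_analogue = ec50_analogue, hill_analogue = hill_analogue,
    nonresponder_green = nonresponder_green,
    synergy_factor = synergy_factor
  ), class = "stimulus_model")
}

#' Responder-switch probability at a dose
#'
#' Digital Hill curve of a [stimulus_model()]; with `costim = TRUE` the
#' probability is multiplied by the model's `synergy_factor` and capped
#' at 1 (capping is reported via a `"capped"` attribute, not an error).
#'
#' @param model a `stimulus_model`.
#' @param dose non-negative dose(s).
#' @param costim logical; apply the co-stimulation multiplier?
#' @return probability vector in \[0, 1\].
#' @export
responder_probability <- function(model, dose, costim = FALSE) {
  p <- hill_response(dose, model$p0, model$pmax,
                     model$ec50_digital, model$hill_digital)
  if (costim) p <- p * model$synergy_factor
  capped <- p > 1
  p <- pmin(p, 1)
  attr(p, "capped") <- any(capped)
  p
}

#' Responder green intensity at a dose
#'
#' Analogue Hill curve of a [stimulus_model()]; with `costim = TRUE` the
#' gain is multiplied by `synergy_factor`.
#'
#' @inheritParams responder_probability
#' @return expected responder green intensity (AU).
#' @export
responder_gain <- function(model, dose, costim = FALSE) {
  g <- hill_response(dose, model$gain0, model$gainmax,
                     model$ec50_analogue, model$hill_analogue)
  if (costim) g <- g * model$synergy_factor
  g
}

#' Simulation configuration for the synthetic reporter assay
#'
#' Plate- and imaging-level parameters of the generator: how many cells
#' per well, what fraction carry the red transfection marker, the dose
#' series, replicate wells, the red-channel intensity model, additive
#' measurement noise on the green channel, and the image geometry used
#' by [render_image_pair()].
#'
#' @param n_cells_per_well positive integer, cells simulated per well.
#' @param transfection_fraction fraction of cells carrying the red
#'   marker, in \[0, 1\].
#' @param doses numeric vector of non-negative stimulus concentrations.
#' @param n_replicate_wells positive integer replicate wells per
#'   condition.
#' @param red_mean,red_sd mean and SD of red marker intensity in
#'   transfected cells (AU).
#' @param red_untransfected red level of untransfected cells (AU).
#' @param noise_sd additive green measurement noise SD (AU).
#' @param noise_model `"normal"` (additive Gaussian) or `"lognormal"`
#'   (multiplicative, log-sd `noise_sd / expected intensity` scale);
#'   per-cell intensity distributions are not pinned down by population
#'   summaries, so both are offered.
#' @param width,height image size in pixels.
#' @param radius_range min and max cell radius in pixels.
#' @param rng_seed integer seed; identical configurations give
#'   bit-identical outputs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells_per_well = 500,
                       transfection_fraction = 0.3,
                       doses = c(0, 0.01, 0.1, 0.3, 1, 3, 10, 100),
                       n_replicate_wells = 18,
                       red_mean = 20000, red_sd = 3000,
                       red_untransfected = 0,
                       noise_sd = 50,
                       noise_model = c("normal", "lognormal"),
                       width = 512, height = 512,
                       radius_range = c(6, 12),
                       rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_cells_per_well <= 0) stop("n_cells_per_well must be positive")
  if (n_replicate_wells <= 0) stop("n_replicate_wells must be positive")
  if (transfection_fraction < 0 || transfection_fraction > 1)
    stop("transfection_fraction must be in [0, 1]")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(radius_range) != 2 || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be increasing and positive")
  structure(list(
    n_cells_per_well = as.integer(n_cells_per_well),
    transfection_fraction = transfection_fraction,
    doses = doses,
    n_replicate_wells = as.integer(n_replicate_wells),
    red_mean = red_mean, red_sd = red_sd,
    red_untransfected = red_untransfected,
    noise_sd = noise_sd, noise_model = noise_model,
    width = as.integer(width), height = as.integer(height),
    radius_range = radius_range,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}
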