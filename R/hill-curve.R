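#' Four-parameter Hill (log-logistic) response curve
#'
#' Computes `e0 + (emax - e0) * dose^hill / (ec50^hill + dose^hill)`.
#' At `dose = 0` the value is exactly `e0`; as `dose -> Inf` it tends to
#' `emax`. Used both by the synthetic-data generator (dose dependence of
#' the responder-switch probability and of the per-cell reporter gain)
#' and as the model function of [fit_hill()].
#'
#' @param dose numeric vector of non-negative concentrations.
#' @param e0 baseline response at zero dose.
#' @param emax asymptotic maximal response.
#' @param ec50 dose of half-maximal effect (must be > 0).
#' @param hill Hill slope (> 0 for activating curves).
#' @return numeric vector of responses, same length as `dose`.
#' @examples
#' hill_response(c(0, 1, 1e6), e0 = 0, emax = 1, ec50 = 1, hill = 1)
#' @export
hill_response <- function(dose, e0, emax, ec50, hill) {
  stopifnot(all(dose >= 0), ec50 > 0)
  frac <- ifelse(dose == 0, 0, 1 / (1 + (ec50 / dose)^hill))
  e0 + (emax - e0) * frac
}
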