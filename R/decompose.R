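#' Responder threshold from a control well
#'
#' Default rule: a transfected cell counts as responding when its green
#' mean exceeds the mean + `k` SD of green among transfected cells in
#' the matched control well. The rule is explicit and the resulting
#' threshold is recorded in every summary so runs remain comparable.
#'
#' @param control_cells cell table of the matched control well.
#' @param k number of SDs above the control mean (default 3).
#' @param use `"mean"` (default) or `"integral"`: which green statistic
#'   the threshold applies to.
#' @return numeric threshold (AU).
#' @export
responder_threshold <- function(control_cells, k = 3,
                                use = c("mean", "integral")) {
  use <- match.arg(use)
  g <- .green_stat(control_cells, use)[.is_transfected(control_cells)]
  if (length(g) == 0) stop("no transfected cells in the control well")
  mean(g) + k * sd(g)
}

.is_transfected <- function(cells) {
  if ("is_transfected" %in% names(cells)) cells$is_transfected
  else if ("truth_transfected" %in% names(cells)) cells$truth_transfected
  else stop("cells carry no transfection flag")
}

.green_stat <- function(cells, use) {
  if (use == "mean") cells$green_mean else cells$green_integral
}

#' Summarise one well: responder counts and intensities
#'
#' Among transfected (red) cells, counts those whose green reporter
#' signal exceeds the responder threshold and computes the three
#' population statistics the decomposition needs: the responding
#' fraction (digital axis), the mean green of responders (analogue
#' axis) and the mean green of all transfected cells (overall axis).
#'
#' @param cells a cell table (simulated or measured) carrying green
#'   values and a transfection flag.
#' @param threshold numeric responder threshold (AU), e.g. from
#'   [responder_threshold()].
#' @param condition,dose optional labels copied into the summary; `dose`
#'   defaults to the table's dose if present.
#' @param use green statistic the threshold applies to, `"mean"`
#'   (default) or `"integral"`.
#' @return an object of class `well_summary` (one-row list) with fields
#'   `condition`, `dose`, `n_transfected`, `n_responding`,
#'   `fraction_responding`, `mean_green_responders`,
#'   `mean_green_transfected`, `responder_threshold_used`.
#' @export
summarize_well <- function(cells, threshold, condition = NA_character_,
                           dose = NULL, use = c("mean", "integral")) {
  use <- match.arg(use)
  tf <- .is_transfected(cells)
  if (!any(tf)) stop("no transfected cells to summarize")
  g <- .green_stat(cells, use)[tf]
  resp <- g > threshold
  if (is.null(dose))
    dose <- if ("dose" %in% names(cells)) cells$dose[1] else NA_real_
  structure(list(
    condition = condition,
    dose = dose,
    n_transfected = sum(tf),
    n_responding = sum(resp),
    fraction_responding = mean(resp),
    mean_green_responders = if (any(resp)) mean(g[resp]) else NA_real_,
    mean_green_transfected = mean(g),
    responder_threshold_used = threshold,
    green_statistic = use
  ), class = "well_summary")
}

#' @export
print.well_summary <- function(x, ...) {
  cat(sprintf(
    "well summary%s: %d/%d transfected cells responding (%.1f%%)\n",
    if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$n_responding, x$n_transfected, 100 * x$fraction_responding))
  cat(sprintf("  mean green: responders %.1f, all transfected %.1f (threshold %.1f)\n",
              x$mean_green_responders, x$mean_green_transfected,
              x$responder_threshold_used))
  invisible(x)
}

#' Digital/analogue/overall decomposition of a treatment effect
#'
#' Splits the overall reporter response into its digital component (the
#' change in the fraction of transfected cells that respond) and its
#' analogue component (the change in mean reporter intensity of the
#' responding cells). Each component is the percent change of the
#' treated well relative to the control well; the overall response is
#' the percent change in mean green over all transfected cells. When
#' non-responders contribute no green signal, the components multiply:
#' `1 + overall/100 = (1 + digital/100) * (1 + analogue/100)`; the
#' relative deviation from that identity is reported as
#' `identity_residual` rather than hidden.
#'
#' Contribution shares are ratios of the percent changes: with digital
#' +200% and analogue +100%, the digital component contributes
#' 200/(200+100) = 2/3 of the effect. Because this percent-change rule
#' is asymmetric for large effects, the log-fold-change share is also
#' reported (`contribution_digital_log`). Contributions are only defined
#' when both deltas are non-zero-sum and share a sign; otherwise the
#' result is flagged (`"undefined"` or `"mixed-sign"`). A control well
#' with no responders makes the digital change undefined
#' (`"de-novo activation"` flag).
#'
#' @param treated,control [summarize_well()] results for the treated and
#'   matched control well.
#' @return an object of class `decomposition_result` with fields
#'   `delta_digital_pct`, `delta_analogue_pct`, `delta_overall_pct`,
#'   `contribution_digital`, `contribution_analogue`,
#'   `contribution_digital_log`, `identity_residual`, `flag`.
#' @examples
#' ctrl <- list(fraction_responding = 0.1, mean_green_responders = 100,
#'              mean_green_transfected = 10)
#' trt <- list(fraction_responding = 0.3, mean_green_responders = 200,
#'             mean_green_transfected = 60)
#' decompose(trt, ctrl)   # digital +200%, analogue +100% -> 2/3
#' @export
decompose <- function(treated, control) {
  fc <- control$fraction_responding
  ft <- treated$fraction_responding
  ac <- control$mean_green_responders
  at <- treated$mean_green_responders
  oc <- control$mean_green_transfected
  ot <- treated$mean_green_transfected

  flag <- "ok"
  if (is.na(fc) || fc == 0) {
    res <- .decomp_result(NA, NA, 100 * (ot / oc - 1), NA, NA, NA, NA,
                          "de-novo activation")
    return(res)
  }
  if (is.na(ac) || ac <= 0) stop("control mean_green_responders must be > 0")

  dd <- 100 * (ft / fc - 1)
  do <- 100 * (ot / oc - 1)
  if (is.na(at)) {  # treated well lost all responders
    return(.decomp_result(dd, NA, do, NA, NA, NA, NA,
                          "no-responders-treated"))
  }
  da <- 100 * (at / ac - 1)

  resid <- abs((1 + do / 100) - (1 + dd / 100) * (1 + da / 100)) /
    abs(1 + do / 100)

  if (dd == 0 && da == 0) {
    return(.decomp_result(dd, da, do, NA, NA, NA, resid, "undefined"))
  }
  if (sign(dd) * sign(da) < 0) {
    return(.decomp_result(dd, da, do, NA, NA, NA, resid, "mixed-sign"))
  }
  cd <- dd / (dd + da)
  cd_log <- {
    ld <- log1p(dd / 100); la <- log1p(da / 100)
    if (ld + la == 0) NA_real_ else ld / (ld + la)
  }
  .decomp_result(dd, da, do, cd, 1 - cd, cd_log, resid, flag)
}

.decomp_result <- function(dd, da, do, cd, ca, cd_log, resid, flag) {
  structure(list(delta_digital_pct = dd, delta_analogue_pct = da,
                 delta_overall_pct = do,
                 contribution_digital = cd, contribution_analogue = ca,
                 contribution_digital_log = cd_log,
                 identity_residual = resid, flag = flag),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("response decomposition (percent change vs control)\n")
  cat(sprintf("  digital  %+8.1f%%\n  analogue %+8.1f%%\n  overall  %+8.1f%%\n",
              x$delta_digital_pct, x$delta_analogue_pct, x$delta_overall_pct))
  if (!is.na(x$contribution_digital))
    cat(sprintf("  contributions: digital %.3f, analogue %.3f (log-share %.3f)\n",
                x$contribution_digital, x$contribution_analogue,
                x$contribution_digital_log))
  if (!identical(x$flag, "ok")) cat("  flag:", x$flag, "\n")
  if (!is.na(x$identity_residual))
    cat(sprintf("  multiplicative-identity residual: %.3g\n",
                x$identity_residual))
  invisible(x)
}

#' Decomposition along a time course
#'
#' Decomposes each timepoint against a common control and reports, per
#' component, the time to half-maximal change by linear interpolation
#' (with an implicit zero change at time 0, since every delta is
#' relative to the unstimulated control). A component that never rises
#' above zero, or stays constant, gets `NA` with a flag — used to show
#' e.g. that the digital response runs ahead of the analogue one.
#'
#' @param summaries list of [summarize_well()] results, one per
#'   timepoint.
#' @param control the shared control [summarize_well()] result.
#' @param times numeric timepoints (same length as `summaries`, >= 2).
#' @return a `data.frame` with one row per timepoint (the three deltas
#'   and contributions) plus attribute `"t_half"`, a named vector of
#'   half-maximum times for the digital, analogue and overall
#'   components.
#' @export
timecourse_decomposition <- function(summaries, control, times) {
  if (length(summaries) < 2) stop("need at least 2 timepoints")
  if (length(times) != length(summaries))
    stop("times must match summaries")
  dec <- lapply(summaries, decompose, control = control)
  df <- data.frame(
    time = times,
    delta_digital_pct = vapply(dec, `[[`, 0, "delta_digital_pct"),
    delta_analogue_pct = vapply(dec, `[[`, 0, "delta_analogue_pct"),
    delta_overall_pct = vapply(dec, `[[`, 0, "delta_overall_pct"),
    contribution_digital = vapply(dec, `[[`, 0, "contribution_digital"),
    flag = vapply(dec, `[[`, "", "flag"),
    stringsAsFactors = FALSE)
  t_half <- c(
    digital = .time_to_half(times, df$delta_digital_pct),
    analogue = .time_to_half(times, df$delta_analogue_pct),
    overall = .time_to_half(times, df$delta_overall_pct))
  attr(df, "t_half") <- t_half
  df
}

.time_to_half <- function(times, delta) {
  if (any(is.na(delta))) return(NA_real_)
  dmax <- max(delta)
  if (dmax <= 0 || diff(range(delta)) == 0) return(NA_real_)
  tt <- c(0, times)
  dd <- c(0, delta)
  half <- dmax / 2
  i <- which(dd >= half)[1]
  if (i == 1) return(tt[1])
  t0 <- tt[i - 1]; t1 <- tt[i]; d0 <- dd[i - 1]; d1 <- dd[i]
  t0 + (half - d0) / (d1 - d0) * (t1 - t0)
}
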