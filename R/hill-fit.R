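.hill4 <- function(dose, e0, emax, lec50, h) {
  frac <- ifelse(dose == 0, 0,
                 1 / (1 + 10^(h * (lec50 - log10(pmax(dose, 1e-300))))))
  e0 + (emax - e0) * frac
}

.hill_sse <- function(par, dose, y, w) {
  sum(w * (y - .hill4(dose, par[1], par[2], par[3], par[4]))^2)
}

#' Fit a four-parameter Hill dose-response curve
#'
#' Least-squares fit of baseline (`e0`), maximal effect (`emax`),
#' half-maximal concentration (`ec50`, parameterised as log10 for
#' optimizer conditioning and symmetric intervals) and Hill slope to a
#' dose series with replicate responses. Zero doses are handled exactly
#' (the curve equals `e0` there). Fitting starts from data-driven
#' values and, if Levenberg-Marquardt fails or stalls, falls back to a
#' multi-start coarse grid refined by Nelder-Mead; a fit that never
#' converges is returned flagged with the best grid estimates rather
#' than erroring. Parameter uncertainty comes from a stratified case
#' bootstrap over replicate wells within each dose.
#'
#' @param doses non-negative dose vector, one entry per well (replicate
#'   wells repeat the dose); at least 4 distinct doses.
#' @param responses numeric response per well (e.g. overall reporter
#'   activity).
#' @param weights optional non-negative fit weights.
#' @param fix_hill fix the slope to this value instead of fitting it
#'   (e.g. 1), or `NULL` (default) to fit it.
#' @param n_boot bootstrap resamples for CIs (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @return an object of class `hill_fit`: coefficients
#'   (`e0`, `emax`, `log_ec50`, `hill`), `sse`, `converged`, `flags`
#'   (e.g. `ec50_unidentifiable` when the response is flat,
#'   `ec50_outside_range`), percentile `ci`, bootstrap draws `boot`,
#'   and the data. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' d <- rep(c(0, 0.1, 0.3, 1, 3, 10), each = 3)
#' y <- hill_response(d, e0 = 0, emax = 1, ec50 = 1, hill = 1)
#' fit <- fit_hill(d, y, n_boot = 0)
#' coef(fit)
#' @export
fit_hill <- function(doses, responses, weights = NULL, fix_hill = NULL,
                     n_boot = 200, seed = 1L) {
  stopifnot(length(doses) == length(responses), all(doses >= 0))
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses")
  w <- if (is.null(weights)) rep(1, length(doses)) else weights

  est <- .fit_hill_once(doses, responses, w, fix_hill)

  boot <- NULL
  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    strata <- split(seq_along(doses), doses)
    boot <- matrix(NA_real_, n_boot, 4,
                   dimnames = list(NULL, names(est$par)))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), replace = TRUE)]), use.names = FALSE)
      bb <- .fit_hill_once(doses[idx], responses[idx], w[idx], fix_hill,
                           start = est$par)
      boot[b, ] <- bb$par
    }
    ci <- t(apply(boot, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
  }

  flags <- character(0)
  yrange <- diff(range(responses))
  if (abs(est$par["emax"] - est$par["e0"]) < 1e-8 * max(yrange, 1) ||
      yrange == 0)
    flags <- c(flags, "ec50_unidentifiable")
  pos <- doses[doses > 0]
  if (length(pos) > 0 &&
      (est$par["log_ec50"] < log10(min(pos)) ||
       est$par["log_ec50"] > log10(max(pos))))
    flags <- c(flags, "ec50_outside_range")

  structure(list(
    coefficients = est$par, sse = est$sse, converged = est$converged,
    flags = flags, ci = ci, boot = boot, n_boot = n_boot,
    doses = doses, responses = responses, weights = w,
    fix_hill = fix_hill
  ), class = "hill_fit")
}

.fit_hill_once <- function(doses, y, w, fix_hill, start = NULL) {
  e0_0 <- mean(y[doses == min(doses)])
  emax_0 <- mean(y[doses == max(doses)])
  pos <- sort(unique(doses[doses > 0]))
  lrange <- log10(range(pos))
  mid <- (e0_0 + emax_0) / 2
  agg <- vapply(pos, function(d) mean(y[doses == d]), numeric(1))
  cross <- which(if (emax_0 >= e0_0) agg >= mid else agg <= mid)[1]
  lec50_0 <- if (is.na(cross)) mean(lrange) else log10(pos[cross])

  starts <- list(c(e0 = e0_0, emax = emax_0, log_ec50 = lec50_0, hill = 1))
  if (!is.null(start)) starts <- c(list(start), starts)
  for (le in seq(lrange[1], lrange[2], length.out = 4))
    for (h in c(0.5, 1, 2))
      starts <- c(starts, list(c(e0 = e0_0, emax = emax_0,
                                 log_ec50 = le, hill = h)))
  if (!is.null(fix_hill))
    starts <- lapply(starts, function(s) { s["hill"] <- fix_hill; s })

  # try the most promising starts (by raw SSE) first; stop once a
  # converged fit beats the raw SSE of every untried start
  raw <- vapply(starts, .hill_sse, numeric(1), dose = doses, y = y, w = w)
  ord <- order(raw)
  best <- NULL
  for (j in seq_along(ord)) {
    fit <- .try_nlsLM(doses, y, w, starts[[ord[j]]], fix_hill)
    if (!is.null(fit) && (is.null(best) || fit$sse < best$sse - 1e-12))
      best <- fit
    if (!is.null(best) && best$converged &&
        (j == length(ord) || best$sse <= raw[ord[j + 1]] + 1e-12)) break
  }
  if (is.null(best)) {  # full grid fallback, flagged not converged
    grid_sse <- vapply(starts, .hill_sse, numeric(1),
                       dose = doses, y = y, w = w)
    s <- starts[[which.min(grid_sse)]]
    op <- optim(s, .hill_sse, dose = doses, y = y, w = w,
                method = "Nelder-Mead",
                control = list(maxit = 2000))
    par <- op$par
    if (!is.null(fix_hill)) par["hill"] <- fix_hill
    best <- list(par = par, sse = op$value, converged = FALSE)
  }
  best
}

.try_nlsLM <- function(doses, y, w, start, fix_hill) {
  out <- tryCatch({
    if (is.null(fix_hill)) {
      fit <- minpack.lm::nlsLM(
        y ~ .hill4(doses, e0, emax, lec50, h),
        start = list(e0 = start[["e0"]], emax = start[["emax"]],
                     lec50 = start[["log_ec50"]], h = start[["hill"]]),
        weights = w,
        lower = c(-Inf, -Inf, -12, 0.05), upper = c(Inf, Inf, 12, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- coef(fit)
      list(par = c(e0 = cf[["e0"]], emax = cf[["emax"]],
                   log_ec50 = cf[["lec50"]], hill = cf[["h"]]),
           sse = sum(w * residuals(fit)^2), converged = TRUE)
    } else {
      fit <- minpack.lm::nlsLM(
        y ~ .hill4(doses, e0, emax, lec50, fix_hill),
        start = list(e0 = start[["e0"]], emax = start[["emax"]],
                     lec50 = start[["log_ec50"]]),
        weights = w,
        lower = c(-Inf, -Inf, -12), upper = c(Inf, Inf, 12),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- coef(fit)
      list(par = c(e0 = cf[["e0"]], emax = cf[["emax"]],
                   log_ec50 = cf[["lec50"]], hill = fix_hill),
           sse = sum(w * residuals(fit)^2), converged = TRUE)
    }
  }, error = function(e) NULL, warning = function(w_) NULL)
  out
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Hill dose-response fit\n")
  cat(sprintf("  e0 = %.4g, Emax = %.4g, EC50 = %.4g (log10 = %.3f), slope = %.3g\n",
              cf["e0"], cf["emax"], 10^cf["log_ec50"], cf["log_ec50"],
              cf["hill"]))
  if (!is.null(x$ci))
    cat(sprintf("  log_ec50 95%% CI: [%.3f, %.3f] (%d bootstrap resamples)\n",
                x$ci["log_ec50", 1], x$ci["log_ec50", 2], x$n_boot))
  cat(sprintf("  SSE %.4g; converged: %s%s\n", x$sse, x$converged,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients)
  if (!is.null(object$ci)) {
    out$ci_lo <- object$ci[, 1]
    out$ci_hi <- object$ci[, 2]
  }
  out
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses
       else if (is.list(newdata)) newdata$dose else newdata
  cf <- object$coefficients
  .hill4(d, cf["e0"], cf["emax"], cf["log_ec50"], cf["hill"])
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...)
  object$responses - fitted(object)

#' @export
plot.hill_fit <- function(x, ...) {
  pos <- x$doses > 0
  dmin <- min(x$doses[pos]) / 10
  px <- ifelse(x$doses == 0, dmin, x$doses)
  plot(px, x$responses, log = "x",
       xlab = "dose (0 plotted at left edge)", ylab = "response", ...)
  dd <- 10^seq(log10(dmin), log10(max(x$doses)), length.out = 200)
  lines(dd, predict(x, dd), col = "red3")
  abline(v = 10^x$coefficients["log_ec50"], lty = 3)
  invisible(x)
}

#' Compare the EC50 of two Hill fits
#'
#' Shift in log10 EC50 (`fit_b` minus `fit_a`) with a bootstrap
#' confidence interval and two-sided p-value from the paired difference
#' of the two fits' bootstrap draws — e.g. to show a sensitising
#' co-stimulus left-shifts the dose-response curve.
#'
#' @param fit_a,fit_b converged [fit_hill()] objects with bootstrap
#'   draws.
#' @return list of class `ec50_shift`: `delta_log_ec50` (negative means
#'   `fit_b` is left-shifted, i.e. more sensitive), `ec50_ratio`, `ci`,
#'   `p_value`, `n_boot`.
#' @export
compare_ec50 <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b)) {
    if (!f$converged) stop("both fits must have converged")
    if ("ec50_unidentifiable" %in% f$flags)
      stop("EC50 unidentifiable in one of the fits")
    if (is.null(f$boot)) stop("fits need bootstrap draws (n_boot > 0)")
  }
  d_hat <- unname(fit_b$coefficients["log_ec50"] -
                  fit_a$coefficients["log_ec50"])
  nb <- min(nrow(fit_a$boot), nrow(fit_b$boot))
  d <- fit_b$boot[seq_len(nb), "log_ec50"] -
    fit_a$boot[seq_len(nb), "log_ec50"]
  d <- d[!is.na(d)]
  ci <- quantile(d, c(0.025, 0.975), names = FALSE)
  # two-sided bootstrap p with add-one correction
  p <- min(1, 2 * min((1 + sum(d <= 0)) / (length(d) + 1),
                      (1 + sum(d >= 0)) / (length(d) + 1)))
  structure(list(delta_log_ec50 = d_hat, ec50_ratio = 10^d_hat,
                 ci = ci, p_value = p, n_boot = length(d)),
            class = "ec50_shift")
}

#' @export
print.ec50_shift <- function(x, ...) {
  cat(sprintf(
    "EC50 shift: delta log10 EC50 = %.3f (ratio %.3g), 95%% CI [%.3f, %.3f], p = %.4g\n",
    x$delta_log_ec50, x$ec50_ratio, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}
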