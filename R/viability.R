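# four-parameter logistic (variable-slope) dose-response curve; hill > 0
# gives a decreasing viability curve, v(0) = top, v(Inf) = bottom,
# v(ic50) = (top + bottom) / 2
fourpl <- function(conc, bottom, top, ic50, hill) {
  out <- bottom + (top - bottom) / (1 + (conc / ic50)^hill)
  out[conc == 0] <- top
  out
}

#' Relative viability from resazurin absorbances
#'
#' `100 * (Abs_experiment - Abs_background) / (Abs_control - Abs_background)`.
#' The untreated control reads 100% by construction; values are not clipped
#' and may exceed 100 or fall below 0. Adding a constant offset to all three
#' absorbances leaves the result unchanged.
#'
#' @param abs_experiment,abs_control,abs_background Absorbance readings
#'   (unitless OD); vectors are recycled the usual way.
#' @return Relative viability in percent.
#' @export
relative_viability <- function(abs_experiment, abs_control, abs_background) {
  denom <- abs_control - abs_background
  if (any(denom == 0)) {
    stop("relative_viability: control equals background (zero denominator)")
  }
  100 * (abs_experiment - abs_background) / denom
}

#' Fit a variable-slope (4PL) dose-response curve
#'
#' Nonlinear least squares of
#' `v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)` on viability
#' percentages, the variable-slope model used to derive reference IC50
#' values. Fitting is done in linear parameter space with the analytic
#' curve, so zero-concentration wells enter through the top asymptote and
#' no log(0) arises. Starting values come from the data extremes and the
#' half-maximal crossing; bounds are `bottom >= -10`, `top <= 150`,
#' `ic50 > 0`, hill free-sign. Non-convergence is flagged, not thrown.
#'
#' @param data A `data.frame` with `concentration_uM` and either
#'   `viability_pct` or the three absorbance columns `abs_experiment`,
#'   `abs_control`, `abs_background`.
#' @return A list of class `fourpl_fit`: `bottom_pct`, `top_pct`,
#'   `ic50_uM`, `hill_slope`, `rss`, `converged`, `message`.
#' @export
fit_ic50 <- function(data) {
  stopifnot(is.data.frame(data), "concentration_uM" %in% names(data))
  conc <- data$concentration_uM
  stopifnot(all(conc >= 0))
  v <- if ("viability_pct" %in% names(data)) {
    data$viability_pct
  } else {
    relative_viability(data$abs_experiment, data$abs_control,
                       data$abs_background)
  }
  stopifnot(all(is.finite(v)))
  if (length(unique(conc)) < 5L) {
    stop("fit_ic50: need at least 5 distinct concentrations")
  }
  top0 <- max(v)
  bottom0 <- min(v)
  mid <- (top0 + bottom0) / 2
  pos <- conc > 0
  ic500 <- conc[pos][which.min(abs(v[pos] - mid))]
  if (!is.finite(ic500) || ic500 <= 0) ic500 <- stats::median(conc[pos])
  # hill > 0 when viability falls with concentration
  hill0 <- if (stats::cor(conc, v) <= 0) 1 else -1
  df <- data.frame(conc = conc, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
      data = df,
      start = list(bottom = bottom0, top = top0, ic50 = ic500, hill = hill0),
      lower = c(bottom = -10, top = -Inf, ic50 = 1e-12, hill = -Inf),
      upper = c(bottom = Inf, top = 150, ic50 = Inf, hill = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(bottom_pct = bottom0, top_pct = top0,
                          ic50_uM = ic500, hill_slope = hill0, rss = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "fourpl_fit"))
  }
  est <- stats::coef(fit)
  structure(
    list(bottom_pct = unname(est["bottom"]), top_pct = unname(est["top"]),
         ic50_uM = unname(est["ic50"]), hill_slope = unname(est["hill"]),
         rss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv,
         message = fit$convInfo$stopMessage),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> IC50 %.4g uM | hill %.3g | top %.1f%% bottom %.1f%% | RSS %.3g%s\n",
    x$ic50_uM, x$hill_slope, x$top_pct, x$bottom_pct, x$rss,
    if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}
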