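# Dose-response analysis: viability percentages from plate absorbances and
# four-parameter logistic (4PL) fitting on the log10 concentration scale.

#' Cell viability percentage
#'
#' @param abs_test Absorbance of treated wells (AU).
#' @param abs_control Absorbance of untreated control wells (AU), positive.
#' @return `abs_test / abs_control * 100`.
#' @examples
#' viability_percent(0.5, 1.0) # 50
#' @export
viability_percent <- function(abs_test, abs_control) {
  if (any(abs_control <= 0)) stop("control absorbance must be positive")
  abs_test / abs_control * 100
}

#' Serial dilution series
#'
#' Geometric series `start / factor^k`, k = 0..n-1, the standard plate
#' layout for dose-response assays (e.g. 100 down to 1.5625 mg/mL for a
#' two-fold series of length 7).
#'
#' @param start Highest concentration, positive.
#' @param factor Dilution factor, greater than 1.
#' @param n Number of concentrations, at least 1.
#' @return Numeric vector of length `n`, decreasing.
#' @examples
#' serial_dilution(100, 2, 7)
#' @export
serial_dilution <- function(start, factor, n) {
  stopifnot(length(start) == 1L, length(factor) == 1L, length(n) == 1L)
  if (start <= 0) stop("start must be positive")
  if (factor <= 1) stop("dilution factor must exceed 1")
  if (n < 1) stop("n must be at least 1")
  start / factor^(0:(n - 1))
}

# 4PL viability curve on the log10 concentration scale; hill > 0 gives a
# response decreasing with concentration.
.fourpl <- function(conc, top, bottom, l10ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - l10ic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = bottom + (top - bottom) / (1 + 10^(hill (log10 c - log10 IC50)))`
#' to (concentration, viability) points, with `hill > 0` so viability
#' decreases with concentration and the fitted curve passes through
#' `(top + bottom) / 2` at the IC50. Replicates enter as individual points
#' so the IC50 standard error reflects replicate scatter. Optimization is
#' bounded: the IC50 is constrained to the tested concentration range
#' widened a hundred-fold either side, the hill slope to [0.1, 10].
#' Non-convergence is reported in the `converged` flag, never silently.
#'
#' Zero-concentration points are accepted as untreated anchors: at zero
#' dose the curve evaluates exactly to `top`, so control wells pin the
#' upper plateau that a dilution series starting near the IC50 never
#' samples. At least five distinct positive concentrations are required.
#'
#' @param conc Concentrations (non-negative; zero marks untreated wells),
#'   or a data.frame with columns `concentration` and `viability`.
#' @param viability Viability percentages (omit when `conc` is a data.frame).
#' @return An object of class `fourpl_fit` with components `top`, `bottom`,
#'   `ic50`, `hill`, `se_ic50` (delta-method SE from the fit covariance on
#'   the log10 scale), `converged`, `fit` (the underlying `nls` object) and
#'   `data`.
#' @examples
#' cc <- rep(serial_dilution(100, 2, 7), each = 3)
#' fit_4pl(cc, 100 / (1 + cc / 2))
#' @export
fit_4pl <- function(conc, viability = NULL) {
  if (is.data.frame(conc)) {
    viability <- conc$viability
    conc <- conc$concentration
  }
  stopifnot(length(conc) == length(viability))
  keep <- is.finite(conc) & is.finite(viability)
  conc <- conc[keep]; viability <- viability[keep]
  pos <- conc > 0
  if (length(unique(conc[pos])) < 5) {
    stop("need at least 5 distinct positive concentrations")
  }
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (stats::sd(viability) == 0) stop("degenerate (constant) response")

  dat <- data.frame(conc = conc, v = viability)
  lo <- c(top = 0, bottom = -20,
          l10ic50 = log10(min(conc[pos]) * 0.01), hill = 0.1)
  hi <- c(top = 2 * max(viability), bottom = max(viability),
          l10ic50 = log10(max(conc) * 100), hill = 10)
  # initialize from the data: plateaus from the response quartiles, IC50
  # from the concentration whose response is nearest the midpoint
  q <- stats::quantile(viability, c(0.1, 0.9), names = FALSE)
  mid <- mean(q)
  cpos <- conc[pos]; vpos <- viability[pos]
  start <- c(top = max(q[2], 1), bottom = q[1],
             l10ic50 = log10(cpos[which.min(abs(vpos - mid))]), hill = 1)
  start <- pmin(pmax(start, lo + 1e-9), hi - 1e-9)

  fit <- try(minpack.lm::nlsLM(
    v ~ .fourpl(conc, top, bottom, l10ic50, hill),
    data = dat, start = as.list(start), lower = lo, upper = hi,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)

  if (inherits(fit, "try-error")) {
    out <- list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                hill = NA_real_, se_ic50 = NA_real_, converged = FALSE,
                fit = NULL, data = dat)
    return(structure(out, class = "fourpl_fit"))
  }
  cf <- stats::coef(fit)
  se_l10 <- tryCatch(sqrt(diag(stats::vcov(fit)))[["l10ic50"]],
                     error = function(e) NA_real_)
  ic50 <- 10^cf[["l10ic50"]]
  structure(list(top = cf[["top"]], bottom = cf[["bottom"]], ic50 = ic50,
                 hill = cf[["hill"]],
                 se_ic50 = ic50 * log(10) * se_l10,
                 converged = isTRUE(fit$convInfo$isConv),
                 fit = fit, data = dat),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  cat(sprintf("  IC50:   %.4g  (SE %.3g)\n", x$ic50, x$se_ic50))
  cat(sprintf("  top:    %.4g    bottom: %.4g    hill: %.4g\n",
              x$top, x$bottom, x$hill))
  cat(sprintf("  n = %d points, %d distinct concentrations\n",
              nrow(x$data), length(unique(x$data$conc))))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, ic50 = object$ic50,
    hill = object$hill)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  .fourpl(conc, object$top, object$bottom, log10(object$ic50), object$hill)
}

#' @export
residuals.fourpl_fit <- function(object, ...) {
  object$data$v - predict(object)
}

#' @export
summary.fourpl_fit <- function(object, ...) {
  cat(sprintf(
    "4PL fit: IC50 %.4g +/- %.3g (SE, from fit covariance), hill %.3g\n",
    object$ic50, object$se_ic50, object$hill))
  cat(sprintf("top %.4g, bottom %.4g; residual SD %.3g on %d points\n",
              object$top, object$bottom, stats::sd(residuals(object)),
              nrow(object$data)))
  if (!is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' @export
plot.fourpl_fit <- function(x, ...) {
  plot(x$data$conc, x$data$v, log = "x", xlab = "concentration",
       ylab = "viability (%)", ...)
  cc <- 10^seq(log10(min(x$data$conc)), log10(max(x$data$conc)), length.out = 200)
  graphics::lines(cc, predict(x, cc))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

#' Fit a dose-response curve from a plate table
#'
#' Computes per-well viability against the mean control absorbance and fits
#' the 4PL model on the individual replicate points. Control wells enter
#' the fit as zero-concentration anchors of the upper plateau (see
#' [fit_4pl()]).
#'
#' @param plate Data.frame with columns `concentration`, `replicate`,
#'   `absorbance`, `is_control`.
#' @return A `fourpl_fit`.
#' @export
fit_plate <- function(plate) {
  need <- c("concentration", "absorbance", "is_control")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ctrl <- plate$absorbance[plate$is_control]
  if (!length(ctrl)) stop("no control wells")
  test <- plate[!plate$is_control, , drop = FALSE]
  fit_4pl(c(rep(0, length(ctrl)), test$concentration),
          viability_percent(c(ctrl, test$absorbance), mean(ctrl)))
}
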