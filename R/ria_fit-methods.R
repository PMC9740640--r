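#' @export
print.ria_fit <- function(x, ...) {
  cat(sprintf("One-pool RIA decay fit: %s (%s+)\n",
              x$sequence, as.character(x$charge)))
  cat(sprintf("  k = %.5f /day  (95%% CI %.5f .. %.5f)\n",
              x$k, x$ci_low, x$ci_high))
  cat(sprintf("  R2 = %.4f  RMSE = %.3g  Pearson r = %.4f  NDP = %d\n",
              x$r2, x$rmse, x$pearson_r, x$ndp))
  invisible(x)
}

#' @export
summary.ria_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Peptide:   %s, charge %s, NEH = %s\n", x$sequence,
              as.character(x$charge), format(x$neh)))
  cat(sprintf("Model:     I0(t) = %.5f + (%.5f - %.5f) * exp(-k t)\n",
              x$I0asymp, x$I00, x$I0asymp))
  cat(sprintf("Rate:      k = %.6f /day, SE = %.3g, 95%% CI [%.6f, %.6f]\n",
              x$k, x$se, x$ci_low, x$ci_high))
  cat(sprintf("GOF:       R2 = %.5f, RMSE = %.4g, r = %.5f, SD = %.4g\n",
              x$r2, x$rmse, x$pearson_r, x$sd))
  cat(sprintf("Data:      %d points (%d MBR)\n",
              x$ndp, sum(x$source == "mbr")))
  invisible(x)
}

#' @export
coef.ria_fit <- function(object, ...) c(k = object$k)

#' @export
fitted.ria_fit <- function(object, ...) object$fitted

#' @export
residuals.ria_fit <- function(object, ...) object$residuals

#' Predict the RIA decay curve from a fit
#' @param object An `ria_fit`.
#' @param newdata Optional numeric vector of times (days); defaults to the
#'   fitted times.
#' @param ... Unused.
#' @return Predicted RIA values.
#' @export
predict.ria_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else as.numeric(newdata)
  theoretical_ria(t, object$k, object$I00, object$I0asymp)
}

#' Simulate RIA observations from a fitted decay
#'
#' Draws Gaussian residual noise (sd = residual SD of the fit) around the
#' fitted curve, the parametric-bootstrap companion of [fit_rate()].
#'
#' @param object An `ria_fit`.
#' @param nsim Number of simulated series.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Matrix `ndp x nsim` of simulated RIA values.
#' @export
simulate.ria_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$ndp
  matrix(rep(object$fitted, nsim) + stats::rnorm(n * nsim, 0, object$sd),
         nrow = n, ncol = nsim)
}

#' Plot an RIA decay fit
#'
#' Scatter of the experimental monoisotopic RIA against labeling time (MBR
#' points in red) with the fitted theoretical decay as a solid line.
#'
#' @param x An `ria_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ria_fit <- function(x, ...) {
  cols <- ifelse(x$source == "mbr", "red", "black")
  graphics::plot(x$time, x$ria, col = cols, pch = 16,
                 xlab = "labeling duration (days)",
                 ylab = "monoisotopic RIA",
                 main = sprintf("%s (%s+)", x$sequence,
                                as.character(x$charge)), ...)
  tt <- seq(0, max(x$time), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}
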