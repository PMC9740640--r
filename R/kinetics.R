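# ---- decay model --------------------------------------------------------

#' Theoretical monoisotopic RIA under one-pool turnover kinetics
#'
#' `I0(t) = I0asymp + (I00 - I0asymp) * exp(-k * t)`: the monoisotopic RIA
#' decays exponentially from its natural value `I00` toward the labeling
#' plateau `I0asymp` with rate constant `k` (per day).
#'
#' @param t Labeling duration(s) in days, >= 0.
#' @param k Turnover rate constant per day, >= 0.
#' @param I00 Natural (unlabeled) monoisotopic RIA.
#' @param I0asymp Plateau monoisotopic RIA.
#' @return RIA value(s), same length as `t`.
#' @export
theoretical_ria <- function(t, k, I00, I0asymp) {
  if (any(t < 0)) stop("labeling time t must be >= 0")
  if (k < 0) stop("rate constant k must be >= 0")
  I0asymp + (I00 - I0asymp) * exp(-k * t)
}

#' RIA time series for one peptide
#'
#' Collects the (time, RIA) observations of a peptide across labeling
#' durations together with the quantities that fix the decay model: the
#' natural monoisotopic RIA `I00`, the plateau `I0asymp`, and the peptide's
#' exchangeable-hydrogen count.
#'
#' @param time Labeling durations in days.
#' @param ria Observed monoisotopic RIA per point, in (0, 1].
#' @param I00 Natural monoisotopic RIA.
#' @param I0asymp Plateau RIA.
#' @param source Character per point: `"identified"` or `"mbr"`.
#' @param experiment Experiment identifier per point.
#' @param sequence,charge,neh Peptide annotation.
#' @return Object of class `ria_series` (a list; points sorted by time).
#' @export
ria_series <- function(time, ria, I00, I0asymp,
                       source = rep("identified", length(time)),
                       experiment = seq_along(time),
                       sequence = NA_character_, charge = NA_integer_,
                       neh = NA_real_) {
  stopifnot(length(time) == length(ria), length(source) == length(time))
  if (any(time < 0)) stop("times must be >= 0")
  if (any(ria <= 0 | ria > 1)) stop("RIA values must lie in (0, 1]")
  if (!all(source %in% c("identified", "mbr")))
    stop("source flags must be 'identified' or 'mbr'")
  ord <- order(time)
  structure(
    list(time = time[ord], ria = ria[ord], source = source[ord],
         experiment = experiment[ord], I00 = I00, I0asymp = I0asymp,
         sequence = sequence, charge = charge, neh = neh),
    class = "ria_series"
  )
}

#' @export
print.ria_series <- function(x, ...) {
  cat(sprintf("RIA time series: %s (%s+), %d points, I00 = %.4f, I0asymp = %.4f\n",
              x$sequence, as.character(x$charge), length(x$time),
              x$I00, x$I0asymp))
  print(data.frame(time = x$time, ria = round(x$ria, 5), source = x$source))
  invisible(x)
}

# ---- fitting ------------------------------------------------------------

#' Fit the turnover rate constant to an RIA time series
#'
#' Nonlinear least squares with a single free parameter: the rate constant
#' `k` of the one-pool exponential decay.  `I00` and `I0asymp` are held fixed
#' at their theoretical values (natural RIA and labeling plateau).  The
#' optimum is located by bounded minimization of the residual sum of squares
#' over `k` in `[0, k_max]`, multi-started at 0.01, 0.1 and 1 per day and
#' polished; the procedure is deterministic.
#'
#' The 95% confidence interval uses the linearized (Wald) standard error at
#' the optimum: `se = sigma / ||J||`, with `J` the gradient of the model
#' curve in `k` and `sigma^2` the residual variance.
#'
#' @param series An [ria_series()].
#' @param min_ndp Minimum number of data points required (default 3).
#' @param k_max Upper bound for the rate constant, per day.
#' @param use_mbr Include points quantified by match-between-runs (default
#'   TRUE); when FALSE only MS/MS-identified points enter the fit.
#' @return Object of class `ria_fit` with components `k`, `ci_low`,
#'   `ci_high`, `se`, `r2`, `rmse`, `pearson_r`, `sd`, `ndp`, plus the data
#'   used.  Errors if fewer than `min_ndp` usable points.
#' @examples
#' tt <- c(0, 1, 2, 3, 6, 7, 9, 13, 16, 21, 24, 31)
#' s <- ria_series(tt, theoretical_ria(tt, 0.05, 0.5, 0.3), 0.5, 0.3)
#' fit <- fit_rate(s)
#' coef(fit)
#' @export
fit_rate <- function(series, min_ndp = 3L, k_max = 10, use_mbr = TRUE) {
  stopifnot(inherits(series, "ria_series"))
  keep <- if (use_mbr) rep(TRUE, length(series$time))
          else series$source == "identified"
  t <- series$time[keep]; y <- series$ria[keep]
  if (length(t) < min_ndp)
    stop(sprintf("peptide %s: %d points < min_ndp = %d",
                 series$sequence, length(t), min_ndp))
  I00 <- series$I00; I0asymp <- series$I0asymp
  if (!(I00 > I0asymp))
    stop("degenerate labeling: I00 must exceed I0asymp")
  # optimizers may probe a hair below the bound; clamp at zero
  rss <- function(k) sum((y - theoretical_ria(t, max(k, 0), I00, I0asymp))^2)
  starts <- c(0.01, 0.1, 1)
  fits <- lapply(starts, function(s0)
    stats::optim(s0, rss, method = "L-BFGS-B", lower = 0, upper = k_max))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  # polish on the bracketed optimum; optimize() is derivative-free and robust
  pol <- stats::optimize(rss, c(max(0, best$par - 0.5), min(k_max, best$par + 0.5)),
                         tol = .Machine$double.eps^0.5)
  k <- if (pol$objective <= best$value) pol$minimum else best$par
  if (rss(0) <= rss(k)) k <- 0
  pred <- theoretical_ria(t, k, I00, I0asymp)
  res <- y - pred
  ndp <- length(t)
  gof <- goodness_of_fit(y, pred)
  J <- -(I00 - I0asymp) * t * exp(-k * t)     # d model / d k
  sigma2 <- sum(res^2) / max(ndp - 1L, 1L)
  se <- if (sum(J^2) > 0) sqrt(sigma2 / sum(J^2)) else NA_real_
  zc <- stats::qnorm(0.975)
  structure(
    list(k = k, se = se,
         ci_low = if (is.na(se)) NA_real_ else k - zc * se,
         ci_high = if (is.na(se)) NA_real_ else k + zc * se,
         r2 = gof[["r2"]], rmse = gof[["rmse"]],
         pearson_r = gof[["pearson_r"]], sd = gof[["sd"]],
         ndp = ndp, time = t, ria = y, fitted = pred, residuals = res,
         source = series$source[keep], I00 = I00, I0asymp = I0asymp,
         sequence = series$sequence, charge = series$charge,
         neh = series$neh),
    class = "ria_fit"
  )
}

#' Goodness-of-fit statistics
#'
#' Standard definitions: `r2 = 1 - SSres/SStot`, root-mean-squared error,
#' Pearson correlation between observed and predicted, and the residual
#' standard deviation `sqrt(SSres / (n - 1))`.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return Named numeric vector `c(r2, rmse, pearson_r, sd)`.  `pearson_r`
#'   is `NA` when either vector is constant.
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 2L) stop("goodness of fit undefined for fewer than 2 points")
  res <- observed - predicted
  sstot <- sum((observed - mean(observed))^2)
  ssres <- sum(res^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_
  pr <- if (stats::sd(observed) > 0 && stats::sd(predicted) > 0)
    stats::cor(observed, predicted) else NA_real_
  c(r2 = r2, rmse = sqrt(ssres / n), pearson_r = pr,
    sd = sqrt(ssres / (n - 1L)))
}

#' Fractional synthesis of a peptide time series
#'
#' `FS(t) = (I00 - I0(t)) / (I00 - I0asymp)`: the fraction of the peptide
#' pool renewed since labeling began.  On a noise-free exponential series
#' this equals `1 - exp(-k t)` identically.
#'
#' @param series An [ria_series()].
#' @return data.frame with columns `time`, `fs`, `source`.
#' @export
fractional_synthesis <- function(series) {
  stopifnot(inherits(series, "ria_series"))
  denom <- series$I00 - series$I0asymp
  if (denom <= 0) stop("degenerate labeling: I00 must exceed I0asymp")
  data.frame(time = series$time,
             fs = (series$I00 - series$ria) / denom,
             source = series$source)
}

# ---- protein-level aggregation -----------------------------------------

#' Protein turnover rate from peptide fits
#'
#' The protein rate constant is the median of the member peptides' rate
#' constants (for an even count, the mean of the two central values).
#'
#' @param fits List of [fit_rate()] results (class `ria_fit`) for the
#'   peptides of one protein; must be non-empty.
#' @param entry Protein entry name.
#' @param r2_floor Optional minimum peptide `r2`; peptides below it are
#'   excluded before taking the median (default `NULL`: no filter).
#' @return Object of class `protein_summary`: list with `entry`, `k`
#'   (protein rate), `peptide_fits`, `n_peptides`, `ndp_total`.
#' @export
protein_rate <- function(fits, entry = NA_character_, r2_floor = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "ria_fit")))
  if (!is.null(r2_floor))
    fits <- Filter(function(f) !is.na(f$r2) && f$r2 >= r2_floor, fits)
  if (!length(fits))
    stop("protein ", entry, ": no peptide fit passes the r2 floor")
  ks <- vapply(fits, `[[`, 0, "k")
  structure(
    list(entry = entry, k = stats::median(ks), peptide_fits = fits,
         n_peptides = length(fits),
         ndp_total = sum(vapply(fits, `[[`, 0L, "ndp"))),
    class = "protein_summary"
  )
}

#' @export
print.protein_summary <- function(x, ...) {
  cat(sprintf("Protein %s: k = %.5f /day (median of %d peptides, %d points)\n",
              x$entry, x$k, x$n_peptides, x$ndp_total))
  invisible(x)
}

#' Identification-consistency filter
#'
#' Keeps peptides identified by MS/MS (not MBR) in at least
#' `min_peptide_runs` experiments, then keeps proteins whose surviving
#' peptides cover at least `min_protein_runs` experiments with MS/MS
#' identifications.  MBR points never count toward identification
#' consistency (they do count toward the number of fitted data points
#' downstream).
#'
#' @param observations data.frame with columns `sequence`, `charge`,
#'   `protein`, `experiment`, `source` (`"identified"` / `"mbr"`).
#' @param min_peptide_runs,min_protein_runs Non-negative integer thresholds.
#' @return The filtered data.frame (all columns preserved).
#' @export
consistency_filter <- function(observations, min_peptide_runs = 1L,
                               min_protein_runs = 1L) {
  stopifnot(all(c("sequence", "charge", "protein", "experiment", "source")
                %in% names(observations)))
  obs <- observations
  ids <- obs[obs$source == "identified", , drop = FALSE]
  pep_key <- function(d) paste(d$sequence, d$charge, sep = "/")
  pep_runs <- tapply(ids$experiment, pep_key(ids),
                     function(e) length(unique(e)))
  keep_pep <- names(pep_runs)[pep_runs >= min_peptide_runs]
  obs <- obs[pep_key(obs) %in% keep_pep, , drop = FALSE]
  ids <- ids[pep_key(ids) %in% keep_pep, , drop = FALSE]
  prot_runs <- tapply(ids$experiment, ids$protein,
                      function(e) length(unique(e)))
  keep_prot <- names(prot_runs)[prot_runs >= min_protein_runs]
  obs[obs$protein %in% keep_prot, , drop = FALSE]
}

#' Median-of-medians normalized protein abundance
#'
#' Divides a protein's average monoisotopic abundance by the median, over
#' experiments, of each experiment's median base-peak abundance.
#'
#' @param abundance Protein average monoisotopic abundance.
#' @param base_peaks List (one element per experiment) of numeric vectors of
#'   per-spectrum base-peak intensities, or a numeric vector of
#'   per-experiment median base-peak abundances.
#' @return Normalized abundance.
#' @export
normalized_protein_abundance <- function(abundance, base_peaks) {
  med <- if (is.list(base_peaks))
    vapply(base_peaks, stats::median, 0) else as.numeric(base_peaks)
  norm <- stats::median(med)
  if (!is.finite(norm) || norm <= 0)
    stop("normalizer (median of median base peaks) is not positive")
  abundance / norm
}
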