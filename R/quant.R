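# ---- isotopomer extraction ---------------------------------------------

#' Integrate six-isotopomer MS1 abundances for one peptide
#'
#' Targets the m/z of isotopomers M0..M5 at
#' `theo_mz + i * spacing / charge` and, for each MS1 scan within
#' `anchor_rt +/- rt_window`, sums intensity within `+/- ppm_tol` of each
#' target.  Elution bounds are found from the M0 chromatogram: starting at
#' its apex, the bounds extend outward while the (3-point smoothed)
#' intensity stays at or above `bound_frac` of the apex.  Abundances are the
#' per-isotopomer sums over the scans inside the bounds.
#'
#' @param spectra An [read_ms1_spectra()] result.
#' @param theo_mz Theoretical monoisotopic m/z.
#' @param charge Charge state.
#' @param anchor_rt Anchor retention time in minutes (typically the
#'   identification RT, or a mapped donor apex for MBR).
#' @param rt_window Half-width of the search window, minutes.
#' @param ppm_tol Mass tolerance in ppm.
#' @param n_isotopomers Number of isotopomers (default 6).
#' @param bound_frac Apex fraction defining the elution bounds (default
#'   0.05).
#' @param source `"identified"` or `"mbr"` provenance flag.
#' @param constants An [isotope_constants()] (supplies the spacing).
#' @return Object of class `isotopomer_xic`: list with `abundances`
#'   (length-6), `elution_start`, `elution_end`, `apex_rt` (minutes),
#'   `ppm_error` (signed, observed M0 vs theoretical), `mono_width` (m/z
#'   FWHM of the M0 peak; NA for centroid data), `source`, `n_scans`.
#'   Returns `NULL` when no M0 signal exists anywhere in the window (the
#'   peptide is not quantifiable in this run).
#' @export
extract_isotope_profile <- function(spectra, theo_mz, charge, anchor_rt,
                                    rt_window = 1.0, ppm_tol = 10,
                                    n_isotopomers = 6L, bound_frac = 0.05,
                                    source = "identified",
                                    constants = isotope_constants()) {
  stopifnot(inherits(spectra, "ms1_spectra"))
  rts <- vapply(spectra, `[[`, 0, "rt")
  inside <- which(rts >= anchor_rt - rt_window & rts <= anchor_rt + rt_window)
  if (!length(inside)) return(NULL)
  targets <- theo_mz + (0:(n_isotopomers - 1L)) * constants$spacing / charge
  half <- targets * ppm_tol * 1e-6
  per_scan <- matrix(0, nrow = length(inside), ncol = n_isotopomers)
  mz_acc_num <- 0; mz_acc_den <- 0
  for (r in seq_along(inside)) {
    sp <- spectra[[inside[r]]]
    for (i in seq_len(n_isotopomers)) {
      sel <- sp$mz >= targets[i] - half[i] & sp$mz <= targets[i] + half[i]
      if (any(sel)) {
        per_scan[r, i] <- sum(sp$intensity[sel])
        if (i == 1L) {
          mz_acc_num <- mz_acc_num + sum(sp$mz[sel] * sp$intensity[sel])
          mz_acc_den <- mz_acc_den + sum(sp$intensity[sel])
        }
      }
    }
  }
  m0 <- per_scan[, 1]
  if (all(m0 <= 0)) return(NULL)
  apex <- which.max(.smooth3(m0))
  thresh <- bound_frac * .smooth3(m0)[apex]
  lo <- apex
  while (lo > 1L && .smooth3(m0)[lo - 1L] >= thresh) lo <- lo - 1L
  hi <- apex
  while (hi < length(m0) && .smooth3(m0)[hi + 1L] >= thresh) hi <- hi + 1L
  keep <- lo:hi
  abund <- colSums(per_scan[keep, , drop = FALSE])
  obs_mz <- if (mz_acc_den > 0) mz_acc_num / mz_acc_den else NA_real_
  apex_scan <- inside[apex]
  width <- if (!spectra[[apex_scan]]$centroided)
    .profile_m0_width(spectra[[apex_scan]], targets[1], half[1])
  else NA_real_
  structure(
    list(abundances = abund,
         elution_start = rts[inside[lo]],
         elution_end = rts[inside[hi]],
         apex_rt = rts[apex_scan],
         ppm_error = (obs_mz - theo_mz) / theo_mz * 1e6,
         mono_width = width,
         source = source,
         n_scans = length(keep)),
    class = "isotopomer_xic"
  )
}

.smooth3 <- function(x) {
  if (length(x) < 3L) return(x)
  c(x[1], (x[-c(1, length(x))] + x[-(1:2)] + x[-((length(x) - 1):length(x))]) / 3,
    x[length(x)])
}

# FWHM of the monoisotopic peak measured from profile-mode points
.profile_m0_width <- function(sp, target, half) {
  sel <- sp$mz >= target - 2 * half & sp$mz <= target + 2 * half
  mz <- sp$mz[sel]; int <- sp$intensity[sel]
  if (length(mz) < 3L || max(int) <= 0) return(NA_real_)
  hm <- max(int) / 2
  above <- which(int >= hm)
  if (!length(above)) return(NA_real_)
  mz[max(above)] - mz[min(above)]
}

#' @export
print.isotopomer_xic <- function(x, ...) {
  cat(sprintf("Isotopomer XIC (%s): elution %.2f-%.2f min, apex %.2f, %d scans\n",
              x$source, x$elution_start, x$elution_end, x$apex_rt,
              x$n_scans))
  cat("  M0..M5:", format(signif(x$abundances, 5)), "\n")
  invisible(x)
}

#' Monoisotopic relative isotope abundance of an XIC
#'
#' The ratio of the monoisotopic abundance to the sum of the abundances of
#' all retained mass isotopomers: `M0 / sum(M0..M5)`.
#'
#' @param xic An `isotopomer_xic` (or bare numeric vector of abundances).
#' @return RIA in (0, 1].
#' @export
monoisotopic_ria <- function(xic) {
  a <- if (inherits(xic, "isotopomer_xic")) xic$abundances else xic
  tot <- sum(a)
  if (tot <= 0) stop("undefined RIA: total isotopomer abundance is zero")
  a[1] / tot
}

#' Absolute deviation between theoretical and observed isotope profiles
#'
#' `sum_i |theoretical_i - observed_i / sum(observed)|` over the retained
#' isotopomers; 0 for proportional profiles, 2 for disjoint ones.  Used as
#' the interference guard on unlabeled samples.
#'
#' @param theoretical An [isotope_pattern()].
#' @param observed An `isotopomer_xic` or numeric abundances.
#' @return Deviation in \[0, 2\].
#' @export
isotope_profile_deviation <- function(theoretical, observed) {
  th <- if (inherits(theoretical, "isotope_pattern"))
    theoretical$abundances else theoretical
  ob <- if (inherits(observed, "isotopomer_xic"))
    observed$abundances else observed
  tot <- sum(ob)
  if (tot <= 0) stop("undefined deviation: observed total abundance is zero")
  sum(abs(th - ob / tot))
}

# ---- retention-time alignment and match between runs --------------------

#' Monotone retention-time mapping between two runs
#'
#' Fits a monotone piecewise-linear mapping from reference RT to target RT
#' on the apex retention times of peptides identified in both runs.
#' Monotonicity is enforced by isotonic regression of the target RTs on the
#' reference RTs; between anchors the mapping interpolates linearly and
#' extrapolates by the boundary shift.  With fewer than 3 shared anchors the
#' identity mapping is returned with a warning.
#'
#' @param ref_rt,target_rt Apex retention times (minutes) of the shared
#'   peptides in the reference and target run.
#' @return A function mapping reference RT to target RT.
#' @export
align_retention_times <- function(ref_rt, target_rt) {
  stopifnot(length(ref_rt) == length(target_rt))
  ok <- is.finite(ref_rt) & is.finite(target_rt)
  ref_rt <- ref_rt[ok]; target_rt <- target_rt[ok]
  if (length(ref_rt) < 3L) {
    warning("fewer than 3 shared anchors; using identity RT mapping")
    return(identity)
  }
  ord <- order(ref_rt)
  x <- ref_rt[ord]; y <- target_rt[ord]
  yfit <- stats::isoreg(x, y)$yf
  ux <- !duplicated(x)
  x <- x[ux]; yfit <- yfit[ux]
  if (length(x) < 2L) return(identity)
  function(rt) {
    out <- stats::approx(x, yfit, xout = rt, rule = 2)$y
    # extrapolate by boundary offset rather than clamping
    below <- rt < x[1]; above <- rt > x[length(x)]
    out[below] <- rt[below] + (yfit[1] - x[1])
    out[above] <- rt[above] + (yfit[length(x)] - x[length(x)])
    out
  }
}

#' Transfer a quantification into a run lacking an identification
#'
#' Match-between-runs: anchors the extraction in the target run at the
#' donor run's apex RT mapped through the RT alignment, then extracts the
#' six-isotopomer profile with the MBR search window.  The result is
#' flagged `source = "mbr"`.  Returns `NULL` (missing point, never a zero)
#' when no monoisotopic signal is found.
#'
#' @param target_spectra `ms1_spectra` of the target run.
#' @param theo_mz,charge Peptide targeting parameters.
#' @param donor_apex_rt Apex RT (minutes) of the peptide in the donor run.
#' @param mapping RT mapping from donor to target
#'   ([align_retention_times()]).
#' @param mbr_rt_window Half-width of the MBR search window, minutes.
#' @param ppm_tol Mass tolerance in ppm.
#' @param ... Passed to [extract_isotope_profile()].
#' @return An `isotopomer_xic` with `source = "mbr"`, or `NULL`.
#' @export
mbr_transfer <- function(target_spectra, theo_mz, charge, donor_apex_rt,
                         mapping = identity, mbr_rt_window = 1.0,
                         ppm_tol = 10, ...) {
  anchor <- mapping(donor_apex_rt)
  extract_isotope_profile(target_spectra, theo_mz, charge, anchor,
                          rt_window = mbr_rt_window, ppm_tol = ppm_tol,
                          source = "mbr", ...)
}
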