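# fixture: spectra containing one peptide's six-isotopomer envelope
envelope_spectra <- function(theo_mz, charge, heights, rts,
                             per_scan_scale = rep(1, length(rts)),
                             extra_mz = NULL, extra_int = NULL,
                             constants = isotope_constants()) {
  targets <- theo_mz + (0:5) * constants$spacing / charge
  specs <- lapply(seq_along(rts), function(i) {
    mz <- c(targets, extra_mz)
    int <- c(heights * per_scan_scale[i], extra_int)
    ord <- order(mz)
    list(rt = rts[i], mz = mz[ord], intensity = int[ord], scan = i,
         centroided = TRUE)
  })
  structure(specs, class = "ms1_spectra", path = "<memory>",
            base_peaks = vapply(specs, function(s) max(s$intensity), 0))
}

test_that("a single-scan envelope integrates to its peak heights", {
  h <- c(500, 300, 150, 60, 20, 5)
  sp <- envelope_spectra(500.0, 2, h, rts = 10)
  x <- extract_isotope_profile(sp, 500.0, 2, anchor_rt = 10)
  expect_equal(x$abundances, h)
  expect_equal(x$apex_rt, 10)
  expect_equal(x$source, "identified")
})

test_that("a constant envelope over 5 scans integrates to 5x the heights", {
  h <- c(500, 300, 150, 60, 20, 5)
  rts <- seq(9.8, 10.2, by = 0.1)
  sp <- envelope_spectra(500.0, 2, h, rts = rts)
  x <- extract_isotope_profile(sp, 500.0, 2, anchor_rt = 10)
  expect_equal(x$abundances, 5 * h)
  expect_equal(x$elution_start, 9.8)
  expect_equal(x$elution_end, 10.2)
  expect_true(x$elution_start <= x$apex_rt && x$apex_rt <= x$elution_end)
})

test_that("peaks outside the ppm window are excluded", {
  h <- c(500, 300, 150, 60, 20, 5)
  off <- 500 * 30e-6   # 30 ppm away from M0 at 10 ppm tolerance
  sp <- envelope_spectra(500.0, 2, h, rts = 10,
                         extra_mz = 500.0 + off, extra_int = 1e6)
  x <- extract_isotope_profile(sp, 500.0, 2, anchor_rt = 10, ppm_tol = 10)
  expect_equal(x$abundances, h)
})

test_that("absent monoisotopic signal yields no result, not an error", {
  sp <- envelope_spectra(500.0, 2, rep(0, 6), rts = 10,
                         extra_mz = 900, extra_int = 100)
  expect_null(extract_isotope_profile(sp, 500.0, 2, anchor_rt = 10))
  expect_null(extract_isotope_profile(sp, 500.0, 2, anchor_rt = 50))
})

test_that("integration is linear and RIA is scale-invariant", {
  h <- c(500, 300, 150, 60, 20, 5)
  rts <- seq(9.7, 10.3, by = 0.1)
  gauss <- exp(-(rts - 10)^2 / 0.02)
  sp1 <- envelope_spectra(500.0, 2, h, rts, per_scan_scale = gauss)
  sp7 <- envelope_spectra(500.0, 2, h, rts, per_scan_scale = 7 * gauss)
  x1 <- extract_isotope_profile(sp1, 500.0, 2, anchor_rt = 10)
  x7 <- extract_isotope_profile(sp7, 500.0, 2, anchor_rt = 10)
  expect_equal(x7$abundances, 7 * x1$abundances, tolerance = 1e-12)
  expect_equal(monoisotopic_ria(x7), monoisotopic_ria(x1),
               tolerance = 1e-12)
})

test_that("monoisotopic RIA is M0 over the summed isotopomers", {
  expect_equal(monoisotopic_ria(c(1, 0, 0, 0, 0, 0)), 1)
  expect_equal(monoisotopic_ria(c(2, 1, 1, 0, 0, 0)), 0.5)
  expect_error(monoisotopic_ria(rep(0, 6)), "zero")
})

test_that("extracted RIA matches the labeling mixture model", {
  nat <- natural_isotope_pattern(composition_from_sequence("NLLSVAYK"),
                                 charge = 2)
  neh <- neh_of_sequence("NLLSVAYK")
  for (fs in c(0, 0.25, 0.5, 0.75, 1)) {
    patt <- labeled_pattern(nat, neh, 0.046, fs)
    sp <- envelope_spectra(nat$mono_mz, 2, 1e6 * patt$abundances, rts = 10)
    x <- extract_isotope_profile(sp, nat$mono_mz, 2, anchor_rt = 10)
    expect_equal(monoisotopic_ria(x), patt$abundances[1], tolerance = 1e-6)
  }
})

test_that("isotope profile deviation is an L1 distance on shares", {
  th <- c(0.5, 0.3, 0.12, 0.05, 0.02, 0.01)
  expect_equal(isotope_profile_deviation(th, th * 1234), 0)
  expect_equal(isotope_profile_deviation(c(1, 0, 0, 0, 0, 0),
                                         c(0, 1, 0, 0, 0, 0)), 2)
  set.seed(3)
  eps <- stats::rnorm(6, 0, 0.01)
  obs <- th + eps - sum(eps) * th      # keeps sum at 1
  obs <- obs / sum(obs)
  expect_equal(isotope_profile_deviation(th, obs), sum(abs(th - obs)))
  expect_error(isotope_profile_deviation(th, rep(0, 6)), "zero")
})

test_that("RT alignment recovers shifts and handles degenerate input", {
  ref <- seq(5, 25, by = 1)
  map <- align_retention_times(ref, ref + 0.5)
  expect_equal(map(seq(6, 24, by = 0.3)), seq(6, 24, by = 0.3) + 0.5,
               tolerance = 1e-9)
  ident <- align_retention_times(ref, ref)
  expect_equal(ident(10.37), 10.37, tolerance = 1e-9)
  expect_warning(m2 <- align_retention_times(c(1, 2), c(1, 2)), "identity")
  expect_equal(m2(3.3), 3.3)
})

test_that("RT alignment tracks a known nonlinear drift within scan spacing", {
  ref <- seq(5, 25, by = 0.5)
  drift <- function(x) x + 0.002 * (x - 5)^2
  map <- align_retention_times(ref, drift(ref))
  probe <- seq(5.25, 24.75, by = 0.5)
  expect_lt(max(abs(map(probe) - drift(probe))), 0.05)
  # monotone
  expect_true(all(diff(map(seq(5, 25, by = 0.1))) >= 0))
})

test_that("MBR transfer equals direct extraction at the same anchor", {
  h <- c(500, 300, 150, 60, 20, 5)
  rts <- seq(9.7, 10.3, by = 0.1)
  gauss <- exp(-(rts - 10)^2 / 0.02)
  sp <- envelope_spectra(500.0, 2, h, rts, per_scan_scale = gauss)
  direct <- extract_isotope_profile(sp, 500.0, 2, anchor_rt = 10)
  mbr <- mbr_transfer(sp, 500.0, 2, donor_apex_rt = 10)
  expect_equal(mbr$abundances, direct$abundances)
  expect_equal(mbr$source, "mbr")
  expect_null(mbr_transfer(sp, 800.0, 2, donor_apex_rt = 10))
})
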