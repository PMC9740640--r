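# numbers are rendered with 6 significant digits so re-runs are
# byte-identical regardless of platform printing defaults
.fmt6 <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
  out
}

.format_numeric_cols <- function(d) {
  for (nm in names(d)) if (is.numeric(d[[nm]])) d[[nm]] <- .fmt6(d[[nm]])
  d
}

#' Write the per-protein Quant and RateConst CSV files
#'
#' Emits `<EntryName>.Quant.csv` (one row per peptide per quantified
#' experiment: sequence, charge, theoretical m/z, the six theoretical
#' isotope abundances, precursor m/z, ion score, expectation, mass accuracy
#' in ppm, scan number, integrated M0..M5 abundances, elution bounds,
#' monoisotopic peak width, experiment and labeling time) and
#' `<EntryName>.RateConst.csv` (one row per accepted peptide: sequence,
#' uniqueness, rate constant with confidence interval, correlation, RMSE,
#' isotope-profile deviation, charge, m/z, NEH, NDP, R2, average
#' monoisotopic abundance; final row carries the protein rate and the
#' median-of-medians normalized abundance).
#'
#' @param results A [turnover_run()] result.
#' @param entry Protein entry name (must be present in `results`).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector with the two file paths.
#' @export
write_protein_files <- function(results, entry, out_dir = ".") {
  stopifnot(inherits(results, "turnover_results"))
  if (!grepl("^[A-Za-z0-9_.-]+$", entry))
    stop("invalid protein entry name: ", entry)
  prow <- results$proteins[results$proteins$protein == entry, , drop = FALSE]
  if (!nrow(prow)) stop("protein not in results: ", entry)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sel <- vapply(strsplit(results$peptides$proteins, ";"),
                function(v) entry %in% v, TRUE)
  peps <- results$peptides[sel, , drop = FALSE]
  keys <- paste(peps$sequence, peps$charge, sep = "/")

  quant <- do.call(rbind, results$quant[keys])
  quant$protein <- NULL
  quant_path <- file.path(out_dir, paste0(entry, ".Quant.csv"))
  utils::write.csv(.format_numeric_cols(quant), quant_path,
                   row.names = FALSE)

  rate <- data.frame(
    sequence = peps$sequence, uniqueness = peps$uniqueness,
    rate_constant = peps$k, ci_low = peps$ci_low, ci_high = peps$ci_high,
    correlation = peps$pearson_r, rmse = peps$rmse,
    profile_deviation = peps$profile_deviation, charge = peps$charge,
    mz = peps$theoretical_mz, neh = peps$neh, ndp = peps$ndp,
    r2 = peps$r2, avg_m0_abundance = peps$avg_m0_abundance,
    protein_rate = NA_real_, normalized_abundance = NA_real_,
    stringsAsFactors = FALSE)
  rate <- rbind(rate, data.frame(
    sequence = entry, uniqueness = "protein",
    rate_constant = prow$k, ci_low = NA_real_, ci_high = NA_real_,
    correlation = NA_real_, rmse = NA_real_, profile_deviation = NA_real_,
    charge = NA_integer_, mz = NA_real_, neh = NA_real_,
    ndp = prow$ndp_total, r2 = NA_real_,
    avg_m0_abundance = prow$avg_m0_abundance,
    protein_rate = prow$k, normalized_abundance = prow$normalized_abundance,
    stringsAsFactors = FALSE))
  rate_path <- file.path(out_dir, paste0(entry, ".RateConst.csv"))
  utils::write.csv(.format_numeric_cols(rate), rate_path, row.names = FALSE)
  c(quant = quant_path, rate = rate_path)
}

#' Write all per-protein files plus an aggregate summary
#'
#' One `.Quant.csv`/`.RateConst.csv` pair per protein, plus
#' `proteins_summary.csv` (a convenience aggregate, not part of the
#' canonical per-protein output) listing every protein's rate, peptide
#' count, total NDP and normalized abundance.
#'
#' @inheritParams write_protein_files
#' @return data.frame manifest of written paths, invisibly.
#' @export
write_outputs <- function(results, out_dir = ".") {
  stopifnot(inherits(results, "turnover_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (entry in results$proteins$protein) {
    paths <- write_protein_files(results, entry, out_dir)
    rows[[entry]] <- data.frame(protein = entry, quant = paths[["quant"]],
                                rate = paths[["rate"]],
                                stringsAsFactors = FALSE)
  }
  summary_path <- file.path(out_dir, "proteins_summary.csv")
  utils::write.csv(.format_numeric_cols(results$proteins), summary_path,
                   row.names = FALSE)
  invisible(do.call(rbind, rows))
}
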