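# ---- parameters ---------------------------------------------------------

#' Processing parameters for a turnover run
#'
#' @param ppm_tol Spectral mass accuracy for isotopomer extraction, ppm.
#' @param rt_window Retention-time half-window for peak detection and
#'   integration around the identification RT, minutes.
#' @param mbr_rt_window Half-window for match-between-runs searches,
#'   minutes.
#' @param min_score Minimum ion score for accepting a PSM.
#' @param max_expectation Maximum expectation value for accepting a PSM.
#' @param min_peptide_runs,min_protein_runs Identification-consistency
#'   minima: number of experiments in which a peptide / protein must be
#'   identified by MS/MS.
#' @param min_ndp Minimum number of time points for fitting a peptide.
#' @param use_mbr Quantify peptides in runs lacking an identification via
#'   match-between-runs, and include those points in the fit.
#' @param plateau `"pattern"`: the plateau RIA is the monoisotopic share of
#'   the fully labeled six-isotopomer pattern (consistent with the
#'   six-isotopomer RIA definition); `"closed_form"`: the analytic
#'   `I00 * ((1-pw)/(1-pH))^NEH`, which ignores truncation to six peaks.
#' @param r2_floor Optional minimum peptide R2 for entering the protein
#'   median (default `NULL`, off).
#' @param k_max Upper bound of the rate-constant search, per day.
#' @return List of class `turnover_params`.
#' @export
turnover_params <- function(ppm_tol = 10, rt_window = 1.0,
                            mbr_rt_window = 1.0, min_score = 20,
                            max_expectation = 0.05,
                            min_peptide_runs = 1L, min_protein_runs = 1L,
                            min_ndp = 3L, use_mbr = TRUE,
                            plateau = c("pattern", "closed_form"),
                            r2_floor = NULL, k_max = 10) {
  structure(list(ppm_tol = ppm_tol, rt_window = rt_window,
                 mbr_rt_window = mbr_rt_window, min_score = min_score,
                 max_expectation = max_expectation,
                 min_peptide_runs = min_peptide_runs,
                 min_protein_runs = min_protein_runs,
                 min_ndp = min_ndp, use_mbr = use_mbr,
                 plateau = match.arg(plateau), r2_floor = r2_floor,
                 k_max = k_max),
            class = "turnover_params")
}

# ---- main pipeline ------------------------------------------------------

#' Run the turnover pipeline on a set of labeling experiments
#'
#' Reads the mzML/mzid pair of every experiment, filters identifications,
#' applies the identification-consistency filter, integrates six-isotopomer
#' abundances per peptide per run (with match-between-runs transfer into
#' runs lacking an identification), assembles the monoisotopic-RIA time
#' series, fits the one-pool exponential decay per peptide and aggregates
#' protein rates as medians of peptide rates.
#'
#' @param experiments Experiment table: data.frame with columns
#'   `mzML_path`, `mzid_path`, `time_days`, `BWE`, or path to such a CSV
#'   ([read_experiment_table()]).
#' @param params A [turnover_params()].
#' @param table A [residue_table()].
#' @param constants An [isotope_constants()].
#' @param verbose Log per-stage counts.
#' @return Object of class `turnover_results`: list with `peptides`
#'   (data.frame of per-peptide fits), `fits` (named list of `ria_fit`),
#'   `series` (named list of `ria_series`), `proteins` (data.frame of
#'   protein rates and normalized abundances), `quant` (per peptide per
#'   experiment quantification rows), `skipped` (peptides not fitted, with
#'   reasons), `experiments`, `params`.
#' @export
turnover_run <- function(experiments, params = turnover_params(),
                         table = residue_table(),
                         constants = isotope_constants(),
                         verbose = TRUE) {
  if (is.character(experiments))
    experiments <- read_experiment_table(experiments)
  stopifnot(all(c("mzML_path", "mzid_path", "time_days", "BWE") %in%
                names(experiments)))
  nruns <- nrow(experiments)
  say <- function(...) if (verbose) message(sprintf(...))

  say("reading %d experiment(s)", nruns)
  spectra <- lapply(experiments$mzML_path, read_ms1_spectra)
  psms <- lapply(experiments$mzid_path, read_identifications,
                 min_score = params$min_score,
                 max_expectation = params$max_expectation)
  for (r in seq_len(nruns))
    say("  run %d (t = %g d): %d MS1 scans, %d PSMs after filtering", r,
        experiments$time_days[r], length(spectra[[r]]), nrow(psms[[r]]))

  obs <- do.call(rbind, lapply(seq_len(nruns), function(r) {
    p <- psms[[r]]
    if (!nrow(p)) return(NULL)
    # one observation row per parent protein of each PSM
    prots <- strsplit(p$proteins, ";", fixed = TRUE)
    idx <- rep(seq_len(nrow(p)), lengths(prots))
    data.frame(sequence = p$sequence[idx], charge = p$charge[idx],
               protein = unlist(prots), experiment = r,
               source = "identified", stringsAsFactors = FALSE)
  }))
  if (is.null(obs) || !nrow(obs))
    stop("no PSM passes the identification filters in any experiment")
  obs <- consistency_filter(obs, params$min_peptide_runs,
                            params$min_protein_runs)
  if (!nrow(obs)) stop("no peptide passes the consistency filters")
  say("consistency filter kept %d peptide/protein observations", nrow(obs))

  pep_key <- unique(paste(obs$sequence, obs$charge, sep = "/"))
  catalog <- do.call(rbind, lapply(pep_key, function(kk) {
    f <- strsplit(kk, "/", fixed = TRUE)[[1]]
    data.frame(key = kk, sequence = f[1], charge = as.integer(f[2]),
               stringsAsFactors = FALSE)
  }))
  catalog$neh <- vapply(catalog$sequence, neh_of_sequence, 0, table = table)
  nat <- lapply(seq_len(nrow(catalog)), function(i)
    natural_isotope_pattern(
      composition_from_sequence(catalog$sequence[i], table),
      charge = catalog$charge[i], constants = constants))
  catalog$theo_mz <- vapply(nat, `[[`, 0, "mono_mz")
  catalog$I00 <- vapply(nat, function(p) p$abundances[1], 0)
  # proteins and uniqueness per peptide (from any run's representative PSM)
  all_psm <- do.call(rbind, lapply(seq_len(nruns), function(r)
    cbind(psms[[r]], experiment = r)))
  rep_row <- all_psm[order(-all_psm$score), ]
  rep_row <- rep_row[!duplicated(paste(rep_row$sequence, rep_row$charge)), ]
  m <- match(paste(catalog$sequence, catalog$charge, sep = "/"),
             paste(rep_row$sequence, rep_row$charge, sep = "/"))
  catalog$proteins <- rep_row$proteins[m]
  catalog$uniqueness <- rep_row$uniqueness[m]

  # labeled-run enrichment for the plateau
  labeled <- experiments$time_days > 0
  pw_lab <- if (any(labeled)) stats::median(experiments$BWE[labeled])
            else stats::median(experiments$BWE)
  catalog$I0asymp <- vapply(seq_len(nrow(catalog)), function(i) {
    switch(params$plateau,
      pattern = labeled_pattern(nat[[i]], catalog$neh[i], pw_lab, 1,
                                constants = constants)$abundances[1],
      closed_form = plateau_ria(catalog$I00[i], pw_lab, constants,
                                catalog$neh[i]))
  }, 0)

  # ---- extraction: identified points ----
  id_key <- function(p) paste(p$sequence, p$charge, sep = "/")
  xics <- vector("list", nrow(catalog))
  names(xics) <- catalog$key
  for (i in seq_len(nrow(catalog))) xics[[i]] <- vector("list", nruns)
  for (r in seq_len(nruns)) {
    p <- psms[[r]]
    if (!nrow(p)) next
    keys <- id_key(p)
    for (j in seq_len(nrow(p))) {
      i <- match(keys[j], catalog$key)
      if (is.na(i)) next
      anchor <- p$rt[j]
      if (is.na(anchor)) {
        # fall back to the RT of the referenced scan
        sc <- match(p$scan[j], vapply(spectra[[r]], `[[`, 0L, "scan"))
        anchor <- if (is.na(sc)) NA_real_ else spectra[[r]][[sc]]$rt
      }
      if (is.na(anchor)) next
      xics[[i]][[r]] <- extract_isotope_profile(
        spectra[[r]], catalog$theo_mz[i], catalog$charge[i], anchor,
        rt_window = params$rt_window, ppm_tol = params$ppm_tol,
        source = "identified", constants = constants)
    }
  }

  # ---- MBR: fill runs lacking an identification ----
  if (params$use_mbr) {
    apex_of <- function(i, r) {
      x <- xics[[i]][[r]]
      if (is.null(x)) NA_real_ else x$apex_rt
    }
    mappings <- vector("list", nruns)   # donor -> target maps, built lazily
    get_mapping <- function(donor, target) {
      if (donor == target) return(identity)
      key <- sprintf("%d->%d", donor, target)
      if (!is.null(mappings[[donor]][[key]]))
        return(mappings[[donor]][[key]])
      shared <- which(vapply(seq_len(nrow(catalog)), function(i)
        !is.na(apex_of(i, donor)) && !is.na(apex_of(i, target)) &&
          xics[[i]][[donor]]$source == "identified" &&
          xics[[i]][[target]]$source == "identified", TRUE))
      map <- suppressWarnings(align_retention_times(
        vapply(shared, apex_of, 0, r = donor),
        vapply(shared, apex_of, 0, r = target)))
      if (is.null(mappings[[donor]])) mappings[[donor]] <<- list()
      mappings[[donor]][[key]] <<- map
      map
    }
    n_mbr <- 0L
    for (i in seq_len(nrow(catalog))) {
      have <- which(!vapply(xics[[i]], is.null, TRUE))
      if (!length(have)) next
      donors <- have
      for (r in setdiff(seq_len(nruns), have)) {
        donor <- donors[which.max(vapply(donors, function(d)
          sum(xics[[i]][[d]]$abundances), 0))]
        x <- mbr_transfer(spectra[[r]], catalog$theo_mz[i],
                          catalog$charge[i], apex_of(i, donor),
                          mapping = get_mapping(donor, r),
                          mbr_rt_window = params$mbr_rt_window,
                          ppm_tol = params$ppm_tol, constants = constants)
        if (!is.null(x)) { xics[[i]][[r]] <- x; n_mbr <- n_mbr + 1L }
      }
    }
    say("match between runs transferred %d quantification(s)", n_mbr)
  }

  # ---- quant rows, series, fits ----
  quant <- list(); series <- list(); fits <- list(); skipped <- list()
  unlabeled_runs <- which(experiments$time_days == 0)
  pep_rows <- list()
  for (i in seq_len(nrow(catalog))) {
    have <- which(!vapply(xics[[i]], is.null, TRUE))
    if (!length(have)) {
      skipped[[catalog$key[i]]] <- "no quantifiable signal in any run"
      next
    }
    nat_i <- nat[[i]]
    psm_i <- rep_row[m[i], ]
    qr <- lapply(have, function(r) {
      x <- xics[[i]][[r]]
      data.frame(
        sequence = catalog$sequence[i], charge = catalog$charge[i],
        protein = catalog$proteins[i],
        theoretical_mz = catalog$theo_mz[i],
        t(stats::setNames(nat_i$abundances, paste0("theo_M", 0:5))),
        precursor_mz = psm_i$precursor_mz, ion_score = psm_i$score,
        expectation = psm_i$expectation,
        ppm_error = x$ppm_error, scan = psm_i$scan,
        t(stats::setNames(x$abundances, paste0("M", 0:5))),
        elution_start = x$elution_start, elution_end = x$elution_end,
        mono_peak_width = x$mono_width, source = x$source,
        experiment = r, time_days = experiments$time_days[r],
        check.names = FALSE, stringsAsFactors = FALSE)
    })
    quant[[catalog$key[i]]] <- do.call(rbind, qr)
    ria <- vapply(have, function(r) monoisotopic_ria(xics[[i]][[r]]), 0)
    src <- vapply(have, function(r) xics[[i]][[r]]$source, "")
    s <- tryCatch(
      ria_series(experiments$time_days[have], pmin(ria, 1), catalog$I00[i],
                 catalog$I0asymp[i], source = src, experiment = have,
                 sequence = catalog$sequence[i], charge = catalog$charge[i],
                 neh = catalog$neh[i]),
      error = function(e) NULL)
    if (is.null(s)) {
      skipped[[catalog$key[i]]] <- "invalid RIA series"
      next
    }
    series[[catalog$key[i]]] <- s
    f <- tryCatch(fit_rate(s, min_ndp = params$min_ndp,
                           k_max = params$k_max,
                           use_mbr = params$use_mbr),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) { skipped[[catalog$key[i]]] <- f; next }
    fits[[catalog$key[i]]] <- f
    dev0 <- NA_real_
    u <- intersect(unlabeled_runs, have)
    if (length(u))
      dev0 <- mean(vapply(u, function(r)
        isotope_profile_deviation(nat_i, xics[[i]][[r]]), 0))
    pep_rows[[catalog$key[i]]] <- data.frame(
      sequence = catalog$sequence[i], charge = catalog$charge[i],
      proteins = catalog$proteins[i], uniqueness = catalog$uniqueness[i],
      k = f$k, ci_low = f$ci_low, ci_high = f$ci_high,
      pearson_r = f$pearson_r, rmse = f$rmse, sd = f$sd, r2 = f$r2,
      profile_deviation = dev0, theoretical_mz = catalog$theo_mz[i],
      neh = catalog$neh[i], ndp = f$ndp, n_mbr = sum(src == "mbr"),
      avg_m0_abundance = mean(vapply(have, function(r)
        xics[[i]][[r]]$abundances[1], 0)),
      stringsAsFactors = FALSE)
  }
  if (!length(fits)) stop("no peptide could be fitted")
  peptides <- do.call(rbind, pep_rows)
  rownames(peptides) <- NULL

  # ---- protein aggregation ----
  # per-experiment base-peak intensities; scans without signal carry no
  # base peak and are excluded from the experiment median
  base_peaks <- lapply(spectra, function(s) {
    b <- attr(s, "base_peaks")
    b[b > 0]
  })
  prot_names <- sort(unique(unlist(strsplit(peptides$proteins, ";"))))
  prot_rows <- list()
  prot_objects <- list()
  for (pn in prot_names) {
    sel <- vapply(strsplit(peptides$proteins, ";"), function(v) pn %in% v,
                  TRUE)
    keys <- paste(peptides$sequence[sel], peptides$charge[sel], sep = "/")
    ps <- tryCatch(protein_rate(fits[keys], entry = pn,
                                r2_floor = params$r2_floor),
                   error = function(e) NULL)
    if (is.null(ps)) next
    abundance <- mean(peptides$avg_m0_abundance[sel])
    prot_objects[[pn]] <- ps
    prot_rows[[pn]] <- data.frame(
      protein = pn, k = ps$k, n_peptides = ps$n_peptides,
      ndp_total = ps$ndp_total, avg_m0_abundance = abundance,
      normalized_abundance =
        normalized_protein_abundance(abundance, base_peaks),
      stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot_rows)
  rownames(proteins) <- NULL
  say("fitted %d peptide(s) across %d protein(s); %d skipped",
      length(fits), nrow(proteins), length(skipped))
  structure(
    list(peptides = peptides, fits = fits, series = series,
         proteins = proteins, protein_objects = prot_objects,
         quant = quant, skipped = skipped, experiments = experiments,
         params = params),
    class = "turnover_results"
  )
}

#' @export
print.turnover_results <- function(x, ...) {
  cat(sprintf("Turnover analysis: %d experiments, %d peptides fitted, %d proteins\n",
              nrow(x$experiments), nrow(x$peptides), nrow(x$proteins)))
  cat(sprintf("Median protein rate: %.4f /day\n",
              stats::median(x$proteins$k)))
  invisible(x)
}

#' @export
summary.turnover_results <- function(object, ...) {
  print(object)
  cat("\nProteins:\n")
  print(object$proteins, digits = 4)
  if (length(object$skipped)) {
    cat("\nSkipped peptides:\n")
    for (nm in names(object$skipped))
      cat("  ", nm, ": ", object$skipped[[nm]], "\n", sep = "")
  }
  invisible(object)
}
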