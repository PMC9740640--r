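# ---- minimal writers ----------------------------------------------------
# Text-XML writers for the subset of mzML/mzIdentML the readers consume.
# Numbers are printed with fixed formats so identical inputs give
# byte-identical files.

.b64 <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                  size = 8, endian = "little"))

#' Write MS1 spectra to a minimal mzML file
#'
#' Emits a schema-shaped mzML document (64-bit little-endian uncompressed
#' peak arrays, retention time in minutes, centroid or profile flag) that
#' standard readers parse.
#'
#' @param spectra List of spectra: each a list with `rt` (minutes), `mz`,
#'   `intensity`, and optionally `scan` and `ms_level` (default 1); scans
#'   are written in list order.
#' @param path Output path.
#' @param centroided Logical peak mode flag written to every spectrum.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path, centroided = TRUE) {
  mode_cv <- if (centroided)
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  blocks <- character(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    scan <- if (is.null(sp$scan)) i else sp$scan
    level <- if (is.null(sp$ms_level)) 1L else sp$ms_level
    emz <- .b64(sp$mz); eint <- .b64(sp$intensity)
    blocks[i] <- paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, scan, length(sp$mz)),
      sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>\n',
              level),
      mode_cv, '\n',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      sprintf('<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>\n',
              sp$rt),
      '<binaryDataArrayList count="2">\n',
      sprintf('<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/><binary>%s</binary></binaryDataArray>\n',
              nchar(emz), emz),
      sprintf('<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>\n',
              nchar(eint), eint),
      '</binaryDataArrayList>\n</spectrum>')
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="UNIT-ONTOLOGY" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sim" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="sim"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="sim"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">\n',
            length(spectra)),
    paste(blocks, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(doc, path, sep = "")
  invisible(path)
}

#' Write peptide-spectrum matches to a minimal mzIdentML file
#'
#' Mascot-dialect mzid: one SpectrumIdentificationResult per PSM carrying
#' ion score and expectation value cvParams plus the scan start time.
#'
#' @param psms data.frame with columns `sequence`, `charge`, `mz`, `scan`,
#'   `rt` (minutes), `score`, `expectation`, `protein` (entry name),
#'   `accession` (optional).
#' @param path Output path.
#' @param spectra_file Name recorded as the source spectra file.
#' @return `path`, invisibly.
#' @export
write_mzid <- function(psms, path, spectra_file = "run.mzML") {
  stopifnot(all(c("sequence", "charge", "mz", "scan", "rt", "score",
                  "expectation", "protein") %in% names(psms)))
  if (is.null(psms$accession)) psms$accession <- psms$protein
  prot <- unique(psms[, c("protein", "accession")])
  dbseq <- sprintf(
    '<DBSequence id="DBSeq_%s" accession="%s" searchDatabase_ref="SDB_1"><cvParam accession="MS:1001088" cvRef="PSI-MS" name="protein description" value="%s synthetic entry"/></DBSequence>',
    prot$protein, prot$accession, prot$protein)
  pep_ids <- paste0("Pep_", seq_len(nrow(psms)))
  peps <- sprintf('<Peptide id="%s"><PeptideSequence>%s</PeptideSequence></Peptide>',
                  pep_ids, psms$sequence)
  evs <- sprintf(
    '<PeptideEvidence id="PE_%d" peptide_ref="%s" dBSequence_ref="DBSeq_%s" isDecoy="false" start="1" end="%d" pre="K" post="A"/>',
    seq_len(nrow(psms)), pep_ids, psms$protein, nchar(psms$sequence))
  sirs <- sprintf(paste0(
    '<SpectrumIdentificationResult id="SIR_%d" spectrumID="scan=%d" spectraData_ref="SD_1">\n',
    '<SpectrumIdentificationItem id="SII_%d_1" chargeState="%d" experimentalMassToCharge="%.6f" calculatedMassToCharge="%.6f" peptide_ref="%s" rank="1" passThreshold="true">\n',
    '<PeptideEvidenceRef peptideEvidence_ref="PE_%d"/>\n',
    '<cvParam accession="MS:1001171" cvRef="PSI-MS" name="Mascot:score" value="%.4f"/>\n',
    '<cvParam accession="MS:1001172" cvRef="PSI-MS" name="Mascot:expectation value" value="%.6g"/>\n',
    '</SpectrumIdentificationItem>\n',
    '<cvParam accession="MS:1000016" cvRef="PSI-MS" name="scan start time" value="%.4f" unitAccession="UO:0000010" unitName="second" unitCvRef="UO"/>\n',
    '</SpectrumIdentificationResult>'),
    seq_len(nrow(psms)), psms$scan, seq_len(nrow(psms)), psms$charge,
    psms$mz, psms$mz, pep_ids, seq_len(nrow(psms)), psms$score,
    psms$expectation, psms$rt * 60)
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<MzIdentML id="MZID" version="1.1.0" xmlns="http://psidev.info/psi/pi/mzIdentML/1.1" creationDate="2022-01-01T00:00:00">\n',
    '<cvList>\n',
    '<cv id="PSI-MS" fullName="PSI-MS" uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="UNIT-ONTOLOGY" uri="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<AnalysisSoftwareList><AnalysisSoftware id="AS_mascot" name="Mascot" version="2.6"><SoftwareName><cvParam accession="MS:1001207" cvRef="PSI-MS" name="Mascot"/></SoftwareName></AnalysisSoftware></AnalysisSoftwareList>\n',
    '<SequenceCollection>\n',
    paste(dbseq, collapse = "\n"), "\n",
    paste(peps, collapse = "\n"), "\n",
    paste(evs, collapse = "\n"), "\n",
    '</SequenceCollection>\n',
    '<AnalysisCollection><SpectrumIdentification id="SI" spectrumIdentificationProtocol_ref="SIP" spectrumIdentificationList_ref="SIL"><InputSpectra spectraData_ref="SD_1"/><SearchDatabaseRef searchDatabase_ref="SDB_1"/></SpectrumIdentification></AnalysisCollection>\n',
    '<AnalysisProtocolCollection><SpectrumIdentificationProtocol id="SIP" analysisSoftware_ref="AS_mascot"><SearchType><cvParam accession="MS:1001083" cvRef="PSI-MS" name="ms-ms search"/></SearchType><Threshold><cvParam accession="MS:1001494" cvRef="PSI-MS" name="no threshold"/></Threshold></SpectrumIdentificationProtocol></AnalysisProtocolCollection>\n',
    '<DataCollection>\n<Inputs>\n',
    '<SearchDatabase id="SDB_1" location="file:///synthetic.fasta"><DatabaseName><userParam name="synthetic"/></DatabaseName></SearchDatabase>\n',
    sprintf('<SpectraData id="SD_1" location="file:///%s"><FileFormat><cvParam accession="MS:1000584" cvRef="PSI-MS" name="mzML format"/></FileFormat><SpectrumIDFormat><cvParam accession="MS:1000776" cvRef="PSI-MS" name="scan number only nativeID format"/></SpectrumIDFormat></SpectraData>\n',
            spectra_file),
    '</Inputs>\n<AnalysisData>\n<SpectrumIdentificationList id="SIL">\n',
    paste(sirs, collapse = "\n"),
    '\n</SpectrumIdentificationList>\n</AnalysisData>\n</DataCollection>\n</MzIdentML>\n')
  writeLines(doc, path, sep = "")
  invisible(path)
}

# ---- simulation design --------------------------------------------------

#' Default simulated peptide panel
#'
#' Three synthetic proteins with five tryptic-style peptides each, spanning
#' slow to fast turnover (k from 0.02 to 0.6 per day) — the range typical of
#' liver proteins over a month of labeling.
#'
#' @return data.frame with columns `sequence`, `charge`, `protein`, `k`,
#'   `scale`, `apex_rt`, `peak_sd`.
#' @export
simulated_peptides <- function() {
  d <- data.frame(
    sequence = c("SDEAVKPLGVK", "LVTDLTK", "AGFAGDDAPR", "VAPEEHPVLLTEAPLNPK",
                 "GYSFTTTAER",
                 "NLLSVAYK", "DSTLIMQLLR", "AVFPSIVGRPR", "HQGVMVGMGQK",
                 "EITALAPSTMK",
                 "IWHHTFYNELR", "DLTDYLMK", "SYELPDGQVITIGNER", "TTGIVMDSGDGVTH",
                 "QEYDESGPSIVHR"),
    charge = c(2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 3L),
    protein = rep(c("FAS_SYN", "ACTB_SYN", "ALBU_SYN"), each = 5L),
    k = rep(c(0.12, 0.035, 0.30), each = 5L) *
      c(1, 0.9, 1.1, 1.05, 0.95, 1, 1.15, 0.85, 1.05, 0.95,
        1, 0.9, 1.1, 1.2, 0.8),
    scale = rep(c(2e6, 5e6, 1e6), each = 5L),
    stringsAsFactors = FALSE
  )
  d$apex_rt <- seq(10, 24, length.out = nrow(d))
  d$peak_sd <- 0.08
  d
}

#' Simulation design for a labeling time course
#'
#' Defaults mirror a month-long murine heavy-water study: twelve labeling
#' time points at 0, 1, 2, 3, 6, 7, 9, 13, 16, 21, 24 and 31 days and a
#' body-water deuterium enrichment of 0.046 in all labeled samples.
#'
#' @param time_points Labeling durations in days, one experiment each.
#' @param pw Body-water enrichment; scalar or one value per time point.
#' @param noise_sigma Multiplicative intensity noise SD (0 = noiseless).
#' @param scan_interval MS1 scan spacing in minutes.
#' @param ppm_jitter SD of random mass error applied to peak m/z, in ppm.
#' @param seed RNG seed; identical seeds give byte-identical fixture files.
#' @param drop_ids Named list: `"<sequence>/<charge>"` -> integer vector of
#'   run indices whose mzid omits that peptide (exercises MBR).
#' @param profile Write profile-mode spectra instead of centroided peaks.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(time_points = c(0, 1, 2, 3, 6, 7, 9, 13, 16,
                                              21, 24, 31),
                              pw = 0.046, noise_sigma = 0,
                              scan_interval = 0.05, ppm_jitter = 0,
                              seed = 1L, drop_ids = list(),
                              profile = FALSE) {
  stopifnot(all(time_points >= 0), all(pw >= 0 & pw < 1),
            noise_sigma >= 0, scan_interval > 0)
  if (length(pw) == 1L) pw <- rep(pw, length(time_points))
  stopifnot(length(pw) == length(time_points))
  structure(list(time_points = time_points, pw = pw,
                 noise_sigma = noise_sigma, scan_interval = scan_interval,
                 ppm_jitter = ppm_jitter, seed = as.integer(seed),
                 drop_ids = drop_ids, profile = profile),
            class = "simulation_design")
}

# ---- generator ----------------------------------------------------------

#' Generate a synthetic labeled experiment set
#'
#' Writes one mzML/mzid pair per labeling time point.  Each run's MS1 scans
#' contain, for every peptide, a six-isotopomer envelope whose pattern is
#' the labeling mixture model at fractional synthesis `1 - exp(-k t)`, with
#' a Gaussian chromatographic profile and optional multiplicative intensity
#' noise.  The generator is decay-model-consistent by construction: the
#' per-run monoisotopic share follows the exponential interpolation between
#' the natural and plateau shares (up to pattern truncation).
#'
#' @param peptides data.frame as [simulated_peptides()].
#' @param design A [simulation_design()].
#' @param out_dir Output directory (created if needed).
#' @param table A [residue_table()]; `constants` an [isotope_constants()].
#' @param constants Isotope constants.
#' @return List with `experiments` (data.frame: mzML_path, mzid_path,
#'   time_days, BWE), `truth` (data.frame of per-peptide ground truth:
#'   sequence, charge, protein, k, neh, I00_share, plateau_share, and the
#'   per-run expected M0 share), and `truth_path` (CSV on disk).
#' @export
simulate_experiment_set <- function(peptides, design,
                                    out_dir = tempfile("simset"),
                                    table = residue_table(),
                                    constants = isotope_constants()) {
  stopifnot(inherits(design, "simulation_design"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(design$seed)
  np <- nrow(peptides)
  comp <- lapply(peptides$sequence, composition_from_sequence, table = table)
  neh <- vapply(peptides$sequence, neh_of_sequence, 0, table = table)
  nat <- mapply(function(cc, z) natural_isotope_pattern(cc, charge = z,
                                                        constants = constants),
                comp, peptides$charge, SIMPLIFY = FALSE)
  theo_mz <- vapply(nat, `[[`, 0, "mono_mz")
  nruns <- length(design$time_points)
  exp_tab <- data.frame(mzML_path = character(nruns),
                        mzid_path = character(nruns),
                        time_days = design$time_points, BWE = design$pw,
                        stringsAsFactors = FALSE)
  m0_share <- matrix(NA_real_, np, nruns)
  rt_grid <- seq(min(peptides$apex_rt) - 1.5, max(peptides$apex_rt) + 1.5,
                 by = design$scan_interval)
  for (r in seq_len(nruns)) {
    t_r <- design$time_points[r]
    pw_r <- design$pw[r]
    patt <- vector("list", np)
    for (j in seq_len(np)) {
      fs <- 1 - exp(-peptides$k[j] * t_r)
      patt[[j]] <- labeled_pattern(nat[[j]], neh[j], pw_r, fs,
                                   constants = constants)
      m0_share[j, r] <- patt[[j]]$abundances[1]
    }
    spectra <- vector("list", length(rt_grid))
    for (i in seq_along(rt_grid)) {
      rt <- rt_grid[i]
      mzs <- numeric(0); ints <- numeric(0)
      for (j in seq_len(np)) {
        g <- exp(-(rt - peptides$apex_rt[j])^2 / (2 * peptides$peak_sd[j]^2))
        if (g < 1e-5) next
        targets <- theo_mz[j] +
          (0:5) * constants$spacing / peptides$charge[j]
        h <- peptides$scale[j] * g * patt[[j]]$abundances
        if (design$noise_sigma > 0)
          h <- h * pmax(0, 1 + stats::rnorm(6, 0, design$noise_sigma))
        if (design$ppm_jitter > 0)
          targets <- targets *
            (1 + stats::rnorm(6, 0, design$ppm_jitter) * 1e-6)
        if (design$profile) {
          # 7-point Gaussian profile per isotopomer, sd 0.004 Th
          off <- seq(-0.012, 0.012, by = 0.004)
          pm <- as.vector(outer(off, targets, `+`))
          pi_ <- as.vector(outer(exp(-off^2 / (2 * 0.004^2)), h))
          mzs <- c(mzs, pm); ints <- c(ints, pi_)
        } else {
          mzs <- c(mzs, targets); ints <- c(ints, h)
        }
      }
      ord <- order(mzs)
      spectra[[i]] <- list(rt = rt, mz = mzs[ord], intensity = ints[ord],
                           scan = i)
    }
    stem <- sprintf("run%02d", r)
    mzml_path <- file.path(out_dir, paste0(stem, ".mzML"))
    mzid_path <- file.path(out_dir, paste0(stem, ".mzid"))
    write_mzml(spectra, mzml_path, centroided = !design$profile)
    keep <- vapply(seq_len(np), function(j) {
      key <- paste(peptides$sequence[j], peptides$charge[j], sep = "/")
      !(r %in% design$drop_ids[[key]])
    }, TRUE)
    psms <- data.frame(
      sequence = peptides$sequence[keep],
      charge = peptides$charge[keep],
      mz = theo_mz[keep],
      scan = vapply(peptides$apex_rt[keep],
                    function(a) which.min(abs(rt_grid - a)), 0L),
      rt = peptides$apex_rt[keep],
      score = 60 + 2 * seq_len(sum(keep)),
      expectation = 1e-3,
      protein = peptides$protein[keep],
      stringsAsFactors = FALSE
    )
    write_mzid(psms, mzid_path, spectra_file = basename(mzml_path))
    exp_tab$mzML_path[r] <- mzml_path
    exp_tab$mzid_path[r] <- mzid_path
  }
  truth <- data.frame(
    sequence = peptides$sequence, charge = peptides$charge,
    protein = peptides$protein, k = peptides$k, neh = neh,
    apex_rt = peptides$apex_rt,
    I00_share = vapply(nat, function(p) p$abundances[1], 0),
    plateau_share = vapply(seq_len(np), function(j)
      labeled_pattern(nat[[j]], neh[j],
                      design$pw[which.max(design$time_points)], 1,
                      constants = constants)$abundances[1], 0),
    stringsAsFactors = FALSE
  )
  share_cols <- as.data.frame(m0_share)
  names(share_cols) <- sprintf("m0_share_run%02d", seq_len(nruns))
  truth <- cbind(truth, share_cols)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  exp_path <- file.path(out_dir, "experiments.csv")
  utils::write.csv(exp_tab, exp_path, row.names = FALSE)
  list(experiments = exp_tab, truth = truth, truth_path = truth_path,
       experiments_path = exp_path, out_dir = out_dir)
}
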