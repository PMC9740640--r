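# ---- mzML ---------------------------------------------------------------

#' Read MS1 spectra from an mzML file
#'
#' Returns only MS-level-1 spectra, ordered by retention time.  Peak mode
#' (centroid/profile) is taken from the file metadata.
#'
#' @param path Path to an mzML file.
#' @return Object of class `ms1_spectra`: list of spectra, each a list with
#'   `scan` (acquisition number), `rt` (retention time, minutes), `mz`,
#'   `intensity`, `centroided` (logical).  Attributes: `path`, `base_peaks`
#'   (per-spectrum maximum intensity).
#' @export
read_ms1_spectra <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e)
                       stop("malformed mzML file ", path, ": ",
                            conditionMessage(e)))
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) {
    warning("no MS1 spectra in ", path)
    return(structure(list(), class = "ms1_spectra", path = path,
                     base_peaks = numeric(0)))
  }
  if (any(is.na(hd$retentionTime[ms1])))
    stop("MS1 spectrum without retention time in ", path)
  ms1 <- ms1[order(hd$retentionTime[ms1])]
  pk <- mzR::peaks(handle, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- vector("list", length(ms1))
  bp <- numeric(length(ms1))
  for (i in seq_along(ms1)) {
    m <- pk[[i]]
    spectra[[i]] <- list(
      scan = hd$acquisitionNum[ms1[i]],
      rt = hd$retentionTime[ms1[i]] / 60,   # mzR reports seconds
      mz = m[, 1], intensity = m[, 2],
      centroided = isTRUE(hd$centroided[ms1[i]])
    )
    bp[i] <- if (nrow(m)) max(m[, 2]) else 0
  }
  structure(spectra, class = "ms1_spectra", path = path, base_peaks = bp)
}

#' @export
print.ms1_spectra <- function(x, ...) {
  cat(sprintf("%d MS1 spectra from %s\n", length(x),
              basename(attr(x, "path"))))
  if (length(x))
    cat(sprintf("  RT %.2f .. %.2f min, %s mode\n", x[[1]]$rt,
                x[[length(x)]]$rt,
                if (x[[1]]$centroided) "centroid" else "profile"))
  invisible(x)
}

# ---- mzIdentML ----------------------------------------------------------

#' Read and filter peptide-spectrum matches from an mzid file
#'
#' Reads Mascot-style identifications (ion score, expectation value),
#' applies the score and expectation thresholds, and keeps per
#' (sequence, charge) the highest-scoring PSM as representative.  Parent
#' protein entry names are collected across the peptide's evidences;
#' uniqueness is `"distinct"` for a single parent, `"shared"` otherwise.
#'
#' @param path Path to an mzIdentML file.
#' @param min_score Minimum ion score (default 20).
#' @param max_expectation Maximum expectation value (default 0.05).
#' @return data.frame of class `psm_table` with columns `sequence`,
#'   `charge`, `precursor_mz`, `scan`, `score`, `expectation`, `rt`
#'   (minutes, NA when the file carries none), `proteins`
#'   (";"-separated entry names), `uniqueness`.
#' @export
read_identifications <- function(path, min_score = 20,
                                 max_expectation = 0.05) {
  if (!file.exists(path)) stop("mzid file not found: ", path)
  handle <- tryCatch(mzR::openIDfile(path),
                     error = function(e)
                       stop("malformed mzid file ", path, ": ",
                            conditionMessage(e)))
  p <- mzR::psms(handle)
  s <- mzR::score(handle)
  if (!nrow(p))
    return(structure(
      data.frame(sequence = character(), charge = integer(),
                 precursor_mz = numeric(), scan = integer(),
                 score = numeric(), expectation = numeric(), rt = numeric(),
                 proteins = character(), uniqueness = character()),
      class = c("psm_table", "data.frame")))
  score_col <- grep("Mascot\\.score", names(s), value = TRUE)[1]
  expect_col <- grep("expectation", names(s), value = TRUE)[1]
  if (is.na(score_col))
    stop("no Mascot score field in ", path)
  key <- paste(p$spectrumID, p$sequence, p$chargeState)
  # one row per (spectrum, peptide, charge); proteins pooled over evidences
  first <- !duplicated(key)
  prot_of <- function(desc, acc) {
    entry <- sub("\\s.*$", "", desc)
    ifelse(nzchar(entry) & !is.na(entry), entry, acc)
  }
  prots <- tapply(prot_of(p$DatabaseDescription, p$DatabaseAccess), key,
                  function(v) paste(sort(unique(v)), collapse = ";"))
  rt <- if ("scan.start.time" %in% names(p))
    suppressWarnings(as.numeric(p$scan.start.time)) / 60 else NA_real_
  d <- data.frame(
    sequence = p$sequence[first],
    charge = as.integer(p$chargeState[first]),
    precursor_mz = p$experimentalMassToCharge[first],
    scan = p$acquisitionNum[first],
    score = s[[score_col]][match(p$spectrumID[first], s$spectrumID)],
    expectation = if (!is.na(expect_col))
      s[[expect_col]][match(p$spectrumID[first], s$spectrumID)]
      else NA_real_,
    rt = if (length(rt) > 1) rt[first] else rt,
    proteins = as.character(prots[key[first]]),
    stringsAsFactors = FALSE
  )
  no_score <- is.na(d$score)
  if (any(no_score)) {
    warning(sum(no_score), " PSM(s) without score excluded in ",
            basename(path))
    d <- d[!no_score, , drop = FALSE]
  }
  d <- d[d$score >= min_score &
           (is.na(d$expectation) | d$expectation <= max_expectation), ,
         drop = FALSE]
  # representative per (sequence, charge): highest score
  d <- d[order(d$sequence, d$charge, -d$score), , drop = FALSE]
  d <- d[!duplicated(paste(d$sequence, d$charge)), , drop = FALSE]
  d$uniqueness <- ifelse(grepl(";", d$proteins), "shared", "distinct")
  rownames(d) <- NULL
  structure(d, class = c("psm_table", "data.frame"))
}

# ---- input pairing and experiment table ---------------------------------

#' Pair mzML and mzid files by filename stem
#'
#' Matches files in a folder on their shared stem (case-insensitive,
#' extension stripped, optional decoration suffixes removed).  Unmatched
#' files are reported with a message.
#'
#' @param folder Directory to scan.
#' @param strip_suffixes Character vector of stem decorations to remove
#'   before matching (default `"_msms"`).
#' @return data.frame with columns `mzML_path`, `mzid_path`, in stem order.
#' @export
match_input_pairs <- function(folder, strip_suffixes = "_msms") {
  files <- list.files(folder, full.names = TRUE)
  ext <- tolower(tools::file_ext(files))
  stem_of <- function(f) {
    s <- tolower(tools::file_path_sans_ext(basename(f)))
    for (suf in strip_suffixes) s <- sub(paste0(suf, "$"), "", s)
    s
  }
  mzml <- files[ext == "mzml"]; mzid <- files[ext == "mzid"]
  sm <- vapply(mzml, stem_of, ""); si <- vapply(mzid, stem_of, "")
  if (anyDuplicated(sm))
    stop("mzML stem collision: ",
         paste(sm[duplicated(sm)], collapse = ", "))
  if (anyDuplicated(si))
    stop("mzid stem collision: ",
         paste(si[duplicated(si)], collapse = ", "))
  shared <- intersect(sm, si)
  shared <- shared[order(shared)]
  unmatched <- c(mzml[!sm %in% shared], mzid[!si %in% shared])
  if (length(unmatched))
    message("unmatched input file(s): ",
            paste(basename(unmatched), collapse = ", "))
  data.frame(mzML_path = unname(mzml[match(shared, sm)]),
             mzid_path = unname(mzid[match(shared, si)]),
             stringsAsFactors = FALSE)
}

#' Read an experiment table
#'
#' CSV with columns `mzML_path`, `mzid_path`, `time_days`, `BWE` — one row
#' per labeling experiment, mirroring the input table of the turnover
#' workflow (file pair, labeling duration, body-water enrichment).
#'
#' @param path CSV path.  Relative file paths are resolved against the CSV's
#'   directory.
#' @return Validated data.frame.
#' @export
read_experiment_table <- function(path) {
  if (!file.exists(path)) stop("experiment table not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mzML_path", "mzid_path", "time_days", "BWE")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("experiment table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(d)) stop("experiment table is empty: ", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  d$mzML_path <- resolve(d$mzML_path)
  d$mzid_path <- resolve(d$mzid_path)
  if (any(d$time_days < 0)) stop("labeling times must be >= 0")
  if (any(d$BWE < 0 | d$BWE >= 1)) stop("BWE must lie in [0, 1)")
  missing_files <- c(d$mzML_path[!file.exists(d$mzML_path)],
                     d$mzid_path[!file.exists(d$mzid_path)])
  if (length(missing_files))
    stop("input file(s) not found: ",
         paste(missing_files, collapse = ", "))
  d
}
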