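# Figures are written as JPEG (default) with a machine-readable sidecar CSV
# holding exactly the data that were drawn, so tests and downstream checks
# assert on the sidecar rather than on pixels.

.open_device <- function(path, format, dpi) {
  w <- 6 * dpi; h <- 4 * dpi
  switch(format,
         jpeg = grDevices::jpeg(path, width = w, height = h, res = dpi,
                                quality = 95),
         png = grDevices::png(path, width = w, height = h, res = dpi),
         stop("unsupported figure format: ", format))
}

.sidecar_path <- function(out_path)
  paste0(tools::file_path_sans_ext(out_path), "_data.csv")

#' Plot a peptide's monoisotopic-RIA time series with its fitted decay
#'
#' Experimental points (MBR-quantified points in red, MS/MS-identified in
#' black) with the theoretical decay curve of the fitted rate constant as a
#' solid line.  A sidecar CSV (`<stem>_data.csv`) records each drawn point
#' (time, RIA, source, predicted value) and the fitted parameters.
#'
#' @param fit An `ria_fit` from [fit_rate()], or `NULL` when only points are
#'   available (no curve is drawn).
#' @param series The [ria_series()] to draw; defaults to the points stored
#'   in `fit`.
#' @param out_path Image path.
#' @param entry Protein entry name for the title.
#' @param format `"jpeg"` (default) or `"png"`.
#' @param dpi Image resolution (default 300).
#' @return Path of the written image, or `NULL` if nothing was drawn.
#' @export
plot_peptide_ria <- function(fit, series = NULL, out_path, entry = "",
                             format = c("jpeg", "png"), dpi = 300) {
  format <- match.arg(format)
  if (is.null(series) && !is.null(fit))
    series <- list(time = fit$time, ria = fit$ria, source = fit$source,
                   sequence = fit$sequence, charge = fit$charge)
  if (is.null(series) || !length(series$time)) {
    warning("empty series: no figure written")
    return(invisible(NULL))
  }
  have_curve <- !is.null(fit) && length(series$time) > 1L
  if (!have_curve && length(series$time) == 1L)
    warning("single point: scatter only, no curve")
  dat <- data.frame(time = series$time, ria = series$ria,
                    source = series$source,
                    predicted = if (have_curve)
                      theoretical_ria(series$time, fit$k, fit$I00,
                                      fit$I0asymp) else NA_real_)
  .open_device(out_path, format, dpi)
  on.exit(grDevices::dev.off())
  cols <- ifelse(dat$source == "mbr", "red", "black")
  graphics::plot(dat$time, dat$ria, col = cols, pch = 16,
                 xlab = "labeling duration (days)",
                 ylab = "monoisotopic RIA",
                 main = sprintf("%s (%s+) %s", series$sequence,
                                as.character(series$charge), entry))
  if (have_curve) {
    tt <- seq(0, max(dat$time), length.out = 200)
    graphics::lines(tt, theoretical_ria(tt, fit$k, fit$I00, fit$I0asymp))
  }
  side <- dat
  side$k <- if (have_curve) fit$k else NA_real_
  utils::write.csv(.format_numeric_cols(side), .sidecar_path(out_path),
                   row.names = FALSE)
  invisible(out_path)
}

#' Plot a protein's fractional-synthesis time series
#'
#' Overlays every peptide's experimental fractional synthesis as a scatter
#' and draws `1 - exp(-k_protein * t)` as a solid line.  Sidecar CSV records
#' the drawn points and the protein rate.
#'
#' @param fs_points data.frame with columns `time`, `fs`, `sequence`
#'   (and optionally `source`).
#' @param k_protein Protein rate constant, per day.
#' @param out_path Image path.
#' @param entry Protein entry name for the title.
#' @inheritParams plot_peptide_ria
#' @return Path of the written image, or `NULL`.
#' @export
plot_protein_fs <- function(fs_points, k_protein, out_path, entry = "",
                            format = c("jpeg", "png"), dpi = 300) {
  format <- match.arg(format)
  if (is.null(fs_points) || !nrow(fs_points)) {
    warning("no fractional-synthesis points: no figure written")
    return(invisible(NULL))
  }
  .open_device(out_path, format, dpi)
  on.exit(grDevices::dev.off())
  graphics::plot(fs_points$time, fs_points$fs, pch = 16,
                 col = "grey30", xlab = "labeling duration (days)",
                 ylab = "fractional synthesis",
                 main = sprintf("%s  k = %.4g /day", entry, k_protein))
  tt <- seq(0, max(fs_points$time), length.out = 200)
  graphics::lines(tt, 1 - exp(-k_protein * tt))
  side <- fs_points
  side$k_protein <- k_protein
  utils::write.csv(.format_numeric_cols(side), .sidecar_path(out_path),
                   row.names = FALSE)
  invisible(out_path)
}

#' Plot a six-isotopomer profile as a bar chart
#'
#' Normalized isotopomer abundances (M0..M5) of an extracted XIC or a
#' theoretical pattern, as drawn for unlabeled/labeled validation figures.
#'
#' @param x An `isotopomer_xic`, [isotope_pattern()], or numeric vector.
#' @param out_path Image path.
#' @param title Figure title.
#' @inheritParams plot_peptide_ria
#' @return Path of the written image, or `NULL`.
#' @export
plot_isotope_profile <- function(x, out_path, title = "isotope profile",
                                 format = c("jpeg", "png"), dpi = 300) {
  format <- match.arg(format)
  a <- if (inherits(x, "isotopomer_xic")) x$abundances
       else if (inherits(x, "isotope_pattern")) x$abundances
       else as.numeric(x)
  if (!length(a) || sum(a) <= 0) {
    warning("zero total abundance: no figure written")
    return(invisible(NULL))
  }
  a <- a / sum(a)
  .open_device(out_path, format, dpi)
  on.exit(grDevices::dev.off())
  graphics::barplot(a, names.arg = paste0("M", seq_along(a) - 1L),
                    ylab = "relative abundance", main = title)
  utils::write.csv(
    .format_numeric_cols(data.frame(isotopomer = paste0("M", seq_along(a) - 1L),
                                    abundance = a)),
    .sidecar_path(out_path), row.names = FALSE)
  invisible(out_path)
}

#' Batch-export validation figures for all proteins and peptides
#'
#' One fractional-synthesis figure per protein and one RIA-decay figure per
#' peptide, plus a manifest CSV of every written path.  Per-item failures
#' are caught, logged and listed in the manifest with an empty path.
#'
#' @param results A [turnover_run()] result.
#' @param out_dir Output directory.
#' @inheritParams plot_peptide_ria
#' @return data.frame manifest (columns `kind`, `id`, `path`; paths are
#'   relative to `out_dir` so identical runs give identical manifests),
#'   invisibly; also written to `manifest.csv` in `out_dir`.
#' @export
batch_export <- function(results, out_dir, format = c("jpeg", "png"),
                         dpi = 300) {
  stopifnot(inherits(results, "turnover_results"))
  format <- match.arg(format)
  ext <- if (format == "jpeg") "jpg" else "png"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(kind, id, path)
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, id = id,
                                             path = path,
                                             stringsAsFactors = FALSE)
  for (entry in results$proteins$protein) {
    sel <- vapply(strsplit(results$peptides$proteins, ";"),
                  function(v) entry %in% v, TRUE)
    keys <- paste(results$peptides$sequence[sel],
                  results$peptides$charge[sel], sep = "/")
    fs <- do.call(rbind, lapply(keys, function(kk) {
      d <- fractional_synthesis(results$series[[kk]])
      d$sequence <- results$series[[kk]]$sequence
      d
    }))
    kp <- results$proteins$k[results$proteins$protein == entry]
    path <- file.path(out_dir, sprintf("%s.FS.%s", entry, ext))
    ok <- tryCatch(plot_protein_fs(fs, kp, path, entry = entry,
                                   format = format, dpi = dpi),
                   error = function(e) {
                     message("FS figure failed for ", entry, ": ",
                             conditionMessage(e)); NULL })
    add("protein_fs", entry, if (is.null(ok)) "" else basename(path))
  }
  for (kk in names(results$fits)) {
    f <- results$fits[[kk]]
    entry <- results$peptides$proteins[
      paste(results$peptides$sequence, results$peptides$charge,
            sep = "/") == kk][1]
    path <- file.path(out_dir,
                      sprintf("%s.RIA.%s", gsub("/", "_", kk), ext))
    ok <- tryCatch(plot_peptide_ria(f, series = results$series[[kk]],
                                    out_path = path, entry = entry,
                                    format = format, dpi = dpi),
                   error = function(e) {
                     message("RIA figure failed for ", kk, ": ",
                             conditionMessage(e)); NULL })
    add("peptide_ria", kk, if (is.null(ok)) "" else basename(path))
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- data.frame(kind = character(), id = character(),
                           path = character(), stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
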