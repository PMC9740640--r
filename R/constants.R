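#' Isotope constants for CHNOS peptides
#'
#' Bundles the per-element isotope masses and natural abundances used to
#' compute peptide isotope distributions, together with the constants of the
#' deuterium-labeling model: the natural deuterium abundance `pH`, the
#' isotopomer mass spacing, and the proton mass.
#'
#' Abundances are the IUPAC representative natural values.  The isotopomer
#' spacing defaults to the 13C-12C mass difference; at peptide masses the
#' difference between carbon- and deuterium-induced spacing is far below the
#' ppm tolerances used for extraction.
#'
#' @param pH Natural deuterium abundance (fraction), default 1.15e-4.
#' @param spacing Mass spacing between adjacent isotopomers in Da.
#' @return An object of class `isotope_constants`: a list with elements
#'   `masses` (named list of per-element isotope mass vectors), `abundances`
#'   (matching abundance vectors, each summing to 1), `pH`, `spacing`, and
#'   `proton_mass`.
#' @examples
#' ic <- isotope_constants()
#' ic$abundances$C
#' @export
isotope_constants <- function(pH = 1.15e-4, spacing = 1.0033548378) {
  stopifnot(is.numeric(pH), length(pH) == 1L, pH > 0, pH < 1)
  stopifnot(is.numeric(spacing), length(spacing) == 1L,
            spacing > 1.0, spacing < 1.01)
  masses <- list(
    C = c(12.0000000, 13.0033548378),
    H = c(1.0078250319, 2.0141017779),
    N = c(14.0030740052, 15.0001088984),
    O = c(15.9949146221, 16.9991315, 17.9991604),
    S = c(31.97207069, 32.97145850, 33.96786683, 35.96708088)
  )
  abundances <- list(
    C = c(0.9893, 0.0107),
    H = c(1 - pH, pH),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
  # mass shift of each isotope relative to the lightest, in isotopomer units
  shifts <- list(C = 0:1, H = 0:1, N = 0:1, O = 0:2, S = c(0L, 1L, 2L, 4L))
  for (el in names(abundances)) {
    s <- sum(abundances[[el]])
    if (abs(s - 1) > 1e-9)
      stop("abundance vector for ", el, " does not sum to 1")
  }
  structure(
    list(masses = masses, abundances = abundances, shifts = shifts,
         pH = pH, spacing = spacing, proton_mass = 1.00727646688),
    class = "isotope_constants"
  )
}

# residue formulas (residue = amino acid minus water) and exchangeable-hydrogen
# counts per residue.  NEH values are the Commerford-style numbers used
# throughout the heavy-water turnover literature; they are data, not code, and
# can be overridden via residue_table(neh = ...) or a config file.
.residue_defaults <- function() {
  comp <- rbind(
    #    C   H  N  O  S
    A = c(3,  5, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    N = c(4,  6, 2, 2, 0),
    D = c(4,  5, 1, 3, 0),
    C = c(3,  5, 1, 1, 1),
    E = c(5,  7, 1, 3, 0),
    Q = c(5,  8, 2, 2, 0),
    G = c(2,  3, 1, 1, 0),
    H = c(6,  7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0),
    L = c(6, 11, 1, 1, 0),
    K = c(6, 12, 2, 1, 0),
    M = c(5,  9, 1, 1, 1),
    F = c(9,  9, 1, 1, 0),
    P = c(5,  7, 1, 1, 0),
    S = c(3,  5, 1, 2, 0),
    T = c(4,  7, 1, 2, 0),
    W = c(11, 10, 2, 1, 0),
    Y = c(9,  9, 1, 2, 0),
    V = c(5,  9, 1, 1, 0)
  )
  colnames(comp) <- c("C", "H", "N", "O", "S")
  neh <- c(A = 4.00, R = 3.43, N = 1.89, D = 1.89, C = 1.62,
           E = 3.95, Q = 3.95, G = 2.06, H = 2.88, I = 1.00,
           L = 0.60, K = 0.54, M = 1.12, F = 0.32, P = 2.59,
           S = 2.61, T = 0.20, W = 0.08, Y = 0.42, V = 0.56)
  list(composition = comp, neh = neh[rownames(comp)])
}

#' Amino-acid residue table
#'
#' Per-residue elemental composition (CHNOS, residue form: amino acid minus
#' water) and exchangeable-hydrogen counts (NEH) — the number of hydrogens per
#' residue that exchange with body-water deuterium during biosynthesis.
#'
#' @param neh Optional named numeric vector overriding per-residue NEH values
#'   (names are one-letter residue codes).
#' @param file Optional path to a plain-text config with lines
#'   `"<residue> <C> <H> <N> <O> <S> <NEH>"`; `#` starts a comment.  Entries
#'   replace the defaults residue by residue.
#' @return An object of class `residue_table`: list with `composition` (20 x 5
#'   integer matrix, rows named by residue letter) and `neh` (named numeric).
#' @examples
#' rt <- residue_table()
#' rt$neh[["A"]]
#' cfg <- system.file("extdata", "residue_config_example.txt",
#'                    package = "hwturnover")
#' residue_table(file = cfg)$neh[["A"]]
#' @export
residue_table <- function(neh = NULL, file = NULL) {
  def <- .residue_defaults()
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      f <- strsplit(ln, "[[:space:],]+")[[1]]
      if (length(f) != 7L)
        stop("bad residue config line (want 7 fields): ", ln)
      r <- f[1]
      if (nchar(r) != 1L) stop("residue code must be one letter: ", r)
      vals <- as.numeric(f[2:7])
      if (anyNA(vals)) stop("non-numeric field in residue config line: ", ln)
      def$composition[r, ] <- vals[1:5]
      def$neh[r] <- vals[6]
    }
  }
  if (!is.null(neh)) {
    stopifnot(is.numeric(neh), !is.null(names(neh)))
    bad <- setdiff(names(neh), rownames(def$composition))
    if (length(bad)) stop("unknown residues in neh override: ",
                          paste(bad, collapse = ", "))
    def$neh[names(neh)] <- neh
  }
  if (any(def$neh < 0)) stop("NEH contributions must be >= 0")
  structure(def, class = "residue_table")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Isotope constants (CHNOS)\n")
  cat(sprintf("  natural deuterium abundance pH: %g\n", x$pH))
  cat(sprintf("  isotopomer spacing: %.10f Da\n", x$spacing))
  cat(sprintf("  proton mass: %.11f Da\n", x$proton_mass))
  invisible(x)
}

#' @export
print.residue_table <- function(x, ...) {
  cat("Residue table: 20 standard residues, CHNOS + NEH\n")
  print(cbind(x$composition, NEH = x$neh))
  invisible(x)
}
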