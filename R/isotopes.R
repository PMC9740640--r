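# ---- elemental composition ---------------------------------------------

#' Elemental composition of a peptide sequence
#'
#' Sums per-residue CHNOS compositions and adds one water (the peptide
#' termini), giving the composition of the whole neutral peptide.
#'
#' @param sequence Amino-acid string using the 20 standard one-letter codes.
#' @param table A [residue_table()].
#' @return Named integer vector of class `elemental_composition` with
#'   components C, H, N, O, S.
#' @examples
#' composition_from_sequence("GG")   # C4 H8 N2 O3
#' @export
composition_from_sequence <- function(sequence, table = residue_table()) {
  letters <- .split_sequence(sequence, table)
  comp <- colSums(table$composition[letters, , drop = FALSE])
  comp[["H"]] <- comp[["H"]] + 2   # water
  comp[["O"]] <- comp[["O"]] + 1
  structure(as.integer(comp), names = names(comp),
            class = "elemental_composition")
}

.split_sequence <- function(sequence, table) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, rownames(table$composition))
  if (length(bad))
    stop("unknown residue letter(s) in \"", sequence, "\": ",
         paste(unique(bad), collapse = ", "))
  letters
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  cat(paste0(names(nz), nz, collapse = " "), "\n")
  invisible(x)
}

#' Exchangeable-hydrogen count of a peptide
#'
#' Number of peptide hydrogens accessible to body-water deuterium during
#' biosynthesis (NEH), as the sum of per-residue contributions.
#'
#' @inheritParams composition_from_sequence
#' @return Non-negative numeric scalar.
#' @export
neh_of_sequence <- function(sequence, table = residue_table()) {
  letters <- .split_sequence(sequence, table)
  sum(table$neh[letters])
}

#' Monoisotopic neutral mass of a composition
#' @param comp An `elemental_composition`.
#' @param constants An [isotope_constants()].
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(comp, constants = isotope_constants()) {
  sum(vapply(names(constants$masses),
             function(el) comp[[el]] * constants$masses[[el]][1], 0))
}

#' Theoretical m/z of a peptide composition at a charge state
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state.
#' @return (monoisotopic neutral mass + charge * proton mass) / charge.
#' @export
theoretical_mz <- function(comp, charge, constants = isotope_constants()) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  (monoisotopic_mass(comp, constants) + charge * constants$proton_mass) /
    charge
}

# ---- isotope patterns ---------------------------------------------------

#' Construct an isotope pattern
#'
#' A pattern holds the relative abundances of the first `n` unit-mass
#' isotopomers (M0, M1, ...), normalized to sum 1 over the retained peaks,
#' with the m/z of the monoisotopic peak at the given charge.
#'
#' @param abundances Non-negative numeric vector; renormalized to sum 1.
#' @param mono_mz m/z of M0.
#' @param charge Positive integer.
#' @param tail Mass of the distribution beyond the retained peaks that was
#'   dropped by truncation (kept as an attribute for diagnostics).
#' @return Object of class `isotope_pattern`.
#' @export
isotope_pattern <- function(abundances, mono_mz = NA_real_, charge = 1L,
                            tail = 0) {
  stopifnot(is.numeric(abundances), all(abundances >= 0),
            sum(abundances) > 0)
  structure(
    list(abundances = abundances / sum(abundances),
         mono_mz = mono_mz, charge = as.integer(charge)),
    tail = tail, class = "isotope_pattern"
  )
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("Isotope pattern, %d isotopomers, mono m/z %.4f (%d+)\n",
              length(x$abundances), x$mono_mz, x$charge))
  print(round(x$abundances, 6))
  invisible(x)
}

# truncated polynomial product: keep first n coefficients (these are exact;
# truncation only drops higher-order terms)
.conv_trunc <- function(a, b, n) {
  la <- min(length(a), n); lb <- min(length(b), n)
  out <- numeric(n)
  for (i in seq_len(la)) {
    jmax <- min(lb, n - i + 1L)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

# n-fold self-convolution by exponentiation-by-squaring, truncated to nkeep
.conv_power <- function(single, count, nkeep) {
  result <- c(1, numeric(nkeep - 1L))
  base <- single
  k <- count
  while (k > 0L) {
    if (k %% 2L == 1L) result <- .conv_trunc(result, base, nkeep)
    base <- .conv_trunc(base, base, nkeep)
    k <- k %/% 2L
  }
  result
}

# per-element single-atom mass-shift polynomial (index = shift + 1)
.element_polynomial <- function(el, constants) {
  sh <- constants$shifts[[el]]
  ab <- constants$abundances[[el]]
  poly <- numeric(max(sh) + 1L)
  poly[sh + 1L] <- ab
  poly
}

#' Natural isotope pattern of a composition
#'
#' Aggregated (unit-mass-binned) isotopomer abundances obtained by convolving
#' the per-element natural isotope distributions, truncated to the first `n`
#' isotopomers and renormalized over the retained peaks.
#'
#' @inheritParams monoisotopic_mass
#' @param charge Charge state used for the reported monoisotopic m/z.
#' @param n Number of isotopomers retained (default 6: M0..M5).
#' @return An [isotope_pattern()] whose `tail` attribute records the
#'   probability mass beyond the retained peaks.
#' @examples
#' p <- natural_isotope_pattern(composition_from_sequence("SDEAVKPLGVK"),
#'                              charge = 2)
#' p$abundances
#' @export
natural_isotope_pattern <- function(comp, charge = 1L, n = 6L,
                                    constants = isotope_constants()) {
  stopifnot(n >= 1L)
  raw <- c(1, numeric(n - 1L))
  for (el in names(constants$abundances)) {
    cnt <- comp[[el]]
    if (cnt > 0L) {
      raw <- .conv_trunc(raw, .conv_power(.element_polynomial(el, constants),
                                          cnt, n), n)
    }
  }
  isotope_pattern(raw, mono_mz = theoretical_mz(comp, charge, constants),
                  charge = charge, tail = max(0, 1 - sum(raw)))
}

# ---- deuterium labeling model ------------------------------------------

#' Plateau monoisotopic RIA
#'
#' Closed-form asymptotic monoisotopic relative isotope abundance reached at
#' the plateau of heavy-water labeling:
#' `I0asymp = I00 * ((1 - pw) / (1 - pH))^NEH`, where `pw` is the body-water
#' deuterium enrichment and `pH` the natural deuterium abundance.
#'
#' @param I00 Natural (unlabeled) monoisotopic RIA.
#' @param pw Body-water enrichment in deuterium, fraction in \[0, 1).
#' @param constants An [isotope_constants()] supplying `pH`.
#' @param neh Exchangeable-hydrogen count, >= 0.
#' @return Plateau RIA value.
#' @export
plateau_ria <- function(I00, pw, constants = isotope_constants(), neh) {
  if (!is.numeric(pw) || length(pw) != 1L || pw < 0 || pw >= 1)
    stop("pw must lie in [0, 1)")
  if (!is.numeric(neh) || length(neh) != 1L || neh < 0)
    stop("neh must be >= 0")
  I00 * ((1 - pw) / (1 - constants$pH))^neh
}

# generalized-binomial deuterium incorporation weights over j = 0..n-1 heavy
# sites; w0 = (1-p)^neh exactly (the plateau closed-form factor).  For
# non-integer neh, terms with j > neh are zero (clamped), which only trims an
# already negligible tail for peptide-scale neh.
.incorporation_weights <- function(neh, p, n) {
  j <- 0:(n - 1L)
  w <- numeric(n)
  if (p == 0) { w[1] <- 1; return(w) }
  keep <- j <= neh
  jj <- j[keep]
  w[keep] <- exp(lgamma(neh + 1) - lgamma(jj + 1) - lgamma(neh - jj + 1) +
                 jj * log(p) + (neh - jj) * log1p(-p))
  w
}

#' Partially labeled isotope pattern
#'
#' Mixture model for the isotope pattern of a peptide pool in which a
#' fraction `fs` has been synthesized since labeling began: the unlabeled
#' (natural) pattern with weight `1 - fs` plus the plateau-labeled pattern
#' with weight `fs`.  The plateau pattern is the natural pattern convolved
#' with a binomial deuterium-incorporation distribution over `neh` sites at
#' per-site probability `(pw - pH) / (1 - pH)`, truncated to the retained
#' isotopomers; the truncated tail is dropped, not redistributed.
#'
#' @param natural An [isotope_pattern()] (unlabeled).
#' @param neh Exchangeable-hydrogen count.
#' @param pw Body-water deuterium enrichment, fraction.
#' @param fs Fractional synthesis in \[0, 1\].
#' @param constants An [isotope_constants()].
#' @return An [isotope_pattern()]; its `tail` attribute is the truncated
#'   mass (0 at `fs = 0`).
#' @export
labeled_pattern <- function(natural, neh, pw, fs,
                            constants = isotope_constants()) {
  stopifnot(inherits(natural, "isotope_pattern"))
  if (!is.numeric(fs) || length(fs) != 1L || fs < 0 || fs > 1)
    stop("fs must lie in [0, 1]")
  if (!is.numeric(neh) || length(neh) != 1L || neh < 0)
    stop("neh must be >= 0")
  if (pw < 0 || pw >= 1) stop("pw must lie in [0, 1)")
  n <- length(natural$abundances)
  p <- (pw - constants$pH) / (1 - constants$pH)
  p <- max(p, 0)
  w <- .incorporation_weights(neh, p, n)
  plateau <- .conv_trunc(natural$abundances, w, n)
  tail <- max(0, 1 - sum(plateau))
  # renormalize the plateau component before mixing: both mixture components
  # then sum to 1, so every isotopomer share is exactly linear in fs and the
  # monoisotopic share follows the decay model without truncation drift
  plateau <- plateau / sum(plateau)
  mix <- (1 - fs) * natural$abundances + fs * plateau
  isotope_pattern(mix, mono_mz = natural$mono_mz, charge = natural$charge,
                  tail = fs * tail)
}
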