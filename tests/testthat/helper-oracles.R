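# Independent oracles and fixture builders shared across the suite.

# exhaustive polynomial-expansion oracle: multiplies the per-atom isotope
# polynomials one atom at a time at full length (no truncation), then takes
# the first n coefficients.  Independent of the package's truncated
# exponentiation-by-squaring engine.
oracle_pattern <- function(comp, n = 6, constants = isotope_constants()) {
  polys <- list(
    C = constants$abundances$C,
    H = constants$abundances$H,
    N = constants$abundances$N,
    O = constants$abundances$O,
    S = {                       # S isotopes sit at shifts 0,1,2,4
      v <- numeric(5)
      v[c(1, 2, 3, 5)] <- constants$abundances$S
      v
    }
  )
  poly <- 1
  for (el in names(polys)) {
    for (i in seq_len(comp[[el]])) {
      a <- poly; b <- polys[[el]]
      out <- numeric(length(a) + length(b) - 1L)
      for (j in seq_along(a))
        out[j:(j + length(b) - 1L)] <- out[j:(j + length(b) - 1L)] + a[j] * b
      poly <- out
    }
  }
  raw <- poly[seq_len(n)]
  raw / sum(raw)
}

# independent residue-mass summation oracle (standard monoisotopic residue
# masses; peptide mass = sum + water)
oracle_peptide_mass <- function(sequence) {
  masses <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
              C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
              H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
              M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
              T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
  sum(masses[strsplit(sequence, "")[[1]]]) + 18.010565
}

random_peptides <- function(n, min_len = 3, max_len = 10) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i)
    paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
          collapse = ""), "")
}

# cache for the synthetic experiment sets shared by slower tests
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, builder) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- builder()
  .sim_cache[[name]]
}

paper_time_points <- c(0, 1, 2, 3, 6, 7, 9, 13, 16, 21, 24, 31)
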