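test_that("composition_from_sequence sums residues plus one water", {
  g <- composition_from_sequence("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O", "S")],
               c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
  gg <- composition_from_sequence("GG")
  expect_equal(unclass(gg)[c("C", "H", "N", "O")],
               c(C = 4L, H = 8L, N = 2L, O = 3L))
  expect_error(composition_from_sequence("GXZ"), "X")
  expect_error(composition_from_sequence(""), "empty")
})

test_that("monoisotopic mass matches the residue-mass summation oracle", {
  for (s in c("SDEAVKPLGVK", "G", "ACDEFGHIKLMNPQRSTVWY")) {
    expect_equal(monoisotopic_mass(composition_from_sequence(s)),
                 oracle_peptide_mass(s), tolerance = 1e-6)
  }
})

test_that("single-element patterns follow the closed forms", {
  ic <- isotope_constants()
  a <- ic$abundances$C[1]
  comp1 <- structure(c(C = 1L, H = 0L, N = 0L, O = 0L, S = 0L),
                     class = "elemental_composition")
  p1 <- natural_isotope_pattern(comp1)$abundances
  expect_equal(p1[1:2], c(a, 1 - a), tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  comp2 <- structure(c(C = 2L, H = 0L, N = 0L, O = 0L, S = 0L),
                     class = "elemental_composition")
  p2 <- natural_isotope_pattern(comp2)$abundances
  expect_equal(p2[1:3], c(a^2, 2 * a * (1 - a), (1 - a)^2),
               tolerance = 1e-12)
})

test_that("convolution engine matches the exhaustive expansion oracle", {
  set.seed(11)
  for (s in c("GG", "CMWK", random_peptides(10))) {
    comp <- composition_from_sequence(s)
    p <- natural_isotope_pattern(comp)
    expect_lt(max(abs(p$abundances - oracle_pattern(comp))), 1e-12)
    expect_true(all(p$abundances >= 0))
    expect_equal(sum(p$abundances), 1, tolerance = 1e-9)
  }
})

test_that("neh_of_sequence is the per-letter sum", {
  rt <- residue_table()
  expect_equal(neh_of_sequence("AA"), 2 * rt$neh[["A"]])
  set.seed(5)
  for (s in random_peptides(5)) {
    expect_equal(neh_of_sequence(s),
                 sum(rt$neh[strsplit(s, "")[[1]]]))
  }
  expect_error(neh_of_sequence("AB"), "B")
  zero <- residue_table(neh = stats::setNames(rep(0, 20),
                                              rownames(rt$composition)))
  expect_equal(neh_of_sequence("PEPTIDE", zero), 0)
})

test_that("plateau_ria evaluates the enrichment closed form", {
  ic <- isotope_constants()
  expect_equal(plateau_ria(0.5, ic$pH, ic, neh = 12), 0.5)
  expect_equal(plateau_ria(0.5, 0.046, ic, neh = 0), 0.5)
  expect_equal(plateau_ria(0.4, 0.046, ic, neh = 20),
               0.4 * ((1 - 0.046) / (1 - ic$pH))^20, tolerance = 1e-15)
  expect_error(plateau_ria(0.4, 1.2, ic, neh = 5), "pw")
  expect_error(plateau_ria(0.4, 0.046, ic, neh = -1), "neh")
})

test_that("plateau_ria decreases in enrichment and in NEH", {
  ic <- isotope_constants()
  pws <- seq(0.01, 0.2, by = 0.01)
  vals <- vapply(pws, function(p) plateau_ria(0.4, p, ic, neh = 10), 0)
  expect_true(all(diff(vals) < 0))
  nehs <- seq(0, 30, by = 2)
  vals <- vapply(nehs, function(n) plateau_ria(0.4, 0.046, ic, neh = n), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("theoretical_mz follows the charge algebra", {
  ic <- isotope_constants()
  comp <- composition_from_sequence("SDEAVKPLGVK")
  mz1 <- theoretical_mz(comp, 1); mz2 <- theoretical_mz(comp, 2)
  expect_equal(mz1, 2 * mz2 - ic$proton_mass, tolerance = 1e-10)
  expect_equal(theoretical_mz(composition_from_sequence("G"), 1),
               oracle_peptide_mass("G") + ic$proton_mass, tolerance = 1e-5)
  mzs <- vapply(1:4, function(z) theoretical_mz(comp, z), 0)
  expect_true(all(diff(mzs) < 0))
  expect_error(theoretical_mz(comp, 0), "charge")
})

test_that("labeled_pattern reduces to the natural pattern at the edges", {
  nat <- natural_isotope_pattern(composition_from_sequence("SDEAVKPLGVK"),
                                 charge = 2)
  expect_equal(labeled_pattern(nat, 19.9, 0.046, 0)$abundances,
               nat$abundances)
  expect_equal(labeled_pattern(nat, 0, 0.046, 1)$abundances,
               nat$abundances, tolerance = 1e-12)
  expect_error(labeled_pattern(nat, 19.9, 0.046, 1.5), "fs")
  expect_error(labeled_pattern(nat, -2, 0.046, 0.5), "neh")
})

test_that("fully labeled monoisotopic share matches the closed-form plateau", {
  ic <- isotope_constants()
  # small peptides with negligible truncated tail: closed-form agreement
  for (s in c("GG", "II", "GI")) {
    nat <- natural_isotope_pattern(composition_from_sequence(s))
    neh <- neh_of_sequence(s)
    lp <- labeled_pattern(nat, neh, 0.046, 1)
    expect_lt(attr(lp, "tail"), 1e-6)
    expect_equal(lp$abundances[1] / sum(lp$abundances),
                 plateau_ria(nat$abundances[1], 0.046, ic, neh),
                 tolerance = 1e-6)
  }
  # high-NEH peptide: agreement within its own truncation error
  nat <- natural_isotope_pattern(composition_from_sequence("SDEAVKPLGVK"))
  neh <- neh_of_sequence("SDEAVKPLGVK")
  lp <- labeled_pattern(nat, neh, 0.046, 1)
  expect_equal(lp$abundances[1],
               plateau_ria(nat$abundances[1], 0.046, ic, neh),
               tolerance = 2 * attr(lp, "tail"))
})

test_that("labeled mixtures are valid patterns at all fs", {
  nat <- natural_isotope_pattern(composition_from_sequence("HQGVMVGMGQK"),
                                 charge = 2)
  neh <- neh_of_sequence("HQGVMVGMGQK")
  for (fs in c(0, 0.25, 0.5, 0.75, 1)) {
    lp <- labeled_pattern(nat, neh, 0.046, fs)
    expect_true(all(lp$abundances >= 0))
    expect_equal(sum(lp$abundances), 1, tolerance = 1e-9)
  }
})

test_that("residue table loads overrides from a config file", {
  cfg <- tempfile(fileext = ".txt")
  writeLines(c("# residue C H N O S NEH", "G 2 3 1 1 0 9.5"), cfg)
  rt <- residue_table(file = cfg)
  expect_equal(rt$neh[["G"]], 9.5)
  expect_equal(rt$neh[["A"]], 4.00)
  expect_error(residue_table(neh = c(Z = 1)), "unknown")
})
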