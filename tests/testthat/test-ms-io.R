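make_spec <- function(rt, mz, intensity, scan = NULL, ms_level = 1L)
  list(rt = rt, mz = mz, intensity = intensity, scan = scan,
       ms_level = ms_level)

test_that("mzML round-trips scans, RTs and peak arrays through the reader", {
  mz <- c(400.1, 400.6017, 401.1034)
  int <- c(100, 50, 25)
  specs <- list(make_spec(1.0, mz, int, scan = 1),
                make_spec(1.5, mz, int * 2, scan = 2),
                make_spec(2.0, mz, int * 3, scan = 3))
  path <- tempfile(fileext = ".mzML")
  write_mzml(specs, path)
  got <- read_ms1_spectra(path)
  expect_length(got, 3)
  expect_equal(vapply(got, `[[`, 0, "rt"), c(1.0, 1.5, 2.0),
               tolerance = 1e-9)
  expect_equal(got[[2]]$mz, mz, tolerance = 1e-12)
  expect_equal(got[[2]]$intensity, int * 2, tolerance = 1e-12)
  expect_true(got[[1]]$centroided)
  expect_equal(attr(got, "base_peaks"), c(100, 200, 300))
})

test_that("only MS-level-1 spectra are returned, in RT order", {
  specs <- list(make_spec(2.0, 400, 10, scan = 3),
                make_spec(1.0, 400, 10, scan = 1),
                make_spec(1.2, c(200, 300), c(5, 5), scan = 2, ms_level = 2L),
                make_spec(1.5, 400, 10, scan = 4),
                make_spec(1.7, 300, 4, scan = 5, ms_level = 2L))
  path <- tempfile(fileext = ".mzML")
  write_mzml(specs, path)
  got <- read_ms1_spectra(path)
  expect_length(got, 3)
  expect_equal(vapply(got, `[[`, 0, "rt"), c(1.0, 1.5, 2.0),
               tolerance = 1e-9)
})

test_that("an mzML without MS1 scans yields an empty stream with a warning", {
  path <- tempfile(fileext = ".mzML")
  write_mzml(list(make_spec(1, 300, 5, ms_level = 2L)), path)
  expect_warning(got <- read_ms1_spectra(path), "no MS1")
  expect_length(got, 0)
})

test_that("malformed mzML is a hard error naming the file", {
  path <- tempfile(fileext = ".mzML")
  writeLines("<mzML>this is not valid", path)
  expect_error(read_ms1_spectra(path), basename(path), fixed = TRUE)
  expect_error(read_ms1_spectra("/nonexistent.mzML"), "not found")
})

mzid_fixture <- function(psms, path = tempfile(fileext = ".mzid")) {
  write_mzid(psms, path)
  path
}

base_psms <- function() data.frame(
  sequence = c("SDEAVKPLGVK", "NLLSVAYK", "AGFAGDDAPR", "LVTDLTK",
               "DLTDYLMK"),
  charge = c(2L, 2L, 2L, 2L, 2L),
  mz = c(571.82, 454.27, 488.73, 395.24, 499.74),
  scan = 1:5, rt = c(10, 11, 12, 13, 14),
  score = c(55, 45, 30, 15, 10),
  expectation = c(1e-4, 1e-3, 0.01, 0.2, 0.9),
  protein = c("FAS_SYN", "ACTB_SYN", "ACTB_SYN", "FAS_SYN", "ALBU_SYN"),
  stringsAsFactors = FALSE)

test_that("identification filters drop low-score and high-expectation PSMs", {
  path <- mzid_fixture(base_psms())
  got <- read_identifications(path, min_score = 20, max_expectation = 0.05)
  expect_equal(sort(got$sequence),
               sort(c("SDEAVKPLGVK", "NLLSVAYK", "AGFAGDDAPR")))
  # idempotence: re-applying the same thresholds changes nothing
  expect_equal(nrow(got), 3)
  all5 <- read_identifications(path, min_score = 0, max_expectation = 1)
  expect_equal(nrow(all5), 5)
})

test_that("the highest-scoring PSM represents a (sequence, charge) pair", {
  p <- base_psms()[c(1, 1), ]
  p$score <- c(40, 60); p$scan <- c(1, 2); p$rt <- c(10, 10.2)
  path <- mzid_fixture(p)
  got <- read_identifications(path, min_score = 0, max_expectation = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$score, 60)
  expect_equal(got$scan, 2)
})

test_that("mzid round-trips all PSM fields", {
  p <- base_psms()
  path <- mzid_fixture(p)
  got <- read_identifications(path, min_score = 0, max_expectation = 1)
  got <- got[match(p$sequence, got$sequence), ]
  expect_equal(got$charge, p$charge)
  expect_equal(got$precursor_mz, p$mz, tolerance = 1e-6)
  expect_equal(got$score, p$score)
  expect_equal(got$expectation, p$expectation, tolerance = 1e-9)
  expect_equal(got$rt, p$rt, tolerance = 1e-6)
  expect_equal(got$proteins, p$protein)
  expect_true(all(got$uniqueness == "distinct"))
})

test_that("shared peptides collect all parent proteins", {
  p <- base_psms()[c(1, 1), ]
  p$protein <- c("FAS_SYN", "ALBU_SYN")
  # same scan (one spectrum, two evidences)
  p$scan <- c(1, 1); p$score <- c(55, 55)
  path <- mzid_fixture(p)
  got <- read_identifications(path, min_score = 0, max_expectation = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$proteins, "ALBU_SYN;FAS_SYN")
  expect_equal(got$uniqueness, "shared")
})

test_that("input pairs match on case-insensitive stems", {
  d <- tempfile("pairs"); dir.create(d)
  file.create(file.path(d, c("a.mzML", "a.mzid", "B.mzML", "b.MZID",
                             "c.mzML")))
  expect_message(pairs <- match_input_pairs(d), "c.mzML")
  expect_equal(nrow(pairs), 2)
  expect_equal(tolower(basename(pairs$mzML_path)), c("a.mzml", "b.mzml"))
  expect_equal(nrow(match_input_pairs(tempfile("empty_missing"))), 0)
})

test_that("stem collisions are hard errors and suffixes are stripped", {
  d <- tempfile("coll"); dir.create(d)
  file.create(file.path(d, c("x.mzML", "x_msms.mzML", "x.mzid")))
  expect_error(match_input_pairs(d), "collision")
  d2 <- tempfile("suf"); dir.create(d2)
  file.create(file.path(d2, c("y_msms.mzML", "y.mzid")))
  expect_equal(nrow(match_input_pairs(d2)), 1)
})

test_that("twelve synthetic pairs enumerate in stem order", {
  d <- tempfile("twelve"); dir.create(d)
  for (i in 1:12)
    file.create(file.path(d, sprintf(c("run%02d.mzML", "run%02d.mzid"), i)))
  pairs <- match_input_pairs(d)
  expect_equal(nrow(pairs), 12)
  expect_equal(basename(pairs$mzML_path), sprintf("run%02d.mzML", 1:12))
})

test_that("experiment tables validate columns, ranges and files", {
  d <- tempfile("tab"); dir.create(d)
  mz <- file.path(d, "r1.mzML"); id <- file.path(d, "r1.mzid")
  write_mzml(list(make_spec(1, 400, 10)), mz)
  write_mzid(base_psms()[1, ], id)
  tab <- file.path(d, "experiments.csv")
  utils::write.csv(data.frame(mzML_path = "r1.mzML", mzid_path = "r1.mzid",
                              time_days = 7, BWE = 0.046), tab,
                   row.names = FALSE)
  got <- read_experiment_table(tab)
  expect_true(file.exists(got$mzML_path))
  utils::write.csv(data.frame(a = 1), tab, row.names = FALSE)
  expect_error(read_experiment_table(tab), "lacks column")
})
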