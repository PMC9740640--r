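test_that("theoretical_ria evaluates the one-pool decay", {
  expect_equal(theoretical_ria(0, 0.1, 0.5, 0.3), 0.5)
  expect_equal(theoretical_ria(1e6, 0.5, 0.5, 0.3), 0.3, tolerance = 1e-12)
  expect_equal(theoretical_ria(10, 0.1, 0.5, 0.3), 0.3 + 0.2 * exp(-1),
               tolerance = 1e-15)
  expect_error(theoretical_ria(-1, 0.1, 0.5, 0.3), "t")
  expect_error(theoretical_ria(1, -0.1, 0.5, 0.3), "k")
})

test_that("noiseless series are recovered to optimizer precision", {
  for (k_true in c(0.01, 0.05, 0.3)) {
    y <- theoretical_ria(paper_time_points, k_true, 0.5, 0.3)
    s <- ria_series(paper_time_points, y, 0.5, 0.3, sequence = "TEST")
    f <- fit_rate(s)
    expect_lt(abs(f$k - k_true) / k_true, 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
    expect_true(f$ci_low <= f$k && f$k <= f$ci_high)
  }
})

test_that("a constant series fits to the k = 0 boundary", {
  s <- ria_series(paper_time_points, rep(0.5, 12), 0.5, 0.3)
  f <- fit_rate(s)
  expect_equal(f$k, 0)
  expect_lt(f$rmse, 1e-12)
})

test_that("fit_rate enforces the minimum point count", {
  s <- ria_series(c(0, 7), c(0.5, 0.4), 0.5, 0.3)
  expect_error(fit_rate(s, min_ndp = 3), "min_ndp")
  expect_s3_class(fit_rate(s, min_ndp = 2), "ria_fit")
})

test_that("rates are recovered within 5% under measurement noise", {
  set.seed(99)
  k_true <- 0.1
  errs <- replicate(100, {
    y <- theoretical_ria(paper_time_points, k_true, 0.5, 0.3) +
      stats::rnorm(12, 0, 0.005)
    y <- pmin(pmax(y, 1e-6), 1)
    f <- fit_rate(ria_series(paper_time_points, y, 0.5, 0.3))
    abs(f$k - k_true) / k_true
  })
  expect_lt(stats::median(errs), 0.05)
})

test_that("fractional synthesis reproduces 1 - exp(-kt) on model series", {
  k <- 0.21
  y <- theoretical_ria(paper_time_points, k, 0.47, 0.19)
  s <- ria_series(paper_time_points, y, 0.47, 0.19)
  fs <- fractional_synthesis(s)
  expect_equal(fs$fs, 1 - exp(-k * paper_time_points), tolerance = 1e-12)
  expect_equal(fs$fs[1], 0)
  s2 <- ria_series(c(0, 1), c(0.47, 0.19), 0.47, 0.19)
  expect_equal(fractional_synthesis(s2)$fs[2], 1)
  s3 <- ria_series(c(0, 1), c(0.5, 0.4), 0.5, 0.5)
  expect_error(fractional_synthesis(s3), "degenerate")
})

test_that("goodness_of_fit matches hand-computed formulas", {
  obs <- c(1, 2, 3, 4); pred <- obs
  g <- goodness_of_fit(obs, pred)
  expect_equal(unname(g[c("r2", "rmse", "pearson_r")]), c(1, 0, 1))
  g0 <- goodness_of_fit(obs, rep(mean(obs), 4))
  expect_equal(unname(g0[["r2"]]), 0)
  obs <- c(0.5, 0.42, 0.37); pred <- c(0.48, 0.44, 0.35)
  g <- goodness_of_fit(obs, pred)
  res <- obs - pred
  expect_equal(unname(g[["r2"]]),
               1 - sum(res^2) / sum((obs - mean(obs))^2))
  expect_equal(unname(g[["rmse"]]), sqrt(mean(res^2)))
  expect_equal(unname(g[["pearson_r"]]), stats::cor(obs, pred))
  expect_equal(unname(g[["sd"]]), sqrt(sum(res^2) / 2))
  expect_error(goodness_of_fit(1, 1), "2 points")
})

test_that("protein rate is the median of peptide rates", {
  mkfit <- function(k) structure(list(k = k, ndp = 12L, r2 = 0.99),
                                 class = "ria_fit")
  expect_equal(protein_rate(lapply(c(0.1, 0.2, 0.9), mkfit))$k, 0.2)
  expect_equal(protein_rate(lapply(c(0.1, 0.3), mkfit))$k, 0.2)
  set.seed(1)
  ks <- stats::runif(50, 0.01, 1)
  # sort-based oracle for the even-count median
  expect_equal(protein_rate(lapply(ks, mkfit))$k, mean(sort(ks)[25:26]))
  # permutation invariance
  expect_equal(protein_rate(lapply(sample(ks), mkfit))$k,
               protein_rate(lapply(ks, mkfit))$k)
  # robustness: replacing one rate by an outlier moves the median at most
  # one order statistic
  ks2 <- ks; ks2[1] <- 100
  m1 <- protein_rate(lapply(ks, mkfit))$k
  m2 <- protein_rate(lapply(ks2, mkfit))$k
  expect_lte(abs(m2 - m1), diff(range(sort(ks)[24:27])))
})

test_that("r2 floor excludes poor peptide fits from the protein median", {
  mkfit <- function(k, r2) structure(list(k = k, ndp = 12L, r2 = r2),
                                     class = "ria_fit")
  fits <- list(mkfit(0.1, 0.99), mkfit(0.2, 0.98), mkfit(5, 0.1))
  expect_equal(protein_rate(fits)$k, 0.2)
  expect_equal(protein_rate(fits, r2_floor = 0.9)$k, 0.15)
  expect_error(protein_rate(list(mkfit(1, 0.1)), r2_floor = 0.5), "floor")
})

test_that("consistency filter counts MS/MS runs only, keeps MBR points", {
  obs <- data.frame(
    sequence = rep("PEPK", 12), charge = 2, protein = "P1",
    experiment = 1:12,
    source = c(rep("identified", 3), rep("mbr", 9)),
    stringsAsFactors = FALSE)
  kept <- consistency_filter(obs, min_peptide_runs = 3, min_protein_runs = 1)
  expect_equal(nrow(kept), 12)
  expect_equal(nrow(consistency_filter(obs, min_peptide_runs = 4)), 0)
  obs2 <- data.frame(sequence = "AK", charge = 2, protein = "P2",
                     experiment = 1:2, source = "identified",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(consistency_filter(obs2, 3, 1)), 0)
  expect_equal(nrow(consistency_filter(rbind(obs, obs2), 0, 0)), 14)
})

test_that("normalized abundance uses the median of per-run medians", {
  expect_equal(normalized_protein_abundance(10, c(2, 2, 2)), 5)
  expect_equal(normalized_protein_abundance(10, list(c(1, 3, 5))), 10 / 3)
  bp <- list(c(1, 2, 3), c(10, 20, 30), c(4, 5, 6))
  expect_equal(normalized_protein_abundance(10, bp), 10 / 5)
  expect_error(normalized_protein_abundance(1, c(0, 0)), "not positive")
})

test_that("ria_fit methods are coherent", {
  y <- theoretical_ria(paper_time_points, 0.1, 0.5, 0.3)
  f <- fit_rate(ria_series(paper_time_points, y, 0.5, 0.3,
                           sequence = "NLLSVAYK", charge = 2L))
  expect_equal(unname(coef(f)), f$k)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, 0), 0.5)
  expect_equal(residuals(f), f$ria - fitted(f))
  expect_output(print(f), "NLLSVAYK")
  expect_output(summary(f), "95% CI")
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(12L, 3L))
})
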