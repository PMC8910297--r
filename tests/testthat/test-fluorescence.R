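test_that("inner-filter correction follows the half-path formula", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 100 * 10^0.1)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 125.89, tolerance = 1e-4)
  # doubling both absorbances squares the correction factor
  f1 <- inner_filter_correct(1, 0.07, 0.13)
  f2 <- inner_filter_correct(1, 0.14, 0.26)
  expect_equal(f2, f1^2)
  expect_error(inner_filter_correct(1, -0.1, 0), "absorbances")
})

test_that("dilution correction rescales by cumulative volume", {
  v <- c(10, 20, 30)
  expect_equal(dilution_correct(v, c(0, 0, 0), 1000), v)
  expect_equal(dilution_correct(c(1, 1), c(50, 50), 1000),
               c(1.05, 1.10))
  # apply-and-invert round trip on a random series
  withr::with_seed(3, {
    x <- runif(8, 50, 200)
    added <- runif(8, 0, 20)
  })
  factor <- (1000 + cumsum(added)) / 1000
  expect_equal(dilution_correct(x, added, 1000) / factor, x)
})

test_that("the one-site model passes through its midpoint and saturates", {
  # L = Kd without depletion: halfway between r_free and r_bound
  s <- simulate_fa_titration(50, protein_total = 1e-6, noise_r = 0,
                             ligand_points = c(0, 10, 25, 50, 100, 400, 5e5),
                             seed = 1)
  expect_equal(s$anisotropy[s$ligand_total_uM == 50], 0.15, tolerance = 1e-5)
  expect_equal(s$anisotropy[7], 0.20, tolerance = 1e-4) # L >> Kd
})

test_that("one-site fits recover a planted anisotropy Kd", {
  s <- simulate_fa_titration(35.2, noise_r = 0, seed = 1)
  f <- fit_one_site(s)
  expect_true(f$converged)
  expect_equal(f$kd_hat, 35.2, tolerance = 1e-4)
  expect_equal(f$r_free_hat, 0.10, tolerance = 1e-5)
  expect_equal(f$r_bound_hat, 0.20, tolerance = 1e-4)
  expect_false(f$saturation_warning)
})

test_that("depletion and no-depletion fits agree when protein is trace-level", {
  kd <- 200
  s <- simulate_fa_titration(kd, protein_total = kd * 1e-3, noise_r = 0,
                             seed = 2)
  f_dep <- fit_one_site(s, deplete = TRUE)
  f_hyp <- fit_one_site(s, deplete = FALSE)
  expect_equal(f_dep$kd_hat / f_hyp$kd_hat, 1, tolerance = 0.005)
})

test_that("an unsaturated titration is flagged but still fitted", {
  # ligand stops at a tenth of Kd: almost no curvature covered
  s <- simulate_fa_titration(1000, ligand_points = seq(0, 100, length.out = 8),
                             noise_r = 0, seed = 3)
  expect_warning(f <- fit_one_site(s), "saturation")
  expect_true(f$saturation_warning)
  expect_lt(f$saturation_fraction, 0.3)
  expect_true(is.finite(f$kd_hat))
})

test_that("specificity testing separates planted binding from a linear null", {
  # exactly linear decrease: no specific binding
  L <- seq(0, 800, length.out = 12)
  lin <- fa_series(tibble::tibble(ligand_total_uM = L,
                                  anisotropy = 0.15 - 5e-5 * L), 3)
  v <- test_specific_binding(lin)
  expect_false(v$specific)
  # flat response short-circuits
  flat <- fa_series(tibble::tibble(ligand_total_uM = L, anisotropy = 0.15), 3)
  expect_false(test_specific_binding(flat)$specific)
  expect_match(test_specific_binding(flat)$criterion, "flat")
  # saturating curve with Kd at mid-series and small noise: specific
  s <- simulate_fa_titration(35.2, noise_r = 0.001, seed = 4)
  v2 <- test_specific_binding(s)
  expect_true(v2$specific)
  expect_lt(v2$saturating_rss, v2$linear_rss)
  expect_lt(v2$p_value, 0.05)
})

test_that("curvature buried in noise is not called specific", {
  L <- seq(0, 800, length.out = 12)
  calls <- vapply(1:100, function(s) {
    y <- 0.15 - 5e-6 * L + 1e-4 * L / (5000 + L) +
      withr::with_seed(s, rnorm(12, 0, 0.002))
    test_specific_binding(
      fa_series(tibble::tibble(ligand_total_uM = L, anisotropy = y), 3)
    )$specific
  }, logical(1))
  expect_gte(mean(!calls), 0.9)
})

test_that("nonspecific-mode synthetic data get the n.a. verdict", {
  s <- simulate_fa_titration(Inf, ligand_points = seq(0, 800, length.out = 12),
                             noise_r = 0, intensity_slope = -0.5, seed = 5)
  expect_false(test_specific_binding(s)$specific)
  expect_false(test_specific_binding(s, response = "intensity")$specific)
})

test_that("fa_series validates its invariants", {
  expect_error(fa_series(tibble::tibble(ligand_total_uM = c(2, 1),
                                        anisotropy = c(0.1, 0.1)), 3),
               "nondecreasing")
  expect_error(fa_series(tibble::tibble(ligand_total_uM = c(1, 2),
                                        anisotropy = c(0.1, 0.9)), 3),
               "range")
  short <- fa_series(tibble::tibble(ligand_total_uM = c(0, 1, 2, 5),
                                    anisotropy = c(0.1, 0.11, 0.12, 0.14)), 3)
  expect_error(fit_one_site(short), "at least 5")
})

test_that("fa tidiers expose estimates in broom form", {
  f <- fit_one_site(simulate_fa_titration(35.2, seed = 6))
  td <- tidy(f)
  expect_equal(td$term, c("Kd", "r_free", "r_bound"))
  expect_true(all(is.finite(td$std.error)))
  expect_identical(glance(f)$kd_uM, f$kd_hat)
})
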