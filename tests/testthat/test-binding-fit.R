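test_that("the depletion isotherm matches its closed forms", {
  expect_equal(binding_isotherm(270, 0, 123, 0.5), 0)
  expect_equal(binding_isotherm(100, c(0, 10, 50), 1e-9, 1),
               c(0, 0.1, 0.5), tolerance = 1e-8) # stoichiometric limit
  # Pt = Lt = Kd: (3 - sqrt(5))/2
  expect_equal(binding_isotherm(100, 100, 100, 1), (3 - sqrt(5)) / 2)
  expect_equal(fraction_bound(100, 100, 100), (3 - sqrt(5)) / 2)
  expect_error(binding_isotherm(270, -1, 123, 1), "ligand_total")
  expect_error(binding_isotherm(0, 1, 123, 1), "protein_total")
})

test_that("the isotherm depends only on concentration ratios and obeys the physical bound", {
  withr::with_seed(7, {
    for (i in 1:20) {
      pt <- runif(1, 1, 500); lt <- runif(1, 0, 5000)
      kd <- runif(1, 1, 2000); k <- runif(1, 0.01, 100)
      expect_equal(binding_isotherm(k * pt, k * lt, k * kd, 1),
                   binding_isotherm(pt, lt, kd, 1))
      expect_lte(binding_isotherm(pt, lt, kd, 0.7),
                 0.7 * min(1, lt / pt) + 1e-12)
    }
  })
})

test_that("fraction bound saturates and is monotone in ligand", {
  expect_equal(fraction_bound(270, 1e12, 123), 1, tolerance = 1e-6)
  grid <- seq(0, 5000, by = 25)
  fb <- fraction_bound(270, grid, 123)
  expect_true(all(diff(fb) >= 0))
  expect_true(all(fb >= 0 & fb <= 1))
})

noiseless_profile <- function(kd, residue = 175, maxfold = 10, pt = 270) {
  res <- galectin_demo_residues()
  ds <- simulate_titration(
    res[res$residue_id == residue, ], kd = kd, protein_total = pt,
    ligand_points = design_ligand_series(pt, kd, 12, maxfold),
    noise_H = 0, noise_N = 0, seed = 1
  )
  csp_profiles(ds)
}

test_that("individual fits recover planted parameters from noiseless data", {
  f <- fit_individual(noiseless_profile(123))
  expect_true(f$converged)
  expect_equal(f$kd_hat, 123, tolerance = 1e-6)
  expect_equal(f$applicability, "ok")
  # independent optimizer cross-check: direct Nelder-Mead on the rss surface
  pr <- csp_profiles(simulate_titration(
    galectin_demo_residues()[67, ], kd = 123, seed = 3
  ))
  obs <- dplyr::filter(pr, ligand_total_uM > 0)
  f2 <- fit_individual(pr)
  rss_fn <- function(p) {
    sum((obs$d_ppm - binding_isotherm(270, obs$ligand_total_uM,
                                      exp(p[1]), exp(p[2])))^2)
  }
  nm <- stats::optim(c(log(500), log(0.05)), rss_fn,
                     control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f2$kd_hat, exp(nm$par[1]), tolerance = 1e-3)
  expect_equal(f2$rss, nm$value, tolerance = 1e-6)
})

test_that("a signal-free profile yields no spurious affinity", {
  pr <- csp_profiles(make_moving_dataset(rep(0, 6)))
  f <- fit_individual(pr)
  expect_true(!f$converged || f$dmax_hat < 1e-4)
  expect_true(!f$converged || !is.finite(f$kd_se) || f$kd_se / f$kd_hat > 10)
})

test_that("applicability flags mark the edges of the titration window", {
  f_weak <- fit_individual(noiseless_profile(11000, maxfold = 2))
  expect_equal(f_weak$kd_hat, 11000, tolerance = 1e-4)
  expect_equal(f_weak$applicability, "near_weak_limit")
  f_tight <- fit_individual(noiseless_profile(1, pt = 2, maxfold = 10))
  expect_equal(f_tight$applicability, "near_tight_limit")
})

test_that("global fits share Kd and recover per-residue amplitudes exactly at zero noise", {
  res9 <- demo_panel9()
  ds <- simulate_titration(res9, kd = 123, noise_H = 0, noise_N = 0, seed = 1)
  pr <- csp_profiles(ds)
  f <- fit_global(pr)
  expect_true(f$converged)
  expect_equal(f$kd_hat, 123, tolerance = 1e-6)
  dmax_true <- combined_shift_distance(res9$dH_offset, res9$dN_offset)
  names(dmax_true) <- res9$residue_id
  expect_equal(f$dmax_hat[names(dmax_true)], dmax_true, tolerance = 1e-5)
})

test_that("a single-residue global fit reduces to the individual fit", {
  pr <- csp_profiles(simulate_titration(
    galectin_demo_residues()[67, ], kd = 200, seed = 5
  ))
  fg <- fit_global(pr)
  fi <- fit_individual(pr)
  expect_equal(fg$kd_hat, fi$kd_hat)
  expect_equal(fg$dmax_hat, fi$dmax_hat)
  expect_equal(fg$rss, fi$rss)
})

test_that("conflicting planted affinities compromise between them", {
  # two residues, equal amplitude and grid, Kd 100 vs 400
  res <- galectin_demo_residues()[c(51, 67), ]
  res$dH_offset <- 0.12; res$dN_offset <- 0.8
  lig <- design_ligand_series(270, 200, 12, 10)
  mk <- function(kd, r) csp_profiles(simulate_titration(
    res[r, ], kd = kd, ligand_points = lig, noise_H = 0, noise_N = 0, seed = 1
  ))
  pr <- dplyr::bind_rows(mk(100, 1), mk(400, 2))
  f <- fit_global(pr)
  expect_gt(f$kd_hat, 100)
  expect_lt(f$kd_hat, 400)
  # brute-force 1-D profile of rss over a Kd grid as the oracle:
  # for fixed Kd the optimal dmax per residue is linear least squares
  obs <- dplyr::filter(pr, ligand_total_uM > 0)
  rss_at <- function(kd) {
    sum(unlist(lapply(split(obs, obs$residue_id), function(o) {
      fb <- fraction_bound(o$protein_total_uM, o$ligand_total_uM, kd)
      dmax <- sum(fb * o$d_ppm) / sum(fb^2)
      sum((o$d_ppm - dmax * fb)^2)
    })))
  }
  kd_grid <- exp(seq(log(50), log(800), length.out = 400))
  kd_star <- kd_grid[which.min(vapply(kd_grid, rss_at, numeric(1)))]
  expect_gt(kd_star, 100); expect_lt(kd_star, 400)
  expect_equal(f$kd_hat, kd_star, tolerance = 0.02)
})

test_that("covariance and bootstrap uncertainties agree on well-conditioned data", {
  ds <- simulate_titration(demo_panel9(), kd = 123, seed = 7)
  f <- fit_global(csp_profiles(ds))
  expect_gt(f$kd_se, 0)
  fb <- estimate_uncertainty(f, "bootstrap", n_boot = 200, seed = 11)
  expect_equal(fb$kd_se / f$kd_se, 1, tolerance = 0.3)
  # same seed, same data: identical bootstrap SE
  fb2 <- estimate_uncertainty(f, "bootstrap", n_boot = 200, seed = 11)
  expect_identical(fb$kd_se, fb2$kd_se)
  expect_identical(fb$kd_boot, fb2$kd_boot)
})

test_that("zero-noise data give a vanishing covariance SE", {
  f <- fit_individual(noiseless_profile(123))
  expect_lt(f$kd_se / f$kd_hat, 1e-4)
})

test_that("global Kd recovery is accurate and calibrated over planted datasets", {
  res9 <- demo_panel9()
  out <- vapply(1:100, function(s) {
    kd <- withr::with_seed(s + 5000, exp(runif(1, log(10), log(1000))))
    ds <- simulate_titration(
      res9, kd = kd,
      ligand_points = design_ligand_series(270, kd, 12, 10), seed = s
    )
    f <- fit_global(csp_profiles(ds))
    c(abs(f$kd_hat - kd) / kd, abs(f$kd_hat - kd) <= 2 * f$kd_se)
  }, numeric(2))
  expect_lt(median(out[1, ]), 0.10)
  expect_gte(mean(out[2, ]), 0.80)
})

test_that("weak binding with a truncated series degrades the relative precision", {
  res <- galectin_demo_residues()
  r175 <- res[res$residue_id == 175, ]
  rel_se <- function(kd, maxfold) {
    vapply(1:8, function(s) {
      ds <- simulate_titration(
        r175, kd = kd,
        ligand_points = design_ligand_series(270, kd, 12, maxfold), seed = s
      )
      f <- fit_individual(csp_profiles(ds))
      f$kd_se / f$kd_hat
    }, numeric(1))
  }
  # the weak titration cannot approach saturation: ligand stops at Kd/2
  ratio <- median(rel_se(8500, 0.5)) / median(rel_se(123, 10))
  expect_gte(ratio, 3)
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_global(csp_profiles(simulate_titration(demo_panel9(), kd = 123,
                                                  seed = 2)))
  td <- tidy(f)
  expect_equal(td$term[1], "Kd")
  expect_equal(nrow(td), 10L)
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(f)
  expect_equal(gl$n_residues, 9L)
  expect_identical(gl$kd_uM, f$kd_hat)
})
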