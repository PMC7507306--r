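test_that("bicarbonate-CO2 equilibrium reproduces the assay correspondences", {
  # 55 mM bicarbonate at pH 8.0 dissolves to roughly 0.7 mM CO2
  expect_equal(co2_from_bicarbonate(55, 8.0), 692.4, tolerance = 1e-3)
  expect_equal(co2_from_bicarbonate(4, 8.0), 50.4, tolerance = 1e-3)
  # at pH = pKa the two species are equimolar
  expect_equal(co2_from_bicarbonate(10, 6.10), 10 * 1000)
  # linear in bicarbonate, strictly decreasing in pH
  expect_equal(
    co2_from_bicarbonate(20, 8), 5 * co2_from_bicarbonate(4, 8)
  )
  expect_lt(co2_from_bicarbonate(10, 8.5), co2_from_bicarbonate(10, 7.5))
  expect_error(co2_from_bicarbonate(10, 12), "pH")
})

test_that("specific-activity calibration divides counts by RuBP", {
  expect_equal(calibrate_specific_activity(780), 150)
  expect_equal(calibrate_specific_activity(1560), 300)
  expect_equal(
    calibrate_specific_activity(2000), 2 * calibrate_specific_activity(1000)
  )
  expect_error(calibrate_specific_activity(0), "> 0")
})

test_that("CPM convert to per-site rates with matched units", {
  pt <- tibble::tibble(
    cpm = 9000, sa_cpm_per_nmol = 150, time_s = 120, sites_nmol = 0.1
  )
  expect_equal(cpm_to_rate(pt)$rate_per_s, 5)
  expect_equal(cpm_to_rate(dplyr::mutate(pt, cpm = 0))$rate_per_s, 0)
  expect_equal(
    cpm_to_rate(dplyr::mutate(pt, sites_nmol = 0.05))$rate_per_s, 10
  )
  # rescaling counts and specific activity together changes nothing
  expect_equal(
    cpm_to_rate(dplyr::mutate(pt,
      cpm = cpm * 7, sa_cpm_per_nmol = sa_cpm_per_nmol * 7
    ))$rate_per_s,
    5
  )
  expect_error(cpm_to_rate(dplyr::mutate(pt, sites_nmol = 0)), "> 0")
})

test_that("Michaelis-Menten fits recover noise-free parameters exactly", {
  s <- c(50, 100, 200, 350, 500, 700)
  pts <- tibble::tibble(co2_uM = s, rate_per_s = 22.2 * s / (276 + s))
  fit <- fit_michaelis_menten(pts)
  expect_equal(fit$kcat_per_s, 22.2, tolerance = 1e-6)
  expect_equal(fit$km_uM, 276, tolerance = 1e-4)
  # half-maximal rate at S = KM
  expect_equal(
    mm_rate(fit$kcat_per_s, fit$km_uM, fit$km_uM),
    fit$kcat_per_s / 2
  )
  # duplicated points leave the least-squares solution unchanged
  fit2 <- fit_michaelis_menten(dplyr::bind_rows(pts, pts))
  expect_equal(fit2$kcat_per_s, fit$kcat_per_s, tolerance = 1e-8)
  expect_equal(fit2$km_uM, fit$km_uM, tolerance = 1e-6)
  expect_error(
    fit_michaelis_menten(pts[c(1, 1, 2), ]),
    ">= 3 distinct"
  )
})

test_that("MM fits stay accurate under proportional Gaussian noise", {
  withr::local_seed(1001)
  s <- rep(c(50, 100, 200, 350, 500, 700), 2)
  truth <- 22.2
  errs <- vapply(1:100, function(i) {
    v <- 22.2 * s / (276 + s) + rnorm(length(s), 0, 0.03 * 22.2)
    fit <- fit_michaelis_menten(
      tibble::tibble(co2_uM = s, rate_per_s = pmax(v, 0))
    )
    abs(fit$kcat_per_s - truth) / truth
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("dissolved gas follows Henry's law", {
  expect_equal(dissolved_gas(4991, 0.0334), 166.7, tolerance = 1e-3)
  expect_equal(dissolved_gas(995009, 0.00126), 1253.7, tolerance = 1e-3)
  expect_equal(dissolved_gas(0, 0.0334), 0)
  expect_error(dissolved_gas(2e6, 0.0334), "ppm")
})

test_that("specificity from peaks matches hand arithmetic", {
  equal <- specificity_from_peaks(1000, 1000, 100, 100)
  expect_equal(equal$s_co, 1)
  res <- specificity_from_peaks(1330, 1000, 166.7, 1254)
  expect_equal(res$s_co, 1.33 * 1254 / 166.7, tolerance = 1e-9)
  expect_equal(res$s_co, 10.0, tolerance = 0.01 * 10)
  doubled <- specificity_from_peaks(1330, 1000, 166.7, 2 * 1254)
  expect_equal(doubled$s_co, 2 * res$s_co)
  expect_error(specificity_from_peaks(10, 0, 100, 100), "glycolate")
})

test_that("the specificity estimator is unbiased under binomial partitioning", {
  co2 <- dissolved_gas(4991, 0.0334)
  o2 <- dissolved_gas(995009, 0.00126)
  est <- vapply(1:50, function(i) {
    counts <- gen_specificity_counts(10, co2, o2, 1e5, seed = 2000 + i)
    specificity_from_peaks(
      counts$glycerate_cpm, counts$glycolate_cpm, co2, o2
    )$s_co
  }, numeric(1))
  expect_equal(mean(est), 10, tolerance = 0.02)
})
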