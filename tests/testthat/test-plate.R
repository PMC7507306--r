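cfg <- assay_config(epsilon_eff = 5000)

test_that("slope fitting recovers exact lines and flags thin data", {
  t <- seq(0, 900, 2)
  trace <- tibble::tibble(time_s = t, a340 = 1.0 - 0.001 * t)
  fit <- fit_slope(trace, cfg)
  expect_equal(fit$slope, -0.001, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- tibble::tibble(time_s = t, a340 = rep(0.8, length(t)))
  expect_equal(fit_slope(flat, cfg)$slope, 0)
  expect_error(
    fit_slope(trace[trace$time_s < 40, ], cfg),
    "need >= 10"
  )
})

test_that("noisy slope estimates fall within three standard errors", {
  withr::local_seed(901)
  t <- seq(0, 900, 2)
  hits <- vapply(1:100, function(i) {
    trace <- tibble::tibble(
      time_s = t, a340 = 2.5 - 0.0008 * t + rnorm(length(t), 0, 0.002)
    )
    fit <- fit_slope(trace, cfg)
    abs(fit$slope - (-0.0008)) <= 3 * fit$slope_se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("slope conversion honors extinction and 2:1 stoichiometry", {
  expect_equal(slope_to_carbox_rate(0, cfg), 0)
  # 1 uM NADH/s oxidation -> 0.5 uM/s carboxylation = 500 nM/s
  expect_equal(
    slope_to_carbox_rate(-cfg$epsilon_eff * 1e-6, cfg), 500
  )
  cfg2 <- assay_config(epsilon_eff = 10000)
  expect_equal(
    slope_to_carbox_rate(-cfg$epsilon_eff * 1e-6, cfg2),
    250
  )
  expect_warning(slope_to_carbox_rate(0.01, cfg), "clamped")
})

test_that("titration fit reads Vmax, [E] and kcat off the exact line", {
  pts <- tibble::tibble(
    cabp_nM = c(0, 10, 20, 30),
    rate_nM_s = c(500, 400, 300, 200)
  )
  fit <- titration_fit(pts, cfg)
  expect_equal(fit$vmax_nM_s, 500)
  expect_equal(fit$active_sites_nM, 50)
  expect_equal(fit$kcat_per_s, 10)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$active)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "kcat_per_s"], 10)
})

test_that("saturated-inhibition points are excluded from the refit", {
  # 90 nM exceeds the 50 nM of sites: rate is pinned at ~0 there
  pts <- tibble::tibble(
    cabp_nM = c(0, 0, 10, 20, 30, 90),
    rate_nM_s = c(500, 500, 400, 300, 200, 0)
  )
  fit <- titration_fit(pts, cfg)
  expect_equal(fit$active_sites_nM, 50, tolerance = 1e-9)
  expect_equal(fit$kcat_per_s, 10, tolerance = 1e-9)
  expect_equal(fit$n_points_used, 4)
})

test_that("flat titrations are inactive and not quantifiable", {
  pts <- tibble::tibble(cabp_nM = c(0, 10, 20, 30), rate_nM_s = 0)
  fit <- titration_fit(pts, cfg)
  expect_false(fit$quantifiable)
  expect_false(fit$active)
  expect_true(is.na(fit$kcat_per_s))
})

test_that("kcat is invariant to a common rescaling of rates and CABP", {
  pts <- tibble::tibble(
    cabp_nM = c(0, 10, 20, 30, 60),
    rate_nM_s = c(330, 264, 198, 132, 0.5)
  )
  f1 <- titration_fit(pts, cfg)
  f2 <- titration_fit(
    dplyr::mutate(pts,
      cabp_nM = cabp_nM * 3, rate_nM_s = rate_nM_s * 3
    ),
    cfg
  )
  expect_equal(f1$kcat_per_s, f2$kcat_per_s, tolerance = 1e-9)
})

test_that("the noise-free plate pipeline inverts the generator exactly", {
  g <- gen_plate_traces(6.6, 50, noise_sd = 0, seed = 902)
  res <- analyze_plate(g$traces, cfg)
  expect_equal(res$kcat_per_s, 6.6, tolerance = 1e-6)
  expect_equal(res$active_sites_nM, 50, tolerance = 1e-6)
  expect_true(res$active)
})

test_that("a reference-like variant lands near seven per second", {
  g <- gen_plate_traces(7, 50, noise_sd = 0.002, seed = 903)
  res <- analyze_plate(g$traces, cfg)
  expect_equal(res$kcat_per_s, 7, tolerance = 0.05)
})

test_that("activity calls are boundary-inclusive at the threshold", {
  expect_false(call_active(0.49, cfg))
  expect_true(call_active(0.5, cfg))
  expect_true(call_active(5.6, cfg))
  expect_false(call_active(NA_real_, cfg))
})

test_that("batch reference QC flags deviant batches and pools the rest", {
  withr::local_seed(904)
  batches <- tibble::tibble(
    batch = rep(1:49, each = 2),
    variant = rep(c("ref", "v1"), 49),
    kcat_per_s = c(rbind(rnorm(49, 6.6, 0.5), rnorm(49, 12, 1)))
  )
  qc <- batch_reference_check(batches, "ref", expected_kcat = 6.6)
  expect_equal(qc$summary$n_batches, 49)
  ref_vals <- batches$kcat_per_s[batches$variant == "ref"]
  expect_equal(qc$summary$se_kcat, sd(ref_vals) / sqrt(49))
  expect_equal(qc$summary$mean_kcat, mean(ref_vals))
  bad <- dplyr::bind_rows(
    batches,
    tibble::tibble(batch = 50, variant = "ref", kcat_per_s = 3.0)
  )
  qc2 <- batch_reference_check(bad, "ref", expected_kcat = 6.6)
  expect_true(qc2$batches$flagged[qc2$batches$batch == 50])
  expect_error(
    batch_reference_check(batches, "nope", 6.6),
    "missing"
  )
})
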